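---
title: "Circuit-level signaling activity: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit-level signaling activity: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathflow)
```

## The model

A signaling pathway is a directed graph. Nodes hold one or more gene
products; edges are signed, either activations or inhibitions. Two node
types are distinguished, following the conventions of curated pathway
repositories such as KEGG: *plain* nodes, whose proteins are alternative
carriers of the same signal, and *complex* nodes, which represent a protein
complex. Receptors are the nodes with no incoming edges, effectors those
with no outgoing edges; the effector proteins are the ones that actually
trigger a response in the cell, so the biologically meaningful unit of
analysis is the sub-pathway delivering signal to one effector.

`decompose_circuits()` extracts, for each (receptor, effector) pair joined
by a directed path, the **canonical circuit**: every node that is both
reachable from the receptor and able to reach the effector, with the edges
among them. An **effector circuit** is the union of the canonical circuits
sharing an effector. Two consequences of this definition are deliberate:

* Parallel branches that re-converge belong to *one* circuit. The
  propagation rule combines convergent activations multiplicatively, so
  branches cannot be scored independently and then reconciled; they must be
  evaluated jointly. A decomposition that enumerated each route separately
  would count more circuits but double-use the convergence rule.
* Cycles whose nodes lie between receptor and effector are kept. The
  propagation engine handles loops by iteration, so there is no reason to
  clip feedback out of the topology (many pathway-scoring approaches must).

### Node values

Expression is used as a proxy for protein presence. `scale_to_unit()` maps
each gene to [0, 1] by min-to-quantile scaling with truncation at the 0.99
quantile; no standard exists for this step, and the truncation guards the
scale against single extreme samples. The low end is not truncated — the
minimum observed expression is taken as absence. A constant gene is
mapped to 0.5, the signal-neutral value, and a single-sample matrix cannot
be scaled at all (0.5 throughout, with a warning). `summarize_nodes()` then
computes node values: the 90th percentile of member genes for plain nodes
(linear interpolation between order statistics, fixed so results are
bit-stable), the minimum for complexes (the limiting component). Genes
missing from the matrix are ignored; a node with no measured gene defaults
to 0.5 (configurable to an error). Both summaries are monotone, so node
values inherit the interpretability of the inputs.

### Propagation

Signal intensity is computed per node as

$$S_n = v_n \,\bigl(1 - \prod_{a \in A}(1 - s_a)\bigr)\,
        \prod_{i \in I}(1 - s_i)$$

with a virtual incoming activation of 1 at each receptor (so a receptor
transmits exactly its node value). One modelling decision deserves
emphasis: for a node with *no* activation inputs the literal empty product
would make the activation factor $1 - 1 = 0$ and permanently silence the
node. Instead the empty activation set contributes factor 1, so
inhibition-only nodes transmit $v_n \prod (1 - s_i)$. Without this choice an
inhibition edge into a pass-through node would be meaningless; with it, the
receptor seeding rule is also just the general rule.

The update is iterated with a worklist: all signals start at 0, nodes are
processed in breadth-first order from the receptors, and whenever a node
changes by more than the convergence threshold (default $10^{-6}$) its
downstream neighbours are re-queued. All factors lie in [0, 1], so signals
are bounded and loop gains never exceed 1: negative feedback contracts to a
fixed point (the package's test fixture A→B→C with C⊣B converges to
$S_B = 2/3$, $S_C = 1/3$). The one degenerate case is a marginal cycle at
unit gain — e.g. an odd ring of inhibitions among nodes with $v = 1$ —
which flips forever; a pass limit (default 100) cuts it off and the
configured policy either warns (returning the last state, flagged
`converged = FALSE`) or errors. On acyclic circuits the iteration agrees
with a single topological-order pass (`propagate_dag_oracle()`, kept as an
independent reference used by the test-suite).

Propagation is vectorized across samples: node values enter as a
nodes × samples matrix and all columns iterate simultaneously.

### Functions, variants, statistics

Effector activities are aggregated to cell-function activities by treating
each annotated function as a virtual node of value 1 receiving only
activations from its effectors: $1 - \prod_e (1 - S_e)$. GMT annotation
inputs carry no sign information, which is why no inhibitory
effector→function link exists.

Variant integration multiplies the scaled expression of a damaged gene by
0. A call is damaging per se for stop gain, stop loss and
splicing-disrupting consequences, or when a pathogenicity score is beyond
its cutoff (SIFT-like ≤ 0.05 *or* PolyPhen-like ≥ 0.85) at a conserved site
(phastCons-like ≥ 0.95). The cutoffs are the scores' conventional damaging
ranges and are configurable; no published standard fixes them for this use.
Dominant inheritance zeroes on any qualifying call; recessive requires a
homozygous call or two distinct heterozygous calls in the gene (compound
heterozygosity, phasing ignored).

Differential activation uses the two-sided Wilcoxon rank-sum test — the
natural choice for bounded, non-normal activity values — exact when the
combined group size is ≤ 20 and tie-free, otherwise the normal
approximation with tie and continuity correction. Benjamini–Hochberg
adjustment is applied across all features of one activity matrix, i.e.
separately per level (circuits, effector circuits, functions), matching how
significant counts are reported per level. Constant features are assigned
p = 1. A logit-t alternative was considered and rejected: it adds a
transform parameter without improving calibration on bounded activities.

The survival layer is self-contained: the Kaplan–Meier product-limit
estimator and the 1-df log-rank test are implemented directly (and checked
against `survival::survdiff` in the tests). For each feature, the samples
in the extreme `fraction` (default 10%, round-half-up, minimum 1, ties
broken by stable sample order) of activity — high and low sides both —
are compared against the remaining samples; p-values are BH-corrected
jointly over all (feature, side) pairs, the conservative choice given that
both sides are always scanned. The prognosis label compares the strata's
K-M curves at the median follow-up time, falling back to restricted mean
survival on exact ties.

## Simulation design

`generate_synthetic_pathway()` builds random connected topologies: a
backbone in which node $j$ receives an edge from a random earlier node
(guaranteeing reachability from the single in-degree-0 receptor), extra
forward edges (40% of the node count by default), optional feedback edges
among interior nodes (so receptor/effector status survives), and a chosen
fraction of inhibition edges. `generate_cohort()` implements three null
scenarios: resampling columns of a template, per-gene normal draws with the
template's empirical means and variances, and the fully synthetic flat
scenario — every value i.i.d. Normal(mean 0.5, **variance** 0.05; the sd is
$\approx 0.224$) clamped to [0, 1], since the propagation rule requires
bounded values. All generators are bit-reproducible under a seed and leave
the caller's RNG state untouched.

The specificity protocol (`estimate_fpr()`) splits a homogeneous cohort in
half at random and counts circuits called significant — all false positives
by construction. The shipped calibration (`scripts/acceptance.R`, also the
deepest test in the suite) uses 3 pathways of ~15 nodes (one with a cycle,
20% inhibition edges), cohorts of 40 samples × 1000 genes, and 100
repetitions at α = 0.05, a desk-scale setting that completes in well under
a minute per 25 repetitions on one CPU; the repetition count and cohort
size are plain arguments for larger runs. Observed FPR in this setting is
of the order of a few per mille — far below α, as expected when BH controls
the FDR under a global null of correlated, rank-tested features.

The sensitivity protocol (`estimate_tpr()`) injects a multiplicative
fold-change (default 1.5×) on one circuit's member genes in the case
samples *before* unit scaling — mimicking coordinated differential
expression — and scores, per designated pathway, whether any of its
circuits is detected at the FDR threshold. With 100 cases vs 100 controls
the injected circuit is recovered with adjusted p-values indistinguishable
from zero and ranks first within its pathway.

What these simulations do *not* emulate: real expression is heteroscedastic
across genes, co-expressed in blocks, and batch-structured; cohorts carry
covariates; real pathway topologies have hubs and far more complexes. A
clean FPR/TPR here therefore demonstrates statistical self-consistency of
the pipeline, not performance on any particular tumour cohort. Upstream
normalization (TMM-style library normalization, batch correction) is
assumed done before data enter the package.

## Numerical choices, degenerate inputs

* Convergence threshold $10^{-6}$, pass limit 100: small enough that toy
  fixtures agree with closed forms to six decimals, large enough that
  marginal oscillators terminate promptly.
* Quantile interpolation: `type = 7` (linear) everywhere, stated so that
  results are reproducible across implementations.
* Extreme-decile size: `floor(0.1 n + 0.5)` (round-half-up), minimum 1.
* Per-gene scaling when the truncation quantile equals the minimum but the
  gene is not constant: values above the quantile map to 1, the rest to 0.
* Unknown variant consequence strings are warned about and treated as
  non-deleterious per se (score-based zeroing still applies).
* KGML relation subtypes outside the configured sign map (e.g.
  binding/association) are dropped with a warning, never silently signed.

## Known limitations

* Receptor/effector status is purely topological; a pathway drawn with a
  regulatory stub upstream of the true receptor will shift the circuit
  boundaries accordingly.
* mRNA abundance is a proxy for protein presence and says nothing about
  post-translational activation; the activity values are comparative, not
  absolute signal flux.
* The decomposition reports one canonical circuit per (receptor, effector)
  pair; counts are not comparable with decompositions that enumerate each
  parallel route separately.
* No paired designs, covariate adjustment or Cox regression; the survival
  layer is a screening scan, not a prognostic model.
* Copy-number and methylation data are not integrated (they would enter the
  same way as variant integrity factors, as multiplicative presence
  proxies).
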