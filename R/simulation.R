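# Synthetic pathways and cohorts, and the specificity (false positive rate)
# and sensitivity (true positive rate) protocols that calibrate the whole
# pipeline without external data.

#' Cohort specification for simulated expression matrices
#'
#' Three scenarios are supported. `flat_normal` draws every value i.i.d.
#' from a normal with the given mean and *variance* (defaults 0.5 and 0.05,
#' i.e. sd ~0.224) and clamps to \[0, 1\]. `gene_wise_normal` draws each
#' gene from a normal with that gene's sample mean and variance in a
#' template matrix. `empirical_resample` resamples template columns with
#' replacement.
#'
#' @param scenario One of `"flat_normal"`, `"gene_wise_normal"`,
#'   `"empirical_resample"`.
#' @param n_samples Cohort size (>= 4).
#' @param genes Gene ids (or a single count) for `flat_normal`.
#' @param template Genes x samples matrix, required by the other two
#'   scenarios.
#' @param mean,variance Parameters of the flat scenario.
#' @param clamp Clamp draws to \[0, 1\] (the propagation rule needs bounded
#'   values).
#' @param seed Optional integer seed; generation is bit-reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(scenario = c("flat_normal", "gene_wise_normal",
                                     "empirical_resample"),
                        n_samples, genes = NULL, template = NULL,
                        mean = 0.5, variance = 0.05, clamp = TRUE,
                        seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n_samples >= 4)
  if (variance <= 0) stop("variance must be positive")
  if (scenario != "flat_normal" && is.null(template)) {
    stop("scenario '", scenario, "' requires a template matrix")
  }
  if (scenario == "flat_normal") {
    if (is.null(genes)) stop("flat_normal requires `genes`")
    if (is.numeric(genes) && length(genes) == 1L) {
      genes <- sprintf("G%04d", seq_len(genes))
    }
  }
  structure(list(scenario = scenario, n_samples = as.integer(n_samples),
                 genes = genes, template = template, mean = mean,
                 variance = variance, clamp = clamp, seed = seed),
            class = "cohort_spec")
}

#' Generate a simulated cohort
#'
#' @param spec A [cohort_spec()].
#' @return Genes x samples numeric matrix; identical for identical specs
#'   (including seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  with_rng_seed(spec$seed, {
    m <- switch(spec$scenario,
      flat_normal = {
        g <- spec$genes
        matrix(rnorm(length(g) * n, mean = spec$mean,
                     sd = sqrt(spec$variance)),
               nrow = length(g), ncol = n,
               dimnames = list(g, sprintf("S%03d", seq_len(n))))
      },
      gene_wise_normal = {
        tm <- spec$template
        mu <- rowMeans(tm)
        v <- apply(tm, 1L, var)
        if (any(v <= 0)) {
          stop("template contains constant gene(s): per-gene variance ",
               "must be positive")
        }
        matrix(rnorm(nrow(tm) * n, mean = rep(mu, times = n),
                     sd = rep(sqrt(v), times = n)),
               nrow = nrow(tm), ncol = n,
               dimnames = list(rownames(tm), sprintf("S%03d", seq_len(n))))
      },
      empirical_resample = {
        tm <- spec$template
        cols <- sample.int(ncol(tm), n, replace = TRUE)
        out <- tm[, cols, drop = FALSE]
        colnames(out) <- sprintf("S%03d", seq_len(n))
        out
      })
    if (spec$clamp) m <- clamp01(m)
    m
  })
}

#' Generate a random synthetic pathway
#'
#' Builds a connected directed graph on `n_nodes` nodes: a random backbone
#' in which every node is reachable from node 1 (the guaranteed receptor),
#' extra forward edges, an optional set of feedback edges creating cycles,
#' and a requested fraction of inhibition edges. The last node never gains
#' outgoing edges, so at least one effector always exists. Deterministic
#' given the seed.
#'
#' @param n_nodes Number of nodes (>= 3; >= 4 when `loop_fraction > 0`).
#' @param loop_fraction Feedback edges added as a fraction of the forward
#'   edge count.
#' @param inhibition_fraction Fraction of edges labelled inhibition.
#' @param gene_ids Optional pool of gene ids to draw node genes from
#'   (without replacement); defaults to `"<pathway_id>_g<i>"`.
#' @param pathway_id Pathway identifier.
#' @param extra_edge_fraction Additional forward edges as a fraction of
#'   `n_nodes`.
#' @param seed Optional integer seed.
#' @return A `pathway` with one gene per (plain) node.
#' @export
generate_synthetic_pathway <- function(n_nodes, loop_fraction = 0,
                                       inhibition_fraction = 0,
                                       gene_ids = NULL,
                                       pathway_id = "synthetic",
                                       extra_edge_fraction = 0.4,
                                       seed = NULL) {
  stopifnot(n_nodes >= 3)
  if (inhibition_fraction < 0 || inhibition_fraction > 1) {
    stop("infeasible inhibition_fraction: must be in [0, 1]")
  }
  if (loop_fraction < 0 || loop_fraction > 1) {
    stop("infeasible loop_fraction: must be in [0, 1]")
  }
  if (loop_fraction > 0 && n_nodes < 4) {
    stop("feedback edges need at least 4 nodes")
  }
  with_rng_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n_nodes))
    if (is.null(gene_ids)) {
      genes <- sprintf("%s_g%02d", pathway_id, seq_len(n_nodes))
    } else {
      if (length(gene_ids) < n_nodes) {
        stop("gene_ids pool smaller than n_nodes")
      }
      genes <- sample(gene_ids, n_nodes)
    }
    # backbone: each node wired from a random earlier node => everything
    # reachable from node 1 and node 1 stays in-degree 0
    src <- vapply(2:n_nodes, function(j) sample.int(j - 1L, 1L), integer(1))
    edges <- data.frame(source = ids[src], target = ids[2:n_nodes],
                        stringsAsFactors = FALSE)
    n_extra <- round_half_up(extra_edge_fraction * n_nodes)
    tries <- 0L
    while (n_extra > 0L && tries < 50L * n_nodes) {
      tries <- tries + 1L
      j <- sample(2:n_nodes, 1L)
      i <- sample.int(j - 1L, 1L)
      cand <- c(ids[i], ids[j])
      if (!any(edges$source == cand[1] & edges$target == cand[2])) {
        edges <- rbind(edges, data.frame(source = cand[1], target = cand[2],
                                         stringsAsFactors = FALSE))
        n_extra <- n_extra - 1L
      }
    }
    # feedback edges among interior nodes: j -> i with 2 <= i < j <= n-1
    n_back <- if (loop_fraction > 0) {
      max(1L, round_half_up(loop_fraction * nrow(edges)))
    } else 0L
    tries <- 0L
    while (n_back > 0L && tries < 50L * n_nodes) {
      tries <- tries + 1L
      j <- sample(3:(n_nodes - 1L), 1L)
      i <- sample(2:(j - 1L), 1L)
      cand <- c(ids[j], ids[i])
      if (!any(edges$source == cand[1] & edges$target == cand[2])) {
        edges <- rbind(edges, data.frame(source = cand[1], target = cand[2],
                                         stringsAsFactors = FALSE))
        n_back <- n_back - 1L
      }
    }
    n_inh <- round_half_up(inhibition_fraction * nrow(edges))
    edges$sign <- "activation"
    if (n_inh > 0L) {
      edges$sign[sample.int(nrow(edges), n_inh)] <- "inhibition"
    }
    nodes <- data.frame(node_id = ids, node_type = "plain",
                        stringsAsFactors = FALSE)
    nodes$genes <- as.list(genes)
    new_pathway(pathway_id, sprintf("synthetic pathway %s", pathway_id),
                nodes, edges)
  })
}

#' Multiply selected genes in selected samples (signal injection)
#'
#' Used by the sensitivity protocol: a multiplicative fold-change applied to
#' one circuit's member genes in the case samples, before unit scaling,
#' mimics coordinated differential expression.
#'
#' @param m Genes x samples matrix.
#' @param genes Genes to perturb (silently intersected with rownames).
#' @param samples Samples to perturb; defaults to all columns.
#' @param fold Multiplicative fold-change (default 1.5).
#' @return Perturbed copy of `m`.
#' @export
inject_signal <- function(m, genes, samples = colnames(m), fold = 1.5) {
  g <- intersect(genes, rownames(m))
  s <- intersect(samples, colnames(m))
  m[g, s] <- m[g, s] * fold
  m
}

# Shared inner pipeline: matrix in [0,1] (or raw if scale = TRUE) + groups
# -> circuit-level differential table.
differential_circuits <- function(pathways, m, design, scale = FALSE,
                                  cfg = propagation_config()) {
  res <- circuit_activity(pathways, m, scale = scale, cfg = cfg)
  list(results = compare_groups(res$circuit, design),
       metadata = activity_metadata(res$circuit))
}

#' Estimate the false positive rate on homogeneous cohorts
#'
#' The specificity protocol: repeatedly generate a cohort in which no group
#' structure exists, split it randomly in half, run the full pipeline
#' (node summarization, propagation, per-circuit Wilcoxon + BH), and count
#' circuits called significant. Any call is a false positive, so the mean
#' fraction of significant circuits across repetitions estimates the FPR.
#'
#' @param pathways A `pathway` or list of pathways.
#' @param spec A [cohort_spec()] with an even `n_samples`; its `seed` field
#'   is ignored in favour of per-repetition seeds derived from `seed`.
#' @param repetitions Number of repetitions (>= 1).
#' @param alpha Significance level on the BH-adjusted p-values.
#' @param seed Base seed; repetition r uses `seed + r`.
#' @return Object of class `ccaa_benchmark` with the per-repetition
#'   fractions, the mean FPR estimate and an exact binomial confidence
#'   interval on the pooled counts.
#' @export
estimate_fpr <- function(pathways, spec, repetitions = 100L, alpha = 0.05,
                         seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), repetitions >= 1)
  if (spec$n_samples %% 2L != 0L) {
    stop("spec$n_samples must be even (cohort is split in half)")
  }
  pathways <- as_pathway_list(pathways)
  half <- spec$n_samples / 2L
  per_rep <- numeric(repetitions)
  n_circuits <- NA_integer_
  total_sig <- 0L
  for (r in seq_len(repetitions)) {
    rep_spec <- spec
    rep_spec$seed <- NULL
    frac <- with_rng_seed(seed + r, {
      m <- generate_cohort(rep_spec)
      grp <- rep("B", spec$n_samples)
      grp[sample.int(spec$n_samples, half)] <- "A"
      design <- group_design(colnames(m), grp, reference = "A")
      differential_circuits(pathways, m, design)$results
    })
    n_circuits <- nrow(frac)
    sig <- sum(frac$fdr < alpha)
    total_sig <- total_sig + sig
    per_rep[r] <- sig / n_circuits
  }
  ci <- stats::binom.test(total_sig, repetitions * n_circuits)$conf.int
  structure(list(metric = "FPR", repetitions = repetitions,
                 per_repetition = per_rep, estimate = mean(per_rep),
                 conf_int = as.numeric(ci), alpha = alpha,
                 n_circuits = n_circuits,
                 config = list(scenario = spec$scenario,
                               n_samples = spec$n_samples,
                               n_genes = length(spec$genes %||%
                                                  rownames(spec$template)),
                               mean = spec$mean, variance = spec$variance,
                               seed = seed)),
            class = "ccaa_benchmark")
}

#' Estimate the true positive rate on a case/control comparison
#'
#' The sensitivity protocol: run the pipeline on case versus control
#' expression matrices and score, for each designated pathway, whether at
#' least one of its circuits is differentially activated at the given FDR
#' level. The TPR is the fraction of designated pathways detected.
#'
#' @param pathways A `pathway` or list of pathways.
#' @param case_matrix,control_matrix Genes x samples matrices on the same
#'   gene universe; sample ids must not overlap.
#' @param cancer_pathway_ids Non-empty subset of the supplied pathway ids in
#'   which differential activation is expected.
#' @param alpha FDR threshold.
#' @param scale Unit-scale the combined matrix first (default `TRUE`;
#'   injected fold-changes are specified pre-scaling).
#' @param cfg A [propagation_config()].
#' @return A `ccaa_benchmark` with the TPR estimate, per-pathway detection
#'   table and the full differential table.
#' @export
estimate_tpr <- function(pathways, case_matrix, control_matrix,
                         cancer_pathway_ids, alpha = 0.05, scale = TRUE,
                         cfg = propagation_config()) {
  pathways <- as_pathway_list(pathways)
  if (length(cancer_pathway_ids) == 0L) {
    stop("cancer_pathway_ids must not be empty")
  }
  missing <- setdiff(cancer_pathway_ids, names(pathways))
  if (length(missing)) {
    stop("cancer_pathway_ids not among supplied pathways: ",
         paste(missing, collapse = ", "))
  }
  if (length(intersect(colnames(case_matrix), colnames(control_matrix)))) {
    stop("case and control matrices share sample ids")
  }
  common <- intersect(rownames(case_matrix), rownames(control_matrix))
  m <- cbind(case_matrix[common, , drop = FALSE],
             control_matrix[common, , drop = FALSE])
  design <- group_design(
    colnames(m),
    rep(c("case", "control"), c(ncol(case_matrix), ncol(control_matrix))),
    reference = "control")
  dc <- differential_circuits(pathways, m, design, scale = scale, cfg = cfg)
  res <- merge(dc$results, dc$metadata[, c("feature", "pathway_id")],
               by = "feature")
  hit <- vapply(cancer_pathway_ids, function(pid) {
    any(res$fdr[res$pathway_id == pid] < alpha)
  }, logical(1))
  structure(list(metric = "TPR", repetitions = 1L,
                 per_repetition = mean(hit), estimate = mean(hit),
                 conf_int = as.numeric(
                   stats::binom.test(sum(hit), length(hit))$conf.int),
                 alpha = alpha,
                 detected = data.frame(pathway_id = cancer_pathway_ids,
                                       detected = unname(hit)),
                 results = res,
                 config = list(n_case = ncol(case_matrix),
                               n_control = ncol(control_matrix),
                               scale = scale)),
            class = "ccaa_benchmark")
}

#' @export
print.ccaa_benchmark <- function(x, ...) {
  cat("ccaa_benchmark [", x$metric, "]\n",
      "  estimate: ", format(x$estimate, digits = 4),
      "  (95% CI ", format(x$conf_int[1], digits = 3), " - ",
      format(x$conf_int[2], digits = 3), ")\n",
      "  repetitions: ", x$repetitions,
      ", alpha: ", x$alpha, "\n", sep = "")
  invisible(x)
}
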