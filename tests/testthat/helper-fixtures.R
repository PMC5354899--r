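# Shared fixtures and independent oracles, all built in code.

make_pathway <- function(id, node_ids, genes, edges,
                         types = rep("plain", length(node_ids))) {
  nodes <- data.frame(node_id = node_ids, node_type = types,
                      stringsAsFactors = FALSE)
  nodes$genes <- genes
  new_pathway(id, nodes = nodes, edges = edges)
}

edge_df <- function(source, target, sign = "activation") {
  data.frame(source = source, target = target,
             sign = rep(sign, length.out = length(source)),
             stringsAsFactors = FALSE)
}

# A -> B -> C, activations
chain_pathway <- function(id = "chain") {
  make_pathway(id, c("A", "B", "C"), as.list(c("gA", "gB", "gC")),
               edge_df(c("A", "B"), c("B", "C")))
}

# A -> B -> D, A -> C -> D
diamond_pathway <- function(id = "diamond") {
  make_pathway(id, c("A", "B", "C", "D"),
               as.list(c("gA", "gB", "gC", "gD")),
               edge_df(c("A", "A", "B", "C"), c("B", "C", "D", "D")))
}

# A -> C <- B (two receptors, one effector)
vee_pathway <- function(id = "vee") {
  make_pathway(id, c("A", "B", "C"), as.list(c("gA", "gB", "gC")),
               edge_df(c("A", "B"), c("C", "C")))
}

# A -> B -> C with C -| B (negative feedback on the read-out's input)
feedback_circuit <- function() {
  p <- make_pathway("fb", c("A", "B", "C"), as.list(c("gA", "gB", "gC")),
                    edge_df(c("A", "B", "C"), c("B", "C", "B"),
                            c("activation", "activation", "inhibition")))
  manual_circuit(p, "A", "C")
}

# Random acyclic pathway drawn from the package generator; every canonical
# circuit of it is a DAG usable for oracle-equivalence checks.
random_dag_circuits <- function(seed, n_nodes = NULL) {
  n <- n_nodes %||% sample(5:25, 1L)
  p <- generate_synthetic_pathway(n, loop_fraction = 0,
                                  inhibition_fraction = 0.25,
                                  pathway_id = sprintf("rand%d", seed),
                                  seed = seed)
  decompose_circuits(p)$circuits
}

random_node_values <- function(circuit) {
  setNames(runif(length(circuit$nodes)), circuit$nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent reachability oracle: plain adjacency-list BFS, no igraph.
bfs_reachable <- function(edges, from, forward = TRUE) {
  adj <- if (forward) split(edges$target, edges$source) else
    split(edges$source, edges$target)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# Brute-force log-rank oracle: explicit 2x2 tables at each event time.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("a", "b"), c(length(time_a), length(time_b)))
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n_a <- sum(time >= t & grp == "a")
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == "a")
    o <- o + d_a
    e <- e + d * n_a / n
    if (n > 1) v <- v + d * n_a * (n - n_a) * (n - d) / (n^2 * (n - 1))
  }
  stat <- (o - e)^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Kaplan-Meier closed-form oracle at one time point.
km_oracle_at <- function(time, event, t0) {
  s <- 1
  for (t in sort(unique(time[event == 1 & time <= t0]))) {
    s <- s * (1 - sum(time == t & event == 1) / sum(time >= t))
  }
  s
}

write_json_pathway <- function(p, path) {
  doc <- list(
    pathway_id = p$pathway_id, name = p$name,
    nodes = lapply(p$node_ids, function(nd) {
      list(id = nd, genes = as.list(p$node_genes[[nd]]),
           type = unname(p$node_type[[nd]]))
    }),
    edges = lapply(seq_len(nrow(p$edges)), function(i) {
      as.list(p$edges[i, ])
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

# Minimal KGML document: 3 gene entries, 1 group (complex of 2 genes), and
# relations covering activation, expression, inhibition and an unsigned
# binding/association.
kgml_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:test01" title="Test pathway">',
    '  <entry id="1" name="hsa:10 hsa:11" type="gene"/>',
    '  <entry id="2" name="hsa:20" type="gene"/>',
    '  <entry id="3" name="hsa:30" type="gene"/>',
    '  <entry id="4" name="undefined" type="group">',
    '    <component id="2"/>',
    '    <component id="3"/>',
    '  </entry>',
    '  <entry id="9" name="cpd:C00165" type="compound"/>',
    '  <relation entry1="1" entry2="2" type="PPrel">',
    '    <subtype name="activation" value="--&gt;"/>',
    '  </relation>',
    '  <relation entry1="2" entry2="3" type="GErel">',
    '    <subtype name="expression" value="--&gt;"/>',
    '  </relation>',
    '  <relation entry1="1" entry2="4" type="PPrel">',
    '    <subtype name="inhibition" value="--|"/>',
    '  </relation>',
    '  <relation entry1="2" entry2="4" type="PPrel">',
    '    <subtype name="binding/association" value="---"/>',
    '  </relation>',
    '</pathway>'), path)
  path
}

write_gmt <- function(lines, path) {
  writeLines(lines, path)
  path
}

vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene">',
    '##INFO=<ID=CSQT,Number=1,Type=String,Description="Consequence">',
    '##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT score">',
    '##INFO=<ID=POLYPHEN,Number=1,Type=Float,Description="PolyPhen score">',
    '##INFO=<ID=PHASTCONS,Number=1,Type=Float,Description="phastCons">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", ".", "A", "T", "50", "PASS",
          "GENE=gA;CSQT=stop_gain;PHASTCONS=0.99", "GT", "0/1", "0/0",
          sep = "\t"),
    paste("1", "200", ".", "C", "G", "50", "PASS",
          "GENE=gB;CSQT=missense;SIFT=0.01;PHASTCONS=0.99", "GT", "1/1",
          "0/1", sep = "\t"),
    paste("1", "300", ".", "G", "A", "50", "PASS",
          "GENE=gC;CSQT=missense;SIFT=0.80;PHASTCONS=0.10", "GT", "0/1",
          "0/1", sep = "\t")), path)
  path
}
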