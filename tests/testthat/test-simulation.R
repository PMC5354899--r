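test_that("flat-normal cohorts hit their stated mean and are reproducible", {
  spec <- cohort_spec("flat_normal", 20, genes = 1000, seed = 61)
  m <- generate_cohort(spec)
  expect_equal(dim(m), c(1000L, 20L))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(abs(colMeans(m) - 0.5) < 0.05))
  # same spec -> identical matrix; different seed -> different draw
  expect_identical(generate_cohort(spec), m)
  spec2 <- cohort_spec("flat_normal", 20, genes = 1000, seed = 62)
  expect_false(identical(generate_cohort(spec2), m))
})

test_that("gene-wise scenario follows the template moments and guards
           degenerate variance", {
  set.seed(63)
  template <- matrix(rnorm(50 * 30, mean = rep(1:50, 30), sd = 0.5),
                     nrow = 50, dimnames = list(sprintf("g%d", 1:50),
                                                sprintf("t%d", 1:30)))
  spec <- cohort_spec("gene_wise_normal", 500, template = template,
                      clamp = FALSE, seed = 64)
  m <- generate_cohort(spec)
  expect_true(all(abs(rowMeans(m) - rowMeans(template)) < 0.2))
  # constant template gene -> error (variance must be positive)
  template[1, ] <- 7
  specc <- cohort_spec("gene_wise_normal", 10, template = template,
                       seed = 64)
  expect_error(generate_cohort(specc), "variance")
  expect_error(cohort_spec("flat_normal", 10, genes = 5, variance = 0),
               "variance")
  expect_error(cohort_spec("gene_wise_normal", 10), "template")
})

test_that("empirical resampling draws template columns", {
  template <- matrix(runif(20), nrow = 4,
                     dimnames = list(sprintf("g%d", 1:4),
                                     sprintf("t%d", 1:5)))
  spec <- cohort_spec("empirical_resample", 8, template = template,
                      seed = 65)
  m <- generate_cohort(spec)
  expect_equal(dim(m), c(4L, 8L))
  # every drawn column is one of the template columns
  for (j in seq_len(ncol(m))) {
    expect_true(any(apply(template, 2, function(tc) all(tc == m[, j]))))
  }
})

test_that("synthetic pathways are connected, decomposable and seeded", {
  p <- generate_synthetic_pathway(5, seed = 66)
  term <- identify_terminals(p)
  expect_gte(length(term$receptors), 1L)
  expect_gte(length(term$effectors), 1L)
  dec <- decompose_circuits(p)
  expect_gte(length(dec$circuits), 1L)
  g <- igraph::graph_from_data_frame(p$edges[, 1:2])
  expect_true(igraph::is_dag(g))  # loop_fraction 0 -> acyclic

  pl <- generate_synthetic_pathway(15, loop_fraction = 0.2, seed = 67)
  gl <- igraph::graph_from_data_frame(pl$edges[, 1:2])
  expect_false(igraph::is_dag(gl))  # feedback requested -> cycle present

  pi <- generate_synthetic_pathway(15, inhibition_fraction = 0.4, seed = 68)
  expect_equal(sum(pi$edges$sign == "inhibition"),
               round(0.4 * nrow(pi$edges)))

  expect_identical(generate_synthetic_pathway(10, seed = 69),
                   generate_synthetic_pathway(10, seed = 69))
  expect_false(identical(generate_synthetic_pathway(10, seed = 69)$edges,
                         generate_synthetic_pathway(10, seed = 70)$edges))
  expect_error(generate_synthetic_pathway(10, inhibition_fraction = 1.5),
               "infeasible")
  expect_error(generate_synthetic_pathway(3, loop_fraction = 0.5),
               "at least 4 nodes")
})

test_that("estimate_fpr is seeded, bounded and nulls out constant cohorts", {
  genes <- sprintf("G%03d", 1:120)
  p <- generate_synthetic_pathway(8, inhibition_fraction = 0.25,
                                  gene_ids = genes, seed = 71)
  spec <- cohort_spec("flat_normal", 12, genes = genes)
  r1 <- estimate_fpr(p, spec, repetitions = 4, seed = 5)
  r2 <- estimate_fpr(p, spec, repetitions = 4, seed = 5)
  expect_identical(r1$per_repetition, r2$per_repetition)
  expect_true(all(r1$per_repetition >= 0 & r1$per_repetition <= 1))
  expect_error(estimate_fpr(p, cohort_spec("flat_normal", 11, genes = genes),
                            repetitions = 2),
               "even")

  # constant cohorts (resampled from a constant template) can never yield a
  # significant circuit
  template <- matrix(0.5, nrow = length(genes), ncol = 6,
                     dimnames = list(genes, sprintf("t%d", 1:6)))
  specc <- cohort_spec("empirical_resample", 12, template = template)
  rc <- estimate_fpr(p, specc, repetitions = 3, seed = 5)
  expect_equal(rc$estimate, 0)
})

test_that("injected fold-changes are recovered by estimate_tpr", {
  genes <- sprintf("G%03d", 1:150)
  pathways <- lapply(1:3, function(i) {
    generate_synthetic_pathway(10, inhibition_fraction = 0.2,
                               gene_ids = genes,
                               pathway_id = sprintf("SP%d", i),
                               seed = 80 + i)
  })
  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  case <- generate_cohort(cohort_spec("flat_normal", 60, genes = genes,
                                      seed = 91))
  colnames(case) <- paste0("case_", colnames(case))
  ctrl <- generate_cohort(cohort_spec("flat_normal", 60, genes = genes,
                                      seed = 92))
  colnames(ctrl) <- paste0("ctrl_", colnames(ctrl))
  # inject into the first two pathways only
  for (p in pathways[1:2]) {
    circ <- decompose_circuits(p)$circuits[[1]]
    case <- inject_signal(case,
                          unique(unlist(circ$node_genes, use.names = FALSE)),
                          fold = 1.5)
  }
  # designated list includes one untouched pathway -> TPR = 2/3
  rep_all <- estimate_tpr(pathways, case, ctrl, cancer_pathway_ids = ids)
  expect_equal(rep_all$estimate, 2 / 3)
  rep_hit <- estimate_tpr(pathways, case, ctrl,
                          cancer_pathway_ids = ids[1:2])
  expect_equal(rep_hit$estimate, 1)
  # case == control -> nothing to find
  rep_null <- estimate_tpr(pathways, case[, 1:30],
                           `colnames<-`(case[, 31:60],
                                        paste0("x_", 31:60)),
                           cancer_pathway_ids = ids)
  expect_equal(rep_null$estimate, 0)
  expect_error(estimate_tpr(pathways, case, ctrl,
                            cancer_pathway_ids = character(0)),
               "empty")
  expect_error(estimate_tpr(pathways, case, ctrl,
                            cancer_pathway_ids = "GHOST"),
               "not among")
})
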