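test_that("hand-evaluated propagation fixtures are reproduced", {
  # single receptor: virtual incoming signal of 1 makes S = v
  p1 <- make_pathway("p1", "A", list("gA"),
                     edge_df(character(0), character(0)))
  c1 <- manual_circuit(p1, "A", "A")
  expect_equal(unname(effector_signal(propagate(c1, c(A = 0.7)))), 0.7)

  # chain: S_B = v_B * (1 - (1 - S_A))
  ch <- decompose_circuits(chain_pathway())$circuits[[1]]
  st <- propagate(ch, c(A = 1, B = 0.5, C = 1))
  expect_equal(unname(st$signal["B", 1]), 0.5)
  expect_equal(unname(effector_signal(st)), 0.5)

  # converging activations combine as 1 - prod(1 - s_a)
  ve <- decompose_circuits(vee_pathway())$effector_circuits[[1]]
  expect_equal(unname(effector_signal(propagate(ve, c(A = 0.5, B = 0.5,
                                                      C = 1)))),
               0.75)

  # full inhibition zeroes the node
  pi <- make_pathway("pi", c("A", "I", "B"), as.list(c("gA", "gI", "gB")),
                     edge_df(c("A", "I"), c("B", "B"),
                             c("activation", "inhibition")))
  ci <- manual_circuit(pi, c("A", "I"), "B")
  expect_equal(unname(effector_signal(propagate(ci, c(A = 1, I = 1,
                                                      B = 0.8)))),
               0)
})

test_that("negative feedback converges to its analytic fixed point", {
  circ <- feedback_circuit()
  st <- propagate(circ, c(A = 1, B = 1, C = 0.5))
  expect_true(st$converged)
  expect_lt(abs(st$signal["B", 1] - 2 / 3), 1e-6)
  expect_lt(abs(st$signal["C", 1] - 1 / 3), 1e-6)
})

test_that("iterative propagation equals the topological oracle on DAGs", {
  set.seed(101)
  thr <- propagation_config()$convergence_threshold
  for (seed in 1:30) {
    for (circ in random_dag_circuits(seed)) {
      nv <- random_node_values(circ)
      a <- propagate(circ, nv)$signal
      b <- propagate_dag_oracle(circ, nv)$signal
      expect_lt(max(abs(a - b)), 10 * thr)
    }
  }
})

test_that("the DAG oracle refuses cyclic circuits and handles edge cases", {
  expect_error(propagate_dag_oracle(feedback_circuit(),
                                    c(A = 1, B = 1, C = 0.5)),
               "cyclic")
  # chain of 5 activations at v=1 transmits the full signal
  p <- make_pathway("c5", paste0("N", 1:5), as.list(paste0("g", 1:5)),
                    edge_df(paste0("N", 1:4), paste0("N", 2:5)))
  circ <- decompose_circuits(p)$circuits[[1]]
  v1 <- setNames(rep(1, 5), paste0("N", 1:5))
  expect_equal(unname(effector_signal(propagate_dag_oracle(circ, v1))), 1)
  # one dead node absorbs everything downstream
  v0 <- v1
  v0["N3"] <- 0
  st <- propagate_dag_oracle(circ, v0)
  expect_equal(unname(st$signal[c("N3", "N4", "N5"), 1]), c(0, 0, 0))
})

test_that("signals stay in [0,1] on random loopy topologies", {
  set.seed(202)
  for (seed in 1:15) {
    p <- generate_synthetic_pathway(sample(5:30, 1), loop_fraction = 0.2,
                                    inhibition_fraction = 0.4, seed = seed)
    term <- identify_terminals(p)
    circ <- manual_circuit(p, term$receptors, sample(p$node_ids, 1))
    nv <- matrix(runif(length(p$node_ids) * 3),
                 nrow = length(p$node_ids),
                 dimnames = list(p$node_ids, c("s1", "s2", "s3")))
    st <- suppressWarnings(propagate(circ, nv))
    expect_true(all(st$signal >= 0 & st$signal <= 1))
  }
})

test_that("effector signal respects path-inhibition parity", {
  # even number of inhibitions: raising v upstream raises the effector
  p_even <- make_pathway("ev", c("A", "B", "C"), as.list(c("gA", "gB", "gC")),
                         edge_df(c("A", "B"), c("B", "C"),
                                 c("inhibition", "inhibition")))
  c_even <- manual_circuit(p_even, "A", "C")
  lo <- effector_signal(propagate(c_even, c(A = 0.2, B = 0.9, C = 0.9)))
  hi <- effector_signal(propagate(c_even, c(A = 0.8, B = 0.9, C = 0.9)))
  expect_gte(hi, lo)
  # odd number: raising v upstream lowers the effector
  p_odd <- make_pathway("od", c("A", "B", "C"), as.list(c("gA", "gB", "gC")),
                        edge_df(c("A", "B"), c("B", "C"),
                                c("activation", "inhibition")))
  c_odd <- manual_circuit(p_odd, "A", "C")
  lo <- effector_signal(propagate(c_odd, c(A = 0.2, B = 0.9, C = 0.9)))
  hi <- effector_signal(propagate(c_odd, c(A = 0.8, B = 0.9, C = 0.9)))
  expect_lte(hi, lo)
})

test_that("converged state does not depend on worklist ordering", {
  set.seed(303)
  circ <- feedback_circuit()
  nv <- c(A = 1, B = 1, C = 0.5)
  ref <- propagate(circ, nv)$signal
  for (i in 1:5) {
    st <- propagate(circ, nv, node_order = sample(circ$nodes))
    expect_equal(st$signal, ref, tolerance = 1e-5)
  }
  for (seed in 1:5) {
    for (dag in random_dag_circuits(seed, n_nodes = 10)) {
      nv <- random_node_values(dag)
      ref <- propagate(dag, nv)$signal
      st <- propagate(dag, nv, node_order = sample(dag$nodes))
      expect_equal(st$signal, ref, tolerance = 1e-5)
    }
  }
})

test_that("genuine oscillation triggers the configured policy", {
  # an odd-length inhibition cycle at v = 1 behaves like a ring of
  # negations: the signal flips between 0 and 1 forever
  p <- make_pathway("osc", c("A", "B", "C", "D"),
                    as.list(c("gA", "gB", "gC", "gD")),
                    edge_df(c("A", "B", "C", "D"), c("B", "C", "D", "B"),
                            c("activation", "inhibition", "inhibition",
                              "inhibition")))
  circ <- manual_circuit(p, "A", "D")
  nv <- c(A = 1, B = 1, C = 1, D = 1)
  expect_warning(st <- propagate(circ, nv), "did not converge")
  expect_false(st$converged)
  expect_error(propagate(circ, nv,
                         propagation_config(non_convergence = "error")),
               "oscillating")
})

test_that("node-value domain is validated", {
  ch <- decompose_circuits(chain_pathway())$circuits[[1]]
  expect_error(propagate(ch, c(A = 1, B = 1.2, C = 1)), "\\[0, 1\\]")
  expect_error(propagate(ch, c(A = 1, B = 1)), "missing")
  st <- propagate(ch, c(A = 1, B = 1, C = 1))
  expect_error(effector_signal(st, "Z"), "unknown node")
})
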