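test_that("native JSON pathways round-trip through load_pathway", {
  p <- chain_pathway()
  f <- withr::local_tempfile(fileext = ".json")
  write_json_pathway(p, f)
  q <- load_pathway(f, "native_json")
  expect_equal(q$pathway_id, "chain")
  expect_equal(q$node_ids, c("A", "B", "C"))
  expect_equal(q$node_genes, p$node_genes)
  expect_equal(nrow(q$edges), 2L)
  expect_true(all(q$edges$sign == "activation"))
})

test_that("malformed pathway files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pathway_id = "bad",
                            nodes = list(list(id = "A", genes = list("gA"),
                                              type = "plain")),
                            edges = list(list(source = "A", target = "Z",
                                              sign = "activation"))),
                       f, auto_unbox = TRUE)
  expect_error(load_pathway(f, "native_json"), "unknown node.*Z")
  writeLines("{not json", f)
  expect_error(load_pathway(f, "native_json"), "cannot parse")
  expect_error(load_pathway("/nonexistent/p.json", "native_json"),
               "not found")
})

test_that("KGML subtypes map to signs, unsigned relations are dropped", {
  f <- withr::local_tempfile(fileext = ".xml")
  kgml_fixture(f)
  expect_warning(p <- load_pathway(f, "kgml"), "binding/association")
  expect_equal(sort(p$node_ids), c("1", "2", "3", "4"))
  expect_equal(unname(p$node_type[c("1", "4")]), c("plain", "complex"))
  expect_setequal(p$node_genes[["1"]], c("hsa:10", "hsa:11"))
  expect_setequal(p$node_genes[["4"]], c("hsa:20", "hsa:30"))
  sgn <- setNames(p$edges$sign, paste(p$edges$source, p$edges$target))
  expect_equal(unname(sgn["1 2"]), "activation")
  expect_equal(unname(sgn["2 3"]), "activation")  # "expression" subtype
  expect_equal(unname(sgn["1 4"]), "inhibition")
  expect_equal(nrow(p$edges), 3L)  # binding relation not silently signed
})

test_that("receptors and effectors are the in-degree-0/out-degree-0 nodes", {
  term <- identify_terminals(chain_pathway())
  expect_equal(term, list(receptors = "A", effectors = "C"))
  term <- identify_terminals(diamond_pathway())
  expect_equal(term, list(receptors = "A", effectors = "D"))
  # pure 2-cycle: every node has both in- and out-edges
  cyc <- make_pathway("cyc", c("B", "C"), as.list(c("gB", "gC")),
                      edge_df(c("B", "C"), c("C", "B")))
  expect_equal(identify_terminals(cyc),
               list(receptors = character(0), effectors = character(0)))
  expect_error(decompose_circuits(cyc), "no receptor")
})

test_that("decomposition yields one circuit per connected pair", {
  dec <- decompose_circuits(chain_pathway())
  expect_length(dec$circuits, 1L)
  expect_length(dec$effector_circuits, 1L)
  expect_equal(dec$circuits[[1]]$nodes, c("A", "B", "C"))

  # two receptors converging: 2 canonical, 1 effector circuit with union
  dec <- decompose_circuits(vee_pathway())
  expect_length(dec$circuits, 2L)
  expect_equal(dec$circuits[["vee:A->C"]]$nodes, c("A", "C"))
  expect_equal(dec$circuits[["vee:B->C"]]$nodes, c("B", "C"))
  expect_length(dec$effector_circuits, 1L)
  expect_setequal(dec$effector_circuits[[1]]$nodes, c("A", "B", "C"))

  # diamond: parallel branches re-converge into ONE canonical circuit
  dec <- decompose_circuits(diamond_pathway())
  expect_length(dec$circuits, 1L)
  expect_setequal(dec$circuits[[1]]$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(dec$circuits[[1]]$edges), 4L)
})

test_that("decomposition is deterministic and satisfies the union and
           reachability invariants on random pathways", {
  for (seed in c(11L, 12L, 13L, 14L, 15L)) {
    p <- generate_synthetic_pathway(12, loop_fraction = 0.15,
                                    inhibition_fraction = 0.3, seed = seed)
    d1 <- decompose_circuits(p)
    d2 <- decompose_circuits(p)
    expect_identical(names(d1$circuits), names(d2$circuits))
    expect_identical(lapply(d1$circuits, `[[`, "nodes"),
                     lapply(d2$circuits, `[[`, "nodes"))
    # union property: effector circuit nodes == union of its canonical nodes
    for (ec in d1$effector_circuits) {
      members <- Filter(function(cc) cc$effector == ec$effector, d1$circuits)
      expect_setequal(ec$nodes,
                      unique(unlist(lapply(members, `[[`, "nodes"))))
    }
    # reachability: every member node on a directed route receptor->effector
    # (checked with an igraph-free BFS oracle)
    for (cc in d1$circuits) {
      fwd <- bfs_reachable(cc$edges, cc$receptors, forward = TRUE)
      bwd <- bfs_reachable(cc$edges, cc$effector, forward = FALSE)
      expect_setequal(cc$nodes, intersect(fwd, bwd))
    }
  }
})

test_that("GMT annotations load, reject duplicates, skip empty sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(c("F1\tdesc one\tG1\tG2", "F2\tdesc two\tG2\tG3\tG4"), f)
  ann <- load_function_annotations(f)
  expect_named(ann, c("F1", "F2"))
  expect_equal(ann$F1, c("G1", "G2"))
  expect_equal(attr(ann, "labels")[["F2"]], "desc two")

  write_gmt(c("F1\td\tG1", "F1\td\tG2"), f)
  expect_error(load_function_annotations(f), "duplicated function id")

  write_gmt(c("F1\td\tG1", "EMPTY\tno genes"), f)
  expect_warning(ann <- load_function_annotations(f), "no member genes")
  expect_named(ann, "F1")

  writeLines(character(0), f)
  expect_length(load_function_annotations(f), 0L)
})

test_that("effectors map to functions through shared genes", {
  p <- vee_pathway()  # effector C holds gene gC
  ann <- list(F1 = c("gC", "gX"), F2 = c("gA"), F3 = c("gZ"))
  m <- map_effectors_to_functions(p, ann)
  expect_equal(m, list(F1 = "vee:*->C"))  # F2 hits a receptor, not effector
  # two effectors sharing an annotated gene are both listed
  p2 <- make_pathway("p2", c("A", "B", "C"), list("gA", "gS", "gS"),
                     edge_df(c("A", "A"), c("B", "C")))
  m2 <- map_effectors_to_functions(p2, list(F = "gS"))
  expect_setequal(m2$F, c("p2:*->B", "p2:*->C"))
})

test_that("pathway validation catches structural violations", {
  expect_error(make_pathway("x", c("A", "A"), as.list(c("g1", "g2")),
                            edge_df("A", "A")), "duplicated node_id")
  expect_error(make_pathway("x", "A", list(character(0)),
                            edge_df(character(0), character(0))),
               "at least one gene")
  expect_error(make_pathway("x", c("A", "B"), as.list(c("g1", "g2")),
                            edge_df("A", "B", "maybe")), "sign")
})
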