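test_that("atom expression subsumption over the feature space", {
  expect_equal(atom_expr_subsumes("F,Cl,Br,I", "F"), "yes")
  expect_equal(atom_expr_subsumes("F", "F,Cl,Br,I"), "no")
  expect_equal(atom_expr_subsumes("C", "CX3"), "yes")
  expect_equal(atom_expr_subsumes("CX3", "C"), "no")
  expect_equal(atom_expr_subsumes("#6", "c"), "yes")    # any C >= aromatic C
  expect_equal(atom_expr_subsumes("c", "#6"), "no")
  expect_equal(atom_expr_subsumes("!F", "Cl"), "yes")
  # recursive environments: opaque, identical text only
  expect_equal(atom_expr_subsumes("$(C=O)", "$(C=N)"), "unknown")
  expect_equal(atom_expr_subsumes("$(C=O)", "$(C=O)"), "yes")
})

test_that("pattern subsumption: the trihalide/trifluoromethyl pair", {
  tri <- "[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]"
  tfm <- "[CX4](F)(F)F"
  expect_equal(pattern_subsumes(tri, tfm), "yes")
  expect_equal(pattern_subsumes(tfm, tri), "no")
  expect_equal(pattern_subsumes(tfm, tfm), "yes")
  # an amide is found in every lactam, but not conversely
  expect_equal(pattern_subsumes("[CX3](=[OX1])[NX3]",
                                "[CX3;R](=[OX1])[NX3;R]"), "yes")
  expect_equal(pattern_subsumes("[CX3;R](=[OX1])[NX3;R]",
                                "[CX3](=[OX1])[NX3]"), "no")
  # recursive environments block a decision
  expect_equal(pattern_subsumes("[CX3]=[OX1]",
                                "[CX3H1;$([CX3H1](=[OX1])[#6])]=[OX1]"),
               "unknown")
})

test_that("build_hierarchy produces exactly the expected edges", {
  col <- tiny_collection(list(
    c("trifluoromethyl", "[CX4](F)(F)F", "functional_group"),
    c("trihalide", "[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]", "functional_group")))
  h <- build_hierarchy(col)
  expect_equal(nrow(h$edges), 1)
  expect_equal(h$edges$general, "02-trihalide")
  expect_equal(h$edges$specific, "01-trifluoromethyl")

  col2 <- tiny_collection(list(
    c("benzene", "c1ccccc1", "cyclic"),
    c("pyridine", "c1ccncc1", "cyclic")))
  expect_equal(nrow(build_hierarchy(col2)$edges), 0)

  # equivalent patterns are merged with a warning, not edged
  col3 <- tiny_collection(list(
    c("hydroxyl", "[OX2H]", "functional_group"),
    c("hydroxy", "[OX2H1]", "functional_group")))
  expect_warning(h3 <- build_hierarchy(col3), "equivalent")
  expect_equal(nrow(h3$edges), 0)
  expect_length(h3$equivalence_classes, 1)
})

test_that("decided subsumption is transitive and acyclic on the seed", {
  h <- seed_hierarchy()
  e <- h$edges
  expect_gt(nrow(e), 0)
  # no two-cycles
  expect_false(any(paste(e$general, e$specific) %in% paste(e$specific, e$general)))
  # transitively closed: composing two edges stays inside the edge set
  for (i in seq_len(nrow(e))) {
    nxt <- e$specific[e$general == e$specific[i]]
    if (length(nxt) > 0)
      expect_true(all(paste(e$general[i], nxt) %in% paste(e$general, e$specific)))
  }
  g <- igraph::graph_from_data_frame(e)
  expect_true(igraph::is_dag(g))
})

test_that("hierarchy serialization round-trips", {
  h <- build_hierarchy(tiny_collection(list(
    c("trifluoromethyl", "[CX4](F)(F)F", "functional_group"),
    c("trihalide", "[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]", "functional_group"))))
  f <- withr::local_tempfile(fileext = ".json")
  save_hierarchy(h, f)
  back <- load_hierarchy(f)
  expect_equal(back$edges, h$edges)
})

test_that("corpus audit is clean on sound edges and catches planted ones", {
  pats <- seed_pattern_collection()
  corpus <- lapply(toy_corpus(11, 4), `[[`, "record")
  aud <- corpus_subsumption_audit(pats, corpus, seed_hierarchy())
  expect_equal(nrow(aud$violations), 0)
  expect_gt(aud$n_checked, 0)

  # a deliberately false edge (benzene "subsumes" pyridine) must surface
  ids <- vapply(pats$patterns, function(p) p$id, character(1))
  bz <- ids[grep("-benzene$", ids)]; py <- ids[grep("-pyridine$", ids)]
  fake <- structure(list(
    edges = data.frame(general = bz, specific = py, stringsAsFactors = FALSE),
    equivalence_classes = list(), ids = ids), class = "ca_hierarchy")
  aud2 <- corpus_subsumption_audit(pats, corpus, fake)
  expect_gt(nrow(aud2$violations), 0)

  empty <- structure(list(edges = data.frame(general = character(0),
                                             specific = character(0)),
                          equivalence_classes = list(), ids = ids),
                     class = "ca_hierarchy")
  expect_equal(nrow(corpus_subsumption_audit(pats, corpus, empty)$violations), 0)
})
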