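seed_ann <- function(smiles, name = NA_character_) {
  annotate_molecule(parse_smiles(smiles, name = name),
                    seed_pattern_collection(), seed_hierarchy())
}

test_that("containment: larger matches hide the substructures they cover", {
  ann <- seed_ann("c1ncc2[nH]cnc2n1", "purine")
  pur <- match_by_name(ann, "purine")
  imi <- match_by_name(ann, "imidazole")
  ov <- match_overshadows(pur, imi, seed_hierarchy())
  expect_true(ov$overshadows)
  expect_equal(ov$reason, "match_containment")
  expect_false(match_overshadows(imi, pur, seed_hierarchy())$overshadows)

  # disjoint matches never overshadow
  ann2 <- seed_ann("c1ccccc1-c1ccccc1")
  bzs <- Filter(function(m) m$pattern_name == "benzene", ann2$matches)
  expect_false(match_overshadows(bzs[[1]], bzs[[2]], seed_hierarchy())$overshadows)
})

test_that("equal atoms, fewer bonds: the monocycle yields to the bicycle", {
  col <- tiny_collection(list(
    c("hydrindane", "C1CCC2CCCC2C1", "cyclic"),
    c("cyclononane", "C1CCCCCCCC1", "cyclic")))
  h <- build_hierarchy(col)
  ann <- annotate_molecule(parse_smiles("C1CCC2CCCC2C1"), col, h)
  expect_equal(visible_names(ann), "hydrindane")
  cn <- match_by_name(ann, "cyclononane")
  expect_equal(cn$suppression, "fewer_bonds")
  expect_equal(sort(cn$atom_indices),
               sort(match_by_name(ann, "hydrindane")$atom_indices))
  expect_equal(nrow(cn$bonds), 9)
  expect_equal(nrow(match_by_name(ann, "hydrindane")$bonds), 10)
})

test_that("equal size: the hierarchy hides the less specific pattern", {
  col <- tiny_collection(list(
    c("trifluoromethyl", "[CX4](F)(F)F", "functional_group"),
    c("trihalide", "[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]", "functional_group"),
    c("benzene", "c1ccccc1", "cyclic")))
  h <- build_hierarchy(col)
  ann <- annotate_molecule(parse_smiles("FC(F)(F)c1ccccc1"), col, h)
  expect_setequal(visible_names(ann), c("trifluoromethyl", "benzene"))
  th <- match_by_name(ann, "trihalide")
  expect_equal(th$suppression, "hierarchy")
  expect_true(any(grepl("trifluoromethyl", th$suppressed_by)))
  # two equal-size matches of unrelated patterns stay visible
  col2 <- tiny_collection(list(
    c("carbonyl", "[CX3]=[OX1]", "functional_group"),
    c("ketone", "[CX3;$([CX3](=[OX1])([#6])[#6])]=[OX1]", "functional_group")))
  ann2 <- annotate_molecule(parse_smiles("CC(=O)C"), col2, build_hierarchy(col2))
  expect_setequal(visible_names(ann2), c("carbonyl", "ketone"))
})

test_that("functional-group subsets vanish inside carboxylic acids", {
  for (smi in c("OC=O", "CC(=O)O")) {
    ann <- seed_ann(smi)
    expect_equal(visible_names(ann), "carboxylic acid")
    expect_equal(match_by_name(ann, "hydroxy")$suppression, "match_containment")
    expect_equal(match_by_name(ann, "carbonyl")$suppression, "match_containment")
  }
})

test_that("caffeine shows the xanthine scaffold and hides the rest", {
  ann <- seed_ann("CN1C=NC2=C1C(=O)N(C(=O)N2C)C", "caffeine")
  expect_equal(visible_names(ann), "xanthine")
  pur <- match_by_name(ann, "purine")
  expect_equal(pur$suppression, "match_containment")
  expect_true(any(grepl("xanthine", pur$suppressed_by)))
  for (nm in c("pyrimidine", "imidazole")) {
    m <- match_by_name(ann, nm)
    expect_equal(m$suppression, "match_containment")
    expect_true(any(grepl("purine", m$suppressed_by)))
  }
})

test_that("suppression partitions matches and admits no cycles", {
  pats <- seed_pattern_collection(); h <- seed_hierarchy()
  for (entry in toy_corpus(13, 6)) {
    ann <- annotate_molecule(entry$record, pats, h)
    ms <- ann$matches
    vis <- visible_matches(ann); sup <- suppressed_matches(ann)
    expect_equal(length(vis) + length(sup), length(ms))
    for (m in vis) expect_length(m$suppressed_by, 0)
    for (m in sup) expect_gt(length(m$suppressed_by), 0)
    if (length(ms) > 1) {
      pairs <- list()
      for (i in seq_along(ms)) for (j in seq_along(ms)) {
        if (i != j && match_overshadows(ms[[i]], ms[[j]], h)$overshadows)
          pairs[[length(pairs) + 1L]] <- c(i, j)
      }
      if (length(pairs) > 0) {
        g <- igraph::graph_from_edgelist(do.call(rbind, pairs))
        expect_true(igraph::is_dag(g))
      }
    }
  }
})

test_that("removing a pattern never hides a previously visible match", {
  pats <- seed_pattern_collection(); h <- seed_hierarchy()
  for (smi in c("CN1C=NC2=C1C(=O)N(C(=O)N2C)C", "FC(F)(F)c1ccccc1", "OC=O")) {
    full <- annotate_molecule(parse_smiles(smi), pats, h)
    vis_full <- visible_names(full)
    drop <- vapply(full$matches, function(m) m$pattern_id, character(1))[1]
    reduced <- pattern_collection(Filter(function(p) p$id != drop, pats$patterns))
    red <- annotate_molecule(parse_smiles(smi), reduced, build_hierarchy(reduced))
    dropped_name <- pats$patterns[[match(drop, vapply(pats$patterns, `[[`,
                                  character(1), "id"))]]$name
    expect_true(all(setdiff(vis_full, dropped_name) %in% visible_names(red)))
  }
})

test_that("single matches and unparseable molecules are handled", {
  ann <- seed_ann("C")           # methane: nothing matches
  expect_length(ann$matches, 0)
  ann1 <- annotate_molecule("CCO", seed_pattern_collection(), seed_hierarchy())
  expect_equal(visible_names(ann1), "hydroxy")
  bad <- annotate_molecule("C1CC", seed_pattern_collection(), seed_hierarchy())
  expect_false(is.null(bad$error))
  expect_length(bad$matches, 0)
  expect_equal(bad$molecule_name, "No Name")
  expect_error(match_overshadows(ann1$matches[[1]], ann1$matches[[1]]))
})
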