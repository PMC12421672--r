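test_that("the seed collection covers the documented substructures", {
  col <- seed_pattern_collection()
  expect_gte(length(col$patterns), 60)
  nms <- vapply(col$patterns, function(p) p$name, character(1))
  required <- c("azo", "aldehyde", "amide", "lactam", "imide", "guanidine",
                "trifluoromethyl", "trihalide", "sulfate", "carboxylic acid",
                "hydroxy", "carbonyl", "ketone", "phenol",
                "benzene", "pyridine", "pyrimidine", "imidazole", "purine",
                "xanthine", "quinazoline", "tetrahydroquinazoline",
                "cyclononane", "hydrindane", "toluene", "cresol",
                "adenine", "guanine", "cytosine", "thymine", "uracil",
                "glucose", "catecholamine", "glycine", "alanine")
  expect_true(all(required %in% nms))

  by_name <- function(nm) Filter(function(p) p$name == nm, col$patterns)[[1]]
  # two-atom patterns whose context lives in recursive environments
  expect_equal(by_name("azo")$atom_count, 2)
  expect_equal(by_name("aldehyde")$atom_count, 2)
  expect_equal(by_name("imidazole")$atom_count, 5)
  expect_equal(by_name("purine")$atom_count, 9)

  # aldehyde needs a carbon neighbour that is not part of the match
  ald <- by_name("aldehyde")$smarts
  expect_equal(emb_count(ald, "CC=O"), 1)
  expect_equal(emb_count(ald, "C=O"), 0)
  expect_equal(emb_count(ald, "CC(=O)C"), 0)
  # imide under the diacyl-amine reading matches succinimide
  expect_gt(emb_count(by_name("imide")$smarts, "O=C1CCC(=O)N1"), 0)
  # the shipped JSON is the same collection
  shipped <- load_patterns(system.file("extdata", "seed_patterns.json",
                                       package = "chemannot"))
  flat <- function(cc) lapply(cc$patterns, function(p)
    p[c("id", "smarts", "name", "category")])
  expect_identical(flat(shipped), flat(col))
})

test_that("the toy corpus is deterministic and discriminative", {
  c1 <- toy_corpus(42, 8)
  c2 <- toy_corpus(42, 8)
  expect_identical(lapply(c1, function(e) e$record$smiles),
                   lapply(c2, function(e) e$record$smiles))
  expect_identical(lapply(c1, `[[`, "expected_visible"),
                   lapply(c2, `[[`, "expected_visible"))
  expect_false(identical(lapply(toy_corpus(43, 8), function(e) e$record$smiles),
                         lapply(c1, function(e) e$record$smiles)))
  # caffeine is present with the xanthine scaffold expected visible
  caf <- Filter(function(e) identical(e$record$name, "caffeine"), c1)
  expect_length(caf, 1)
  expect_true("xanthine" %in% caf[[1]]$expected_visible)

  # every seed pattern matches at least one corpus molecule and fails to
  # match at least one (discriminative fixtures)
  pats <- seed_pattern_collection()
  hits <- stats::setNames(integer(length(pats$patterns)),
                          vapply(pats$patterns, `[[`, character(1), "id"))
  nmol <- 0L
  for (e in toy_corpus(1, 0)) {
    nmol <- nmol + 1L
    ms <- find_pattern_matches(e$record, pats)
    for (id in unique(vapply(ms, `[[`, character(1), "pattern_id")))
      hits[id] <- hits[id] + 1L
  }
  expect_true(all(hits >= 1))
  expect_true(all(hits < nmol))
})

test_that("expected visible names are exact for the fixed corpus", {
  pats <- seed_pattern_collection(); h <- seed_hierarchy()
  for (e in toy_corpus(1, 0)) {
    ann <- annotate_molecule(e$record, pats, h)
    expect_identical(visible_names(ann), e$expected_visible,
                     info = e$record$name)
  }
})
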