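test_that("automorphic embeddings collapse; distinct locations are kept", {
  col <- tiny_collection(list(c("benzene", "c1ccccc1", "cyclic")))
  bz <- find_pattern_matches(parse_smiles("c1ccccc1"), col)
  expect_length(bz, 1)   # 12 symmetry-equivalent embeddings -> 1 match

  bi <- find_pattern_matches(parse_smiles("c1ccccc1-c1ccccc1"), col)
  expect_length(bi, 2)
  expect_length(intersect(bi[[1]]$atom_indices, bi[[2]]$atom_indices), 0)

  expect_identical(dedupe_matches(list()), list())
  expect_length(dedupe_matches(c(bz, bz)), 1)
  # same atoms, different bond sets: both kept
  a <- bz[[1]]; b <- bz[[1]]
  b$bonds <- b$bonds[-1, , drop = FALSE]
  expect_length(dedupe_matches(list(a, b)), 2)
})

test_that("caffeine contains its textbook ring substructures", {
  col <- tiny_collection(list(
    c("imidazole", "c1cncn1", "cyclic"),
    c("pyrimidine", "c1cncnc1", "cyclic"),
    c("purine", "c1ncc2ncnc2n1", "cyclic")))
  caf <- parse_smiles("CN1C=NC2=C1C(=O)N(C(=O)N2C)C")
  ms <- find_pattern_matches(caf, col)
  byname <- table(vapply(ms, function(m) m$pattern_name, character(1)))
  expect_true(all(c("imidazole", "pyrimidine", "purine") %in% names(byname)))
})

test_that("matches are well-formed and deterministic", {
  pats <- seed_pattern_collection()
  for (entry in toy_corpus(3, 3)[c(1, 4, 7, 60, 75)]) {
    mol <- entry$record
    ms <- find_pattern_matches(mol, pats)
    bond_keys <- paste(chemannot:::.mol_bond_pairs(mol)[, 1],
                       chemannot:::.mol_bond_pairs(mol)[, 2])
    ids <- vapply(pats$patterns, function(p) p$id, character(1))
    for (m in ms) {
      p <- pats$patterns[[match(m$pattern_id, ids)]]
      expect_length(m$atom_indices, p$atom_count)
      if (nrow(m$bonds) > 0) {
        expect_true(all(paste(m$bonds[, 1], m$bonds[, 2]) %in% bond_keys))
        expect_true(all(m$bonds %in% m$atom_indices))
      }
    }
    expect_identical(ms, find_pattern_matches(mol, pats))
  }
})

test_that("prefiltered and exhaustive matching agree", {
  pats <- seed_pattern_collection()
  for (entry in toy_corpus(5, 4)[c(1, 3, 12, 40, 68, 74)]) {
    with_pf <- find_pattern_matches(entry$record, pats, use_prefilter = TRUE)
    without <- find_pattern_matches(entry$record, pats, use_prefilter = FALSE)
    expect_identical(with_pf, without)
  }
})

test_that("unique match counts agree with the OpenBabel oracle", {
  cases <- list(
    c("c1ccccc1", "c1ccccc1-c1ccccc1"),   # benzene in biphenyl
    c("c1ccncc1", "c1ccncc1"),            # pyridine in itself
    c("C(F)(F)F", "FC(F)(F)c1ccccc1"),    # trifluoromethyl
    c("[OX2H]", "OCC(O)CO"),              # glycerol hydroxyls
    c("C1CCCCC1", "C1CCC2CCCCC2C1"))      # cyclohexane in decalin
  for (cs in cases) {
    mine <- length(dedupe_matches(lapply(
      chemannot:::.match_embeddings(parse_smarts(cs[1]), parse_smiles(cs[2])),
      chemannot:::.embedding_to_match, pg = parse_smarts(cs[1]),
      mol = parse_smiles(cs[2]), pattern_id = "x")))
    obmol <- ChemmineOB::forEachMol("SMILES", cs[2], identity)
    oracle <- ChemmineOB::smartsSearch_OB(obmol, cs[1], uniqueMatches = TRUE)
    expect_equal(mine, as.integer(oracle), info = paste(cs, collapse = " in "))
  }
})
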