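test_that("ring-system recognition follows the exocyclic O/S rule", {
  expect_true(is_ring_system_molecule(parse_smiles("c1ccccc1")))
  expect_false(is_ring_system_molecule(parse_smiles("Cc1ccccc1")))
  expect_true(is_ring_system_molecule(parse_smiles("O=C1CCCCC1")))
  expect_true(is_ring_system_molecule(parse_smiles("S=C1CCCCC1")))
  expect_false(is_ring_system_molecule(parse_smiles("Oc1ccccc1")))
  expect_false(is_ring_system_molecule(parse_smiles("C=C1CCCCC1")))  # C, not O/S
  expect_false(is_ring_system_molecule(parse_smiles("CCO")))
})

test_that("structure filters fire in fixed order with the right reasons", {
  expect_equal(passes_structure_filters("C1CC1.C1CC1")$reason, "mixture")
  expect_equal(passes_structure_filters("[CH]1CCCCC1")$reason, "radical")
  expect_equal(passes_structure_filters("[13C]1CCCCC1")$reason, "isotope")
  big <- paste0("C1", strrep("C", 99), "C1")
  expect_equal(passes_structure_filters(big)$reason, "too_large")
  ok <- paste0("C1", strrep("C", 98), "C1")
  expect_true(passes_structure_filters(ok)$passed)
  expect_equal(passes_structure_filters("not a molecule")$reason, "unparseable")
  # a mixture of a radical and an isotope is reported as a mixture first
  expect_equal(passes_structure_filters("[CH3].[13CH4]")$reason, "mixture")
})

test_that("name filters count digit runs and check affixes in order", {
  expect_equal(passes_name_filters("CID1234567")$reason, "name_cid_prefix")
  expect_equal(passes_name_filters("phenyl")$reason, "name_yl_suffix")
  expect_true(passes_name_filters("1,2,3,4-tetrahydroquinazoline")$passed)
  expect_equal(passes_name_filters("1,2,3,4,5-pentasomething")$reason,
               "name_numbers")
  expect_true(passes_name_filters("benzene")$passed)
  expect_true(passes_name_filters("7H-purine")$passed)
  expect_equal(passes_name_filters("")$reason, "unparseable")
  expect_equal(passes_name_filters("   ")$reason, "unparseable")
  # prefix beats suffix beats numbers
  expect_equal(passes_name_filters("CID1,2,3,4,5-yl")$reason, "name_cid_prefix")
})

test_that("generated ring patterns are substitution-tolerant", {
  # xanthine scaffold pattern matches caffeine (N-methylation allowed)
  xp <- ring_pattern_from_molecule(parse_smiles("O=C1NC(=O)C2=C(N1)N=CN2"))
  expect_equal(emb_count(xp, "CN1C=NC2=C1C(=O)N(C(=O)N2C)C"), 1)
  # benzene pattern matches toluene, phenol, any substituted benzene
  bp <- ring_pattern_from_molecule(parse_smiles("c1ccccc1"))
  for (smi in c("Cc1ccccc1", "Oc1ccccc1", "Clc1ccccc1"))
    expect_gt(emb_count(bp, smi), 0)
  # but the cyclohexanone pattern rejects cyclohexanol
  cp <- ring_pattern_from_molecule(parse_smiles("O=C1CCCCC1"))
  expect_equal(emb_count(cp, "OC1CCCCC1"), 0)
  expect_error(ring_pattern_from_molecule(parse_smiles("Cc1ccccc1")),
               "not a pure ring system")
})

test_that("every emitted pattern self-matches covering all atoms", {
  fix <- extraction_fixture()
  res <- extract_cyclic_patterns(fix)
  srcs <- fix$smiles[fix$expected_reason == "ok"]
  for (p in res$collection$patterns) {
    pg <- parse_smarts(p$smarts)
    covered <- FALSE
    for (smi in srcs) {
      m <- tryCatch(parse_smiles(smi), error = function(e) NULL)
      if (is.null(m) || m$n != pg$n) next
      embs <- chemannot:::.match_embeddings(pg, m)
      if (any(vapply(embs, function(e) length(unique(e)) == m$n, logical(1))))
        covered <- TRUE
    }
    expect_true(covered, info = p$name)
  }
})

test_that("the mining pipeline reproduces the hand-derived fixture outcome", {
  fix <- extraction_fixture()
  res <- extract_cyclic_patterns(fix)
  expect_equal(nrow(res$log), nrow(fix))
  expect_equal(res$log$reason, fix$expected_reason)
  expect_equal(res$log$passed, fix$expected_reason == "ok")
  # 15 passing records collapse to 13 distinct ring systems
  expect_length(res$collection$patterns, 13)
  nms <- vapply(res$collection$patterns, function(p) p$name, character(1))
  # shortest-name tie-breaks: purine over 7H-purine, benzene over benzole
  expect_true("purine" %in% nms)
  expect_false("7H-purine" %in% nms)
  expect_true("benzene" %in% nms)
  expect_false("benzole" %in% nms)
  expect_true(all(vapply(res$collection$patterns, function(p) p$category,
                         character(1)) == "cyclic"))

  # empty input
  empty <- extract_cyclic_patterns(data.frame(name = character(0),
                                              smiles = character(0)))
  expect_length(empty$collection$patterns, 0)
  expect_equal(nrow(empty$log), 0)
})

test_that("extraction is idempotent on its own survivors", {
  fix <- extraction_fixture()
  res <- extract_cyclic_patterns(fix)
  ok <- fix[fix$expected_reason == "ok", ]
  keys1 <- sort(unique(vapply(ok$smiles, canonical_structure_key, character(1))))
  again <- extract_cyclic_patterns(ok)
  expect_length(again$collection$patterns, length(keys1))
  expect_true(all(again$log$reason == "ok"))
})

test_that("pass/fail partition is independent of reason ordering", {
  fix <- extraction_fixture()
  for (i in seq_len(nrow(fix))) {
    mol <- tryCatch(parse_smiles(fix$smiles[i]), error = function(e) NULL)
    indep_fail <- is.null(mol) ||
      !passes_structure_filters(mol)$passed ||
      !is_ring_system_molecule(mol) ||
      !passes_name_filters(fix$name[i])$passed
    expect_equal(!indep_fail, fix$expected_reason[i] == "ok", info = fix$name[i])
  }
})
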