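test_that("TSV and JSON pattern files round-trip", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1ccncc1\tpyridine\tcyclic",
               "[OX2H]\thydroxy\tfunctional_group"), tsv)
  col <- load_patterns(tsv)
  expect_length(col$patterns, 2)
  p <- col$patterns[[1]]
  expect_equal(p$atom_count, 6)
  expect_equal(p$bond_count, 6)
  expect_equal(p$category, "cyclic")

  # round-trip on both formats preserves (id, smarts, name, category)
  for (ext in c(".tsv", ".json")) {
    out <- withr::local_tempfile(fileext = ext)
    save_patterns(col, out)
    back <- load_patterns(out)
    fields <- function(cc) lapply(cc$patterns, function(q)
      q[c("id", "smarts", "name", "category")])
    expect_identical(fields(back), fields(col))
  }

  # empty collection round-trips
  out <- withr::local_tempfile(fileext = ".json")
  save_patterns(pattern_collection(list()), out)
  expect_length(load_patterns(out)$patterns, 0)
})

test_that("invalid records are reported with their position", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1ccccc1\tbenzene\tcyclic",
               "c1ccncc1\tpyridine\tring"), tsv)        # bad category
  expect_error(load_patterns(tsv), "record 2")
  expect_warning(col <- load_patterns(tsv, permissive = TRUE), "skipped")
  expect_length(col$patterns, 1)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c1ccccc1\tben\tzene\tcyclic", bad)        # stray tab
  expect_error(load_patterns(bad), "3 tab-separated fields")

  # a name containing a tab cannot be saved as TSV
  col2 <- pattern_collection(list(new_pattern("x", "C", "a\tb", "cyclic")))
  expect_error(save_patterns(col2, withr::local_tempfile(fileext = ".tsv")),
               "tab")
  expect_error(load_patterns(tempfile()), "cannot read")
})

test_that("prefilter signatures are the documented lower bounds", {
  s <- compute_prefilter_signature("C(F)(F)F")
  expect_equal(s$min_heavy_atoms, 4)
  expect_equal(s$required_elements, c(C = 1L, F = 3L))
  expect_equal(s$min_ring_atoms, 0)
  expect_equal(s$min_aromatic_atoms, 0)

  # disjunctive element lists contribute no element requirement
  s <- compute_prefilter_signature("[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]")
  expect_equal(s$min_heavy_atoms, 4)
  expect_equal(s$required_elements, c(C = 1L))

  s <- compute_prefilter_signature("c1ccncc1")
  expect_equal(s$required_elements, c(C = 5L, N = 1L))
  expect_equal(s$min_ring_atoms, 6)
  expect_equal(s$min_aromatic_atoms, 6)
})

test_that("prefilter is sound: skipped pairs never have matches", {
  pats <- seed_pattern_collection()
  psigs <- lapply(pats$patterns, compute_prefilter_signature)
  mols <- lapply(toy_corpus(7, 5), `[[`, "record")[seq(1, 80, by = 8)]
  for (mol in mols) {
    ms <- molecule_signature(mol)
    for (i in seq_along(pats$patterns)) {
      if (!prefilter_pass(psigs[[i]], ms)) {
        emb <- chemannot:::.match_embeddings(parse_smarts(pats$patterns[[i]]$smarts), mol)
        expect_length(emb, 0)
      }
    }
  }
})

test_that("the shipped seed file re-parses under an independent toolkit", {
  path <- system.file("extdata", "seed_patterns.json", package = "chemannot")
  col <- load_patterns(path)
  expect_gte(length(col$patterns), 60)
  ids <- vapply(col$patterns, function(p) p$id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  # every SMARTS must also be accepted by OpenBabel's SMARTS parser
  mol <- ChemmineOB::forEachMol("SMILES", "c1ccccc1", identity)
  for (p in col$patterns)
    expect_no_error(ChemmineOB::smartsSearch_OB(mol, p$smarts))
})
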