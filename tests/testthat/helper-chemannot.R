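# Shared helpers and fixtures built in code.

emb_count <- function(smarts, smiles) {
  length(chemannot:::.match_embeddings(parse_smarts(smarts), parse_smiles(smiles)))
}

visible_names <- function(ann) {
  sort(unique(vapply(visible_matches(ann), function(m) m$pattern_name, character(1))))
}

match_by_name <- function(ann, name) {
  hits <- Filter(function(m) m$pattern_name == name, ann$matches)
  if (length(hits) == 0L) NULL else hits[[1]]
}

tiny_collection <- function(specs) {
  # specs: list of c(name, smarts, category)
  pattern_collection(lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    new_pattern(sprintf("%02d-%s", i, gsub("[^a-z0-9]+", "-", tolower(s[1]))),
                s[2], s[1], s[3])
  }))
}

# 30-row extraction fixture exercising every filter, with hand-derived
# reason codes; survivors dedupe to 13 distinct ring systems
extraction_fixture <- function() {
  ring101 <- paste0("C1", strrep("C", 99), "C1")   # 101 heavy atoms
  ring100 <- paste0("C1", strrep("C", 98), "C1")   # 100 heavy atoms
  rows <- list(
    list("benzene",                      "c1ccccc1",            "ok"),
    list("toluene",                      "Cc1ccccc1",           "not_ring_system"),
    list("cyclohexanone",                "O=C1CCCCC1",          "ok"),
    list("phenol",                       "Oc1ccccc1",           "not_ring_system"),
    list("cyclohexane radical",          "[CH]1CCCCC1",         "radical"),
    list("labelled cyclohexane",         "[13C]1CCCCC1",        "isotope"),
    list("giant macrocycle",             ring101,               "too_large"),
    list("hectane ring",                 ring100,               "ok"),
    list("cyclopropane dimer",           "C1CC1.C1CC1",         "mixture"),
    list("CID1234",                      "c1ccccc1",            "name_cid_prefix"),
    list("phenyl",                       "c1ccccc1",            "name_yl_suffix"),
    list("1,2,3,4,5-somering",           "C1CCCC1",             "name_numbers"),
    list("1,2,3,4-tetrahydroquinazoline","N1CNCc2ccccc21",      "ok"),
    list("purine",                       "c1ncc2[nH]cnc2n1",    "ok"),
    list("7H-purine",                    "c1ncc2[nH]cnc2n1",    "ok"),
    list("caffeine",                     "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "not_ring_system"),
    list("xanthine",                     "O=C1NC(=O)C2=C(N1)N=CN2", "ok"),
    list("broken",                       "C1CC",                "unparseable"),
    list("",                             "C1CC1",               "unparseable"),
    list("pyridine",                     "c1ccncc1",            "ok"),
    list("cyclohexanethione",            "S=C1CCCCC1",          "ok"),
    list("naphthalene",                  "c1ccc2ccccc2c1",      "ok"),
    list("CIDX",                         "c1ccncc1",            "name_cid_prefix"),
    list("methyl radical",               "[CH3]",               "radical"),
    list("thiophene",                    "c1ccsc1",             "ok"),
    list("imidazole",                    "c1c[nH]cn1",          "ok"),
    list("benzole",                      "C1=CC=CC=C1",         "ok"),
    list("glucose",                      "OCC1OC(O)C(O)C(O)C1O","not_ring_system"),
    list("pyrylium",                     "c1cc[o+]cc1",         "ok"),
    list("cyclohexene",                  "C1CCC=CC1",           "ok")
  )
  data.frame(
    name = vapply(rows, function(r) r[[1]], character(1)),
    smiles = vapply(rows, function(r) r[[2]], character(1)),
    expected_reason = vapply(rows, function(r) r[[3]], character(1)),
    source_line = seq_along(rows),
    stringsAsFactors = FALSE
  )
}
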