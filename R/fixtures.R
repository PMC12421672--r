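# Seed pattern collection and toy corpus.
#
# The seed collection is a curated set of named substructures across the
# three categories.  Functional-group and biological patterns are written
# as literal SMARTS against their textbook definitions; following the
# principle that only the atoms of the pattern are matched even when
# outside atoms are needed for the definition, the azo and aldehyde
# patterns consist of two atoms joined by a double bond, with the
# required carbon neighbours demanded through recursive environments but
# not part of the match.  Cyclic patterns are generated from ring-system
# molecules with ring_pattern_from_molecule(), so they match any
# substituted variant of the cycle.

.SEED_FUNCTIONAL <- list(
  c("hydroxy",          "[OX2H]"),
  c("carbonyl",         "[CX3]=[OX1]"),
  c("ketone",           "[CX3;$([CX3](=[OX1])([#6])[#6])]=[OX1]"),
  c("aldehyde",         "[CX3H1;$([CX3H1](=[OX1])[#6])]=[OX1]"),
  c("azo",              "[NX2;$([NX2](=[NX2])[#6])]=[NX2;$([NX2](=[NX2])[#6])]"),
  c("carboxylic acid",  "[CX3](=[OX1])[OX2H1,OX1-]"),
  c("ester",            "[CX3](=[OX1])[OX2H0][#6]"),
  c("amide",            "[CX3](=[OX1])[NX3]"),
  c("lactam",           "[CX3;R](=[OX1])[NX3;R]"),
  c("imide",            "[CX3](=[OX1])[NX3][CX3]=[OX1]"),
  c("guanidine",        "[NX3][CX3](=[NX2])[NX3]"),
  c("urea",             "[NX3][CX3](=[OX1])[NX3]"),
  c("carbamate",        "[NX3][CX3](=[OX1])[OX2]"),
  c("trifluoromethyl",  "[CX4](F)(F)F"),
  c("trihalide",        "[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]"),
  c("sulfate",          "[SX4](=[OX1])(=[OX1])([OX2])[OX2]"),
  c("sulfonamide",      "[SX4](=[OX1])(=[OX1])[NX3]"),
  c("phosphate",        "[PX4](=[OX1])([OX2,OX1-])([OX2,OX1-])[OX2,OX1-]"),
  c("nitro",            "[NX3](~[OX1])~[OX1]"),
  c("nitrile",          "[CX2]#[NX1]"),
  c("primary amine",    "[NX3H2;$([NX3H2][#6])]"),
  c("thiol",            "[SX2H]"),
  c("ether",            "[OX2H0;$([OX2H0]([#6])[#6])]"),
  c("phenol",           "[OX2H]c1ccccc1"),
  c("fluoro",           "[F;$(F[#6])]"),
  c("chloro",           "[Cl;$(Cl[#6])]"),
  c("bromo",            "[Br;$(Br[#6])]"),
  c("iodo",             "[I;$(I[#6])]")
)

# ring-system molecules whose generated patterns form the cyclic category
.SEED_CYCLIC <- list(
  c("benzene",                "c1ccccc1"),
  c("pyridine",               "c1ccncc1"),
  c("pyrimidine",             "c1cncnc1"),
  c("pyrazine",               "c1cnccn1"),
  c("pyridazine",             "c1ccnnc1"),
  c("imidazole",              "c1c[nH]cn1"),
  c("pyrazole",               "c1cc[nH]n1"),
  c("pyrrole",                "c1cc[nH]c1"),
  c("furan",                  "c1ccoc1"),
  c("thiophene",              "c1ccsc1"),
  c("oxazole",                "c1ocnc1"),
  c("thiazole",               "c1scnc1"),
  c("purine",                 "c1ncc2[nH]cnc2n1"),
  c("xanthine",               "O=C1NC(=O)C2=C(N1)N=CN2"),
  c("quinazoline",            "c1ccc2ncncc2c1"),
  c("tetrahydroquinazoline",  "N1CNCc2ccccc21"),
  c("quinoline",              "c1ccc2ncccc2c1"),
  c("indole",                 "c1ccc2[nH]ccc2c1"),
  c("naphthalene",            "c1ccc2ccccc2c1"),
  c("cyclopropane",           "C1CC1"),
  c("cyclopentane",           "C1CCCC1"),
  c("cyclohexane",            "C1CCCCC1"),
  c("cyclononane",            "C1CCCCCCCC1"),
  c("hydrindane",             "C1CCC2CCCC2C1"),
  c("decalin",                "C1CCC2CCCCC2C1"),
  c("piperidine",             "C1CCNCC1"),
  c("piperazine",             "C1CNCCN1"),
  c("morpholine",             "C1COCCN1"),
  c("pyrrolidine",            "C1CCNC1"),
  c("tetrahydrofuran",        "C1CCOC1"),
  c("tetrahydropyran",        "C1CCOCC1")
)

.SEED_BIOLOGICAL <- list(
  c("adenine",        "Nc1ncnc2ncnc12"),
  c("guanine",        "Nc1nc2ncnc2c(=O)n1"),
  c("cytosine",       "Nc1ccnc(=O)n1"),
  c("thymine",        "Cc1cnc(=O)nc1=O"),
  c("uracil",         "O=c1ccnc(=O)n1"),
  c("glucose",        "OCC1OC(O)C(O)C(O)C1O"),
  c("catecholamine",  "NCCc1ccc([OX2H])c([OX2H])c1"),
  c("glycine",        "[NX3][CX4H2][CX3](=[OX1])[OX2H1,OX1-]"),
  c("alanine",        "[NX3][CX4H1]([CX4H3])[CX3](=[OX1])[OX2H1,OX1-]"),
  c("toluene",        "[CX4H3]c1ccccc1"),
  c("cresol",         "[CX4H3]c1ccc([OX2H])cc1")
)

.fixture_env <- new.env(parent = emptyenv())

#' The shipped seed pattern collection
#'
#' A curated collection of named substructure patterns covering common
#' functional groups, (hetero)cyclic ring systems and biologically
#' relevant motifs, built in code (the same collection is shipped as
#' `inst/extdata/seed_patterns.json`).  Cyclic entries are generated from
#' their defining ring-system molecules and therefore tolerate
#' substitution: the xanthine-scaffold pattern matches caffeine.
#'
#' @return A `ca_pattern_collection` with >= 60 patterns.
#' @examples
#' seed_pattern_collection()
#' @export
seed_pattern_collection <- function() {
  hit <- get0("seed", envir = .fixture_env)
  if (!is.null(hit)) return(hit)
  patterns <- list()
  ordinal <- 0L
  push <- function(name, smarts, category) {
    ordinal <<- ordinal + 1L
    patterns[[ordinal]] <<- new_pattern(
      id = sprintf("%04d-%s", ordinal, .slug(name)),
      smarts = smarts, name = name, category = category)
  }
  for (e in .SEED_FUNCTIONAL) push(e[1], e[2], "functional_group")
  for (e in .SEED_CYCLIC)
    push(e[1], ring_pattern_from_molecule(parse_smiles(e[2])), "cyclic")
  for (e in .SEED_BIOLOGICAL) push(e[1], e[2], "biological")
  out <- pattern_collection(patterns, version = "seed")
  assign("seed", out, envir = .fixture_env)
  out
}

#' The seed hierarchy (memoized)
#'
#' [build_hierarchy()] over the seed collection; cached per session.
#'
#' @return A `ca_hierarchy`.
#' @export
seed_hierarchy <- function() {
  hit <- get0("seed_h", envir = .fixture_env)
  if (!is.null(hit)) return(hit)
  h <- build_hierarchy(seed_pattern_collection())
  assign("seed_h", h, envir = .fixture_env)
  h
}

# fixed corpus entries: smiles, molecule name, expected visible pattern
# names under the full seed collection + hierarchy
.FIXED_CORPUS <- list(
  # worked examples
  list("CN1C=NC2=C1C(=O)N(C(=O)N2C)C", "caffeine", c("xanthine")),
  list("c1ncc2[nH]cnc2n1", "purine", c("purine")),
  list("C1CCC2CCCC2C1", "hydrindane", c("hydrindane")),
  list("FC(F)(F)c1ccccc1", "trifluoromethylbenzene",
       c("trifluoromethyl", "benzene")),
  list("OC=O", "formic acid", c("carboxylic acid")),
  list("c1ccccc1-c1ccccc1", "biphenyl", c("benzene")),
  list("O=C1CCC(=O)N1", "succinimide", c("imide", "pyrrolidine")),
  # functional-group exemplars
  list("CCO", "ethanol", c("hydroxy")),
  list("CC(=O)C", "acetone", c("ketone", "carbonyl")),
  list("CC=O", "acetaldehyde", c("aldehyde", "carbonyl")),
  list("c1ccccc1N=Nc1ccccc1", "azobenzene", c("azo", "benzene")),
  list("CC(=O)O", "acetic acid", c("carboxylic acid")),
  list("COC(=O)C", "methyl acetate", c("ester")),
  list("CC(=O)N", "acetamide", c("amide")),
  list("O=C1CCCCCN1", "caprolactam", c("lactam")),
  list("NC(=N)N", "guanidine", c("guanidine")),
  list("NC(=O)N", "urea", c("urea")),
  list("COC(=O)N", "methyl carbamate", c("carbamate", "ester")),
  list("FC(F)F", "fluoroform", c("trifluoromethyl")),
  list("COS(=O)(=O)OC", "dimethyl sulfate", c("sulfate")),
  list("CS(=O)(=O)N", "methanesulfonamide", c("sulfonamide")),
  list("COP(=O)(O)O", "methyl phosphate", c("phosphate")),
  list("C[N+](=O)[O-]", "nitromethane", c("nitro")),
  list("CC#N", "acetonitrile", c("nitrile")),
  list("CCN", "ethylamine", c("primary amine")),
  list("CCS", "ethanethiol", c("thiol")),
  list("CCOCC", "diethyl ether", c("ether")),
  list("Oc1ccccc1", "phenol", c("phenol")),
  list("Fc1ccccc1", "fluorobenzene", c("fluoro", "benzene")),
  list("Clc1ccccc1", "chlorobenzene", c("chloro", "benzene")),
  list("Brc1ccccc1", "bromobenzene", c("bromo", "benzene")),
  list("Ic1ccccc1", "iodobenzene", c("iodo", "benzene")),
  # cyclic exemplars
  list("c1ccccc1", "benzene", c("benzene")),
  list("c1ccncc1", "pyridine", c("pyridine")),
  list("c1cncnc1", "pyrimidine", c("pyrimidine")),
  list("c1cnccn1", "pyrazine", c("pyrazine")),
  list("c1ccnnc1", "pyridazine", c("pyridazine")),
  list("c1c[nH]cn1", "imidazole", c("imidazole")),
  list("c1cc[nH]n1", "pyrazole", c("pyrazole")),
  list("c1cc[nH]c1", "pyrrole", c("pyrrole")),
  list("c1ccoc1", "furan", c("furan")),
  list("c1ccsc1", "thiophene", c("thiophene")),
  list("c1ocnc1", "oxazole", c("oxazole")),
  list("c1scnc1", "thiazole", c("thiazole")),
  list("O=C1NC(=O)C2=C(N1)N=CN2", "xanthine", c("xanthine")),
  list("c1ccc2ncncc2c1", "quinazoline", c("quinazoline")),
  list("N1CNCc2ccccc21", "tetrahydroquinazoline", c("tetrahydroquinazoline")),
  list("c1ccc2ncccc2c1", "quinoline", c("quinoline")),
  list("c1ccc2[nH]ccc2c1", "indole", c("indole")),
  list("c1ccc2ccccc2c1", "naphthalene", c("naphthalene")),
  list("C1CC1", "cyclopropane", c("cyclopropane")),
  list("C1CCCC1", "cyclopentane", c("cyclopentane")),
  list("C1CCCCC1", "cyclohexane", c("cyclohexane")),
  list("C1CCCCCCCC1", "cyclononane", c("cyclononane")),
  list("C1CCC2CCCCC2C1", "decalin", c("decalin")),
  list("C1CCNCC1", "piperidine", c("piperidine")),
  list("C1CNCCN1", "piperazine", c("piperazine")),
  list("C1COCCN1", "morpholine", c("morpholine")),
  list("C1CCNC1", "pyrrolidine", c("pyrrolidine")),
  list("C1CCOC1", "tetrahydrofuran", c("tetrahydrofuran")),
  list("C1CCOCC1", "tetrahydropyran", c("tetrahydropyran")),
  # biological exemplars
  list("Nc1ncnc2[nH]cnc12", "adenine", c("adenine")),
  list("Nc1nc2[nH]cnc2c(=O)[nH]1", "guanine", c("guanine")),
  list("Nc1cc[nH]c(=O)n1", "cytosine", c("cytosine")),
  list("Cc1c[nH]c(=O)[nH]c1=O", "thymine", c("thymine")),
  list("O=c1cc[nH]c(=O)[nH]1", "uracil", c("uracil")),
  list("OCC1OC(O)C(O)C(O)C1O", "glucose", c("glucose")),
  list("NCCc1ccc(O)c(O)c1", "dopamine", c("catecholamine")),
  list("NCC(=O)O", "glycine", c("glycine")),
  list("CC(N)C(=O)O", "alanine", c("alanine")),
  list("Cc1ccccc1", "toluene", c("toluene")),
  list("Cc1ccc(O)cc1", "p-cresol", c("cresol"))
)

# scaffold + substituent grammar for randomized corpus molecules; each
# substituent SMILES prefix bonds its last-opened atom to the scaffold's
# first atom (always a carbon with a free valence)
.RAND_SCAFFOLDS <- list(
  c("benzene", "c1ccccc1"),
  c("pyridine", "c1ccncc1"),
  c("pyrimidine", "c1cncnc1"),
  c("naphthalene", "c1ccc2ccccc2c1"),
  c("thiophene", "c1ccsc1"),
  c("furan", "c1ccoc1"),
  c("cyclohexane", "C1CCCCC1"),
  c("cyclopentane", "C1CCCC1"),
  c("piperidine", "C1CCNCC1"),
  c("tetrahydrofuran", "C1CCOC1")
)
.RAND_SUBSTITUENTS <- list(
  list(prefix = "", names = character(0), label = "unsubstituted"),
  list(prefix = "F", names = "fluoro", label = "fluoro"),
  list(prefix = "Cl", names = "chloro", label = "chloro"),
  list(prefix = "Br", names = "bromo", label = "bromo"),
  list(prefix = "N#C", names = "nitrile", label = "cyano"),
  list(prefix = "FC(F)(F)", names = "trifluoromethyl", label = "trifluoromethyl"),
  list(prefix = "OC(=O)", names = "carboxylic acid", label = "carboxy"),
  list(prefix = "N", names = "primary amine", label = "amino")
)

#' Deterministic toy corpus with expected visible annotations
#'
#' Fixed worked-example and exemplar molecules (one or more per seed
#' pattern) plus `n` randomized molecules assembled from a
#' scaffold-plus-substituent grammar.  Every entry carries the pattern
#' names expected to be visible after annotation with the full seed
#' collection and hierarchy; the combinations in the grammar are chosen
#' so that the expectation is derivable by construction.
#'
#' @param seed Integer random seed (only the randomized tail depends on it).
#' @param n Number of randomized molecules to append (>= 0).
#' @return A list of entries, each a list with `record` (a named `ca_mol`)
#'   and `expected_visible` (sorted unique pattern names).
#' @examples
#' corp <- toy_corpus(1, 2)
#' corp[[1]]$record$name
#' @export
toy_corpus <- function(seed, n) {
  stopifnot(n >= 0L)
  out <- lapply(.FIXED_CORPUS, function(e)
    list(record = parse_smiles(e[[1]], name = e[[2]]),
         expected_visible = sort(unique(e[[3]]))))
  if (n > 0L) {
    set.seed(seed)
    si <- sample.int(length(.RAND_SCAFFOLDS), n, replace = TRUE)
    bi <- sample.int(length(.RAND_SUBSTITUENTS), n, replace = TRUE)
    for (t in seq_len(n)) {
      sc <- .RAND_SCAFFOLDS[[si[t]]]
      sub <- .RAND_SUBSTITUENTS[[bi[t]]]
      smi <- paste0(sub$prefix, sc[2])
      nm <- sprintf("%s %s %d", sub$label, sc[1], t)
      expected <- sort(unique(c(sc[1], sub$names)))
      out[[length(out) + 1L]] <- list(
        record = parse_smiles(smi, name = nm),
        expected_visible = expected)
    }
  }
  out
}
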