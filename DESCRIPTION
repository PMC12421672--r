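Package: chemannot
Title: Named Substructure Annotation for Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates molecules with the human-readable names of the
    substructures they contain: functional groups, (hetero)cyclic ring
    systems and biologically relevant motifs.  A curated collection of
    named SMARTS patterns is matched against input molecules (SMILES or
    SDF) and the matches are resolved with an overshadowing relation so
    that only the most specific name for each part of the molecule is
    shown by default, while less specific matches remain available on
    request.  Includes a restricted SMARTS subsumption engine that
    detects when one pattern is strictly more specific than another, a
    prefilter screen that skips impossible pattern/molecule pairs, and a
    mining pipeline that builds cyclic-pattern collections from tables
    of named SMILES, with structure and name filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
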