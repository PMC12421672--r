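# chemannot

Named substructure annotation for small molecules.

Interdisciplinary drug-discovery teams constantly talk about *parts* of
molecules — "the imidazole ring", "the carboxylic acid", "the xanthine
scaffold" — and the mapping between such names and actual atoms is
exactly what non-chemists lack.  `chemannot` closes that gap: it
matches a collection of named SMARTS patterns (functional groups,
cyclic ring systems, biologically relevant motifs) against input
molecules and reports, per molecule, which named substructures are
present and where, showing by default only the **most specific** name
for each region while keeping the rest retrievable.

## The core ideas

**Overshadowing.**  With overlapping patterns, a naive report drowns the
user: caffeine contains imidazole, pyrimidine, purine, a hidden uracil,
and the xanthine scaffold, all at once.  A match *A* overshadows a
match *B* when

* *B*'s atoms and bonds are a proper subset of *A*'s
  (`match_containment`); or
* both cover the same atom set and *B* has fewer bonds
  (`fewer_bonds` — e.g. the 9-bond cyclononane perimeter inside
  10-bond hydrindane); or
* both cover the same atoms and bonds and *A*'s pattern is strictly
  more specific in the SMARTS subsumption hierarchy (`hierarchy` —
  e.g. trifluoromethyl hides trihalide).

Overshadowed matches are hidden by default and serialized only on
request.

**Pattern hierarchy.**  A restricted SMARTS subsumption engine decides
when every structure matched by one pattern is necessarily matched by
another, by normalizing atom and bond expressions over a finite feature
space and searching for an expression-wise subsuming graph mapping.  It
is sound but deliberately incomplete: recursive environments are
opaque, `unknown` produces no edge, and the only consequence of
incompleteness is that an equally specific-looking match stays visible.

**Pattern mining.**  `extract_cyclic_patterns()` builds cyclic-pattern
collections from (name, SMILES) tables: it keeps pure ring systems
(allowing exocyclic double bonds to terminal O/S), drops mixtures,
radicals, isotope-labelled and >100-heavy-atom molecules, drops names
with a `CID` prefix, an `yl` suffix, or more than four digit runs, and
emits one substitution-tolerant pattern per distinct ring system under
the shortest passing name.

## Worked example

```r
library(chemannot)
pats <- seed_pattern_collection()   # 70 curated patterns
h    <- seed_hierarchy()            # specificity graph (40 edges)
annotate_molecule(parse_smiles("CN1C=NC2=C1C(=O)N(C(=O)N2C)C",
                               name = "caffeine"), pats, h)
```

```
<annotation> caffeine  CN1C=NC2=C1C(=O)N(C(=O)N2C)C
  5 match(es): 1 visible, 4 overshadowed
    xanthine                 [cyclic]  atoms {1,2,3,4,5,6,7,8,9,10,11}
    (pyrimidine overshadowed: match_containment by 0041-purine,0042-xanthine,0064-uracil)
    (imidazole overshadowed: match_containment by 0041-purine,0042-xanthine)
    (purine overshadowed: match_containment by 0042-xanthine)
    (uracil overshadowed: match_containment by 0042-xanthine)
```

The xanthine scaffold (atoms 1–11, 0-based over SMILES parse order) is
the one visible cyclic match; the purine core is hidden inside it, the
two monocycles and the uracil motif inside the purine/xanthine matches.
`write_annotations()` serializes results as JSON (schema shipped in
`inst/extdata/annotation_schema.json`); pass
`include_overshadowed = TRUE` to include the hidden matches with their
suppression reasons.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/chemannot.R annotate --smiles "OC=O formic_acid"
Rscript inst/cli/chemannot.R build-cyclic --input rings.tsv --output cyclic.json --log log.tsv
Rscript inst/cli/chemannot.R build-hierarchy --patterns cyclic.json --output hierarchy.json
Rscript inst/cli/chemannot.R validate --patterns cyclic.json
```

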