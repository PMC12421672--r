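---
title: "Naming substructures: matching, overshadowing, and pattern mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naming substructures: matching, overshadowing, and pattern mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemannot)
```

## The problem

Communicating about small-molecule structure across disciplines requires
names for *parts* of molecules: functional groups, ring systems, and
biologically meaningful motifs.  `chemannot` matches a collection of
named SMARTS patterns against molecules and decides which of the many
overlapping matches deserve to be shown, so that each region of a
molecule is labelled with its most specific available name while less
specific labels remain retrievable.

Caffeine is the running example.  Its pyrimidinedione and imidazole
rings, their fused purine core, a hidden uracil motif, and the xanthine
scaffold all match simultaneously; only the xanthine scaffold — the most
specific name covering all of them — is shown by default.

```{r caffeine}
pats <- seed_pattern_collection()
h <- seed_hierarchy()
annotate_molecule(parse_smiles("CN1C=NC2=C1C(=O)N(C(=O)N2C)C",
                               name = "caffeine"), pats, h)
```

## The pattern model

A pattern is a named SMARTS expression in one of three categories:

* `functional_group` — small motifs such as hydroxy, azo, carboxylic
  acid.  Following the design principle that *only the atoms of the
  pattern are matched*, even when outside atoms are required by the
  definition, the azo and aldehyde patterns consist of exactly two atoms
  joined by a double bond; the carbon neighbours that the definitions
  demand are imposed through recursive environments (`$(...)`) and are
  not part of the match.  So the aldehyde pattern matches acetaldehyde
  on its C=O atoms only, and matches neither formaldehyde (no carbon
  neighbour) nor acetone (no carbonyl hydrogen).
* `cyclic` — ring systems.  These are *generated* from ring-system
  molecules by `ring_pattern_from_molecule()`: each atom keeps its
  atomic number, aromaticity and formal charge, but no hydrogen-count or
  degree constraint, so any substituted variant of the cycle still
  matches (the xanthine-scaffold pattern matches N-methylated caffeine);
  terminal exocyclic O/S keep their double bond and a connectivity-1
  constraint, so a cyclohexanone pattern does not match cyclohexanol.
* `biological` — nucleobases, amino acids, sugars, and trivial names
  (toluene, cresol) that fit neither of the other groups.

Collections are flat files: JSON (`id`, `smarts`, `name`, `category`)
or three-column TSV without quoting (a tab inside a field is a
validation error).  Missing ids are generated as zero-padded ordinal
plus a name slug, which makes the TSV round-trip exact.

## Matching and the prefilter

`find_pattern_matches()` enumerates *every* embedding of every pattern
by backtracking over the molecular graph, then collapses embeddings
that cover the same atom and bond sets (the twelve automorphic images
of benzene in benzene are one match; the two benzene matches in
biphenyl are kept separate).  Order is deterministic: collection order,
then the lexicographically smallest atom tuple.

Before full matching, a cheap screen discards pattern/molecule pairs
that cannot match.  A pattern's prefilter signature is a *sound lower
bound* derived by normalizing each atom expression over a finite
feature space: minimum heavy atoms, per-element minimum counts (only
for atoms forced to a single element — a halogen list `[F,Cl,Br,I]`
contributes nothing), and minimum ring/aromatic atom counts.
Soundness, not tightness, is the contract: annotation with and without
the prefilter is asserted equal over the whole toy corpus, and every
skipped pair is re-checked to have zero matches by exhaustive search.

Compiled patterns are cached per SMARTS text for multi-molecule
queries; the cache is a pure optimization asserted to have no semantic
effect.

## Overshadowing

Match A overshadows match B when A describes a larger portion of the
molecule, or is more specific, while always containing what B matched.
Three rules are evaluated over all ordered pairs of deduplicated
matches of one molecule:

1. **Same atom set, fewer bonds** — the match with fewer bonds is
   hidden.  Hydrindane versus its cyclononane perimeter is the standard
   case: same nine atoms, ten bonds versus nine.
2. **Same atom set, equal bond count** — the *less specific* pattern is
   hidden if the specificity hierarchy says its pattern subsumes the
   other (trihalide is hidden behind trifluoromethyl).  Without a
   decided hierarchy relation, both stay visible.
3. **Proper containment** — B's atoms and bonds are a proper subset of
   A's (imidazole inside purine, hydroxy inside a carboxylic acid).

Matches covering different atoms never hide each other.  Suppression is
computed against *all* matches, not only visible ones, so the result is
a pure declarative function of the match set with no order dependence;
a match overshadowed only by an itself-overshadowed match stays
suppressed.  Equal-atom-set cases are tested before containment, so the
hydrindane/cyclononane pair reports `fewer_bonds` even though the
perimeter's bonds happen to be a subset.  Visible and suppressed
matches always partition the deduplicated match set, and the pairwise
overshadow relation is acyclic by construction (the first two rules
strictly decrease `(|atoms|, |bonds|)`; the third uses a DAG).

## The restricted subsumption engine

Deciding "every structure matched by S is matched by G" for full SMARTS
is hard; this package implements a deliberately restricted engine that
is *sound but incomplete*, with `unknown` as an explicit answer.

Atom expressions are normalized to allowed-tuple sets over a finite
feature space: supported elements {H, B, C, N, O, F, Si, P, S, Cl, Br,
I} × aromaticity × formal charge [−2, 2] × total hydrogens [0, 4] ×
heavy degree [0, 6] × ring membership (aromatic tuples imply ring
membership, matching the molecule model).  `G` subsumes `S` iff S's
tuple set is contained in G's, decided by enumeration.  Expressions
using anything outside the space — above all recursive environments —
are *opaque*: they compare equal only on identical text and otherwise
yield `unknown`.  Pattern-level subsumption then searches for an
injective, adjacency-preserving mapping of the general pattern's graph
into the specific one under atom- and bond-expression subsumption; for
equal-size patterns (the case overshadowing consumes) the mapping is a
bijection on atoms and bonds.

`build_hierarchy()` runs this over all ordered pairs, merges mutually
subsuming patterns into equivalence classes with a warning, closes the
edge set transitively, and guarantees a DAG.  `unknown` pairs get no
edge.  The design is fail-visible: the only possible consequence of
incompleteness is that an equally sized, less specific match is
*displayed* (e.g. a generic carbonyl next to an aldehyde match, whose
recursive environment blocks the decision), never that a match is
wrongly hidden.  `corpus_subsumption_audit()` re-checks every edge
empirically: each match of the specific pattern must contain a match of
the general one on a subset of its atoms (the same set when atom counts
are equal).

## Mining cyclic patterns from named SMILES

`extract_cyclic_patterns()` turns a table of (name, SMILES) records —
the shape of a chemical-database name dump — into a cyclic-pattern
collection:

1. parse (failures logged `unparseable`);
2. structure filters, in fixed order: `mixture` (multiple fragments),
   `radical`, `isotope`, `too_large` (more than 100 heavy atoms — 100
   itself passes);
3. pure-ring-system test: every atom in a ring or a terminal O/S on an
   exocyclic double bond to a ring atom, and every bond a ring bond or
   such a double bond (cyclohexanone passes, phenol and toluene do not);
4. name filters, in fixed order: `CID` prefix, `yl` suffix (residue
   names), more than four *numbers*, where a number is one maximal
   digit run — "1,2,3,4-tetrahydroquinazoline" has exactly four and is
   kept;
5. pattern construction and deduplication by canonical structure key
   (OpenBabel canonical SMILES, so Kekulé and aromatic spellings
   collapse), keeping the shortest passing name, ties broken
   lexicographically, preferring the "speakable" trivial name.

The decision log carries one reason per input record.  The pass/fail
partition is independent of rule order; only the reported reason
depends on it.  Whole molecules are selected as ring systems; ring
systems are not excised from larger molecules.  Empty or
whitespace-only names are rejected (`unparseable`): they cannot serve
communication.  Charged ring systems (pyrylium, N-methylated aromatic
cations) are retained, since several common named heterocyclic cations
would otherwise vanish.

Radical detection deserves a note: an uncharged bracket atom with an
*odd* valence deficit carries an unpaired electron and is rejected;
even deficits (carbene-like) are not treated as radicals, so an
isotope-labelled `[13C]` ring atom is rejected for its isotope, not
mis-reported as a radical.

## The molecule model and aromaticity

SMILES parsing covers the organic subset, bracket atoms (isotope,
charge, explicit H; stereo descriptors are read and ignored), branches,
ring closures including `%nn`, and dot-separated fragments.  Explicit
hydrogens fold into heavy-atom hydrogen counts, so atom indices (0-based,
parse order) always enumerate heavy atoms.  Implicit hydrogens follow
standard valence rules; aromatic atoms use their lowest valence.

Rings written in lowercase aromatic form are taken as written.  Rings
written in Kekulé form are aromatized by a Hückel model over 5-7
membered rings: every ring atom must be able to carry a p-orbital (at
most three connections for B/C/N/P, two for O/S), and contributions are
1 for an atom in a ring double bond, 0 for a carbon with an exocyclic
double bond, 2 for a lone-pair heteroatom or carbanion; the ring is
aromatic when the sum is 4n+2.  This is the model under which the
pyrimidinedione ring of caffeine *is* aromatic — necessary for the
pyrimidine and uracil patterns to match it, as they should.  Aromaticity
models differ between toolkits; all patterns shipped with this package
are written and tested against this one, and independent cross-checks
with OpenBabel in the test suite are restricted to structures on which
the models agree.

## Fixtures and what passing tests show

`toy_corpus()` provides the study conditions: 72 fixed molecules (the
worked examples plus at least one exemplar per seed pattern, each with
hand-derived expected visible names) and `n` randomized molecules from
a scaffold-plus-substituent grammar (10 ring scaffolds × 8 substituent
choices, all 80 combinations verified exhaustively), with expected
annotations derived by construction.  Corpus-scale checks run on 200
molecules at a fixed seed; the prefilter equivalence and subsumption
audits cover the same 200.  The generator emulates pharmacologically
typical scaffolds with single substituents; it does not emulate large
natural products, stereochemistry, tautomer proliferation, or charged
macrocycles, so passing tests certify the resolution logic, not
coverage of all chemistry.

## Known limitations

* The SMARTS subset excludes ring-size (`r`), multi-ring membership
  (`R2`…), valence (`v`), and disconnected patterns; unsupported
  primitives fail loudly at parse time rather than matching wrongly.
* Subsumption is incomplete by design; recursive environments compare
  by text only, so e.g. carbonyl/ketone at the same location are both
  shown (fail-visible).
* No stereochemistry-aware matching; no tautomer enumeration.
* SDF reading covers V2000 with charge codes and `M  CHG` lines;
  isotope annotations in SDF are not detected.
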