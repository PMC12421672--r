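# Substructure matching: enumeration of all embeddings of a pattern in a
# molecule, deduplication of automorphic embeddings, and the prefilter
# screen that skips pattern/molecule pairs that cannot possibly match.

# Enumerate embeddings of a compiled pattern graph in a molecule by
# backtracking along the pattern's DFS order.  `anchor` pins pattern atom 1
# to a given molecule atom (recursive SMARTS semantics).  Returns a list of
# integer mappings (pattern atom -> molecule atom, 1-based), or, with
# `first_only`, TRUE/FALSE.
.match_embeddings <- function(pg, mol, anchor = NULL, first_only = FALSE) {
  nmol <- mol$n
  feat <- .mol_atom_feat(mol)
  bfeat <- .mol_bond_feat(mol)

  allowed <- matrix(FALSE, nrow = pg$n, ncol = nmol)
  for (p in seq_len(pg$n))
    allowed[p, ] <- .eval_atom_expr(pg$atom_expr[[p]], feat, mol)

  nb <- length(pg$bond_from)
  bond_ok <- vector("list", nb)
  if (nb > 0L && length(mol$bond_from) > 0L) {
    for (k in seq_len(nb))
      bond_ok[[k]] <- .eval_bond_expr(pg$bond_expr[[k]], bfeat)
  } else if (nb > 0L) {
    for (k in seq_len(nb)) bond_ok[[k]] <- logical(0)
  }

  ord <- pg$dfs_order
  pos_of <- integer(pg$n); pos_of[ord] <- seq_len(pg$n)
  # pattern bonds from the atom at each position back to already-placed atoms
  back <- vector("list", pg$n)
  for (t in seq_len(pg$n)) back[[t]] <- list()
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      pa <- pg$bond_from[k]; pb <- pg$bond_to[k]
      if (pos_of[pa] < pos_of[pb]) { late <- pb; early <- pa } else { late <- pa; early <- pb }
      t <- pos_of[late]
      back[[t]][[length(back[[t]]) + 1L]] <- c(k, early)
    }
  }

  results <- list()
  found <- FALSE
  mapping <- integer(pg$n)
  used <- logical(nmol)

  mol_bond_between <- function(u, v) {
    m <- match(v, mol$adj[[u]])
    if (is.na(m)) NA_integer_ else mol$abond[[u]][m]
  }

  extend <- function(t) {
    if (found && first_only) return(invisible(NULL))
    if (t > pg$n) {
      if (first_only) { found <<- TRUE } else {
        results[[length(results) + 1L]] <<- mapping
      }
      return(invisible(NULL))
    }
    p <- ord[t]
    bedges <- back[[t]]
    if (length(bedges) == 0L) {
      cands <- if (t == 1L && !is.null(anchor)) {
        if (allowed[p, anchor]) anchor else integer(0)
      } else which(allowed[p, ] & !used)
    } else {
      first <- bedges[[1]]
      cands <- mol$adj[[mapping[first[2]]]]
      cands <- cands[!used[cands] & allowed[p, cands]]
      if (t == 1L) stop("internal: back edge at position 1")
    }
    for (cand in cands) {
      ok <- TRUE
      for (be in bedges) {
        k <- be[1]; early <- be[2]
        mb <- mol_bond_between(mapping[early], cand)
        if (is.na(mb) || !bond_ok[[k]][mb]) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[p] <<- cand; used[cand] <<- TRUE
      extend(t + 1L)
      used[cand] <<- FALSE
      if (found && first_only) return(invisible(NULL))
    }
    invisible(NULL)
  }

  # anchored matching pins pattern atom 1, which is always first in DFS order
  if (!is.null(anchor) && ord[1] != 1L) stop("internal: anchor atom not first in DFS order")
  extend(1L)
  if (first_only) found else results
}

.match_anchored <- function(pg, mol, ai) {
  .match_embeddings(pg, mol, anchor = ai, first_only = TRUE)
}

# Convert one embedding into a match record with 0-based sorted atom and
# bond index sets.
.embedding_to_match <- function(pg, mol, mapping, pattern_id,
                                pattern_name = NA_character_,
                                category = NA_character_) {
  atoms0 <- sort(mapping) - 1L
  nb <- length(pg$bond_from)
  if (nb > 0L) {
    u <- mapping[pg$bond_from]; v <- mapping[pg$bond_to]
    bonds <- cbind(pmin(u, v), pmax(u, v)) - 1L
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  list(pattern_id = pattern_id, pattern_name = pattern_name,
       category = category, atom_indices = atoms0, bonds = bonds,
       suppression = "none", suppressed_by = character(0))
}

.match_key <- function(m) {
  paste(m$pattern_id,
        paste(m$atom_indices, collapse = ","),
        paste(t(m$bonds), collapse = ","), sep = "|")
}

#' Summary counts of a molecule used by the prefilter screen
#'
#' @param m A `ca_mol` molecule (see [parse_smiles()]).
#' @return A list with `heavy_atom_count`, `element_histogram` (named
#'   integer vector), `ring_atom_count`, `aromatic_atom_count` and
#'   `ring_count` (smallest-set-of-smallest-rings size).
#' @examples
#' molecule_signature(parse_smiles("c1ccccc1"))
#' @export
molecule_signature <- function(m) {
  stopifnot(inherits(m, "ca_mol"))
  hist <- table(m$elem)
  list(
    heavy_atom_count = m$n,
    element_histogram = stats::setNames(as.integer(hist), names(hist)),
    ring_atom_count = sum(m$in_ring),
    aromatic_atom_count = sum(m$arom),
    ring_count = length(m$bond_from) - m$n + m$nfrag
  )
}

#' Decide whether a pattern could possibly match a molecule
#'
#' Sound necessary-condition screen: compares a pattern's prefilter
#' signature (see [compute_prefilter_signature()]) against a molecule's
#' signature.  Returns `FALSE` only when some requirement of the pattern
#' exceeds what the molecule provides; it never returns `FALSE` for a
#' pattern that has a match in the molecule.
#'
#' @param ps A prefilter signature.
#' @param ms A molecule signature from [molecule_signature()].
#' @return `TRUE` if full matching needs to run, `FALSE` if it can be
#'   skipped.
#' @export
prefilter_pass <- function(ps, ms) {
  if (ms$heavy_atom_count < ps$min_heavy_atoms) return(FALSE)
  if (ms$ring_atom_count < ps$min_ring_atoms) return(FALSE)
  if (ms$aromatic_atom_count < ps$min_aromatic_atoms) return(FALSE)
  req <- ps$required_elements
  if (length(req) > 0L) {
    for (el in names(req)) {
      have <- ms$element_histogram[el]
      if (is.na(have) || have < req[[el]]) return(FALSE)
    }
  }
  TRUE
}

#' Find all pattern matches of a collection in one molecule
#'
#' Enumerates every embedding of every pattern, collapses automorphic
#' duplicates (identical pattern, atom set and bond set), and returns the
#' matches in deterministic order: collection order first, then by the
#' lexicographically smallest atom-index tuple.  The match list is
#' identical with and without the prefilter; the prefilter only skips
#' pattern/molecule pairs that provably cannot match.
#'
#' @param m A `ca_mol` molecule.
#' @param collection A pattern collection (see [load_patterns()]).
#' @param use_prefilter Apply the element/ring-count screen before full
#'   matching (default `TRUE`).
#' @return A list of match records; each has `pattern_id`, `pattern_name`,
#'   `category`, `atom_indices` (0-based, sorted), `bonds` (two-column
#'   0-based matrix of unordered pairs), `suppression` (initialized to
#'   `"none"`) and `suppressed_by`.
#' @examples
#' pats <- seed_pattern_collection()
#' caf <- parse_smiles("CN1C=NC2=C1C(=O)N(C(=O)N2C)C")
#' length(find_pattern_matches(caf, pats))
#' @export
find_pattern_matches <- function(m, collection, use_prefilter = TRUE) {
  stopifnot(inherits(m, "ca_mol"), inherits(collection, "ca_pattern_collection"))
  ms <- if (use_prefilter) molecule_signature(m) else NULL
  out <- list()
  for (i in seq_along(collection$patterns)) {
    p <- collection$patterns[[i]]
    if (use_prefilter) {
      ps <- .cached_prefilter_signature(collection, i)
      if (!prefilter_pass(ps, ms)) next
    }
    pg <- parse_smarts(p$smarts)
    embs <- .match_embeddings(pg, m)
    if (length(embs) == 0L) next
    recs <- lapply(embs, .embedding_to_match, pg = pg, mol = m,
                   pattern_id = p$id, pattern_name = p$name,
                   category = p$category)
    recs <- dedupe_matches(recs)
    keys <- vapply(recs, function(r)
      paste(sprintf("%05d", r$atom_indices), collapse = ","), character(1))
    out <- c(out, recs[order(keys)])
  }
  out
}

#' Collapse duplicate matches
#'
#' Matches with identical pattern id, atom-index set and bond set (e.g. the
#' twelve automorphic embeddings of benzene in benzene) are collapsed to
#' one; matches differing in atoms or bonds are all kept.
#'
#' @param matches A list of match records.
#' @return The deduplicated list, first occurrence kept, order preserved.
#' @export
dedupe_matches <- function(matches) {
  if (length(matches) == 0L) return(list())
  keys <- vapply(matches, .match_key, character(1))
  matches[!duplicated(keys)]
}
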