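# Overshadowing: deciding which pattern matches are shown by default.
#
# A match A overshadows a match B when A describes a larger portion of the
# molecule while always containing the part B matched, or -- at the very
# same location -- when A's pattern is strictly more specific than B's.
# Overshadowed matches stay in the result with their suppression reason
# and are simply hidden from default output.

#' Does match `a` overshadow match `b`?
#'
#' Three rules, checked on matches from the same molecule:
#' \itemize{
#'   \item `fewer_bonds`: both cover the same atom set but `b` has fewer
#'     bonds (e.g. the cyclononane perimeter inside hydrindane).
#'   \item `hierarchy`: same atom set and equal bond count, and `b`'s
#'     pattern subsumes `a`'s in the specificity graph (`a` is strictly
#'     more specific, e.g. trifluoromethyl vs. trihalide).
#'   \item `match_containment`: `b`'s atoms and bonds are a proper subset
#'     of `a`'s (e.g. an imidazole match inside a purine match).
#' }
#' Matches covering different atoms never overshadow each other, and
#' equivalent patterns at the same location leave both matches visible.
#'
#' @param a,b Match records from [find_pattern_matches()].
#' @param h A `ca_hierarchy` (or `NULL`: the hierarchy rule never fires).
#' @return A list with `overshadows` (flag) and `reason` (one of
#'   `"none"`, `"match_containment"`, `"fewer_bonds"`, `"hierarchy"`).
#' @export
match_overshadows <- function(a, b, h = NULL) {
  if (identical(.match_key(a), .match_key(b)))
    stop("match_overshadows() requires two distinct matches")
  no <- list(overshadows = FALSE, reason = "none")
  na_a <- length(a$atom_indices); na_b <- length(b$atom_indices)
  nb_a <- nrow(a$bonds); nb_b <- nrow(b$bonds)
  if (na_b > na_a) return(no)
  atoms_sub <- all(b$atom_indices %in% a$atom_indices)
  if (!atoms_sub) return(no)
  if (na_b == na_a) {
    # same atom set
    if (nb_b < nb_a) return(list(overshadows = TRUE, reason = "fewer_bonds"))
    if (nb_b > nb_a) return(no)
    if (!is.null(h) && !.same_equivalence_class(h, a$pattern_id, b$pattern_id) &&
        .hierarchy_has_edge(h, b$pattern_id, a$pattern_id))
      return(list(overshadows = TRUE, reason = "hierarchy"))
    return(no)
  }
  # proper atom subset: bonds must be contained too
  if (nb_b > 0L) {
    akey <- paste(a$bonds[, 1], a$bonds[, 2])
    bkey <- paste(b$bonds[, 1], b$bonds[, 2])
    if (!all(bkey %in% akey)) return(no)
  }
  list(overshadows = TRUE, reason = "match_containment")
}

#' Resolve overshadowing over a molecule's deduplicated matches
#'
#' Evaluates [match_overshadows()] for every ordered pair and marks
#' suppressed matches with their reason and the ids of all overshadowing
#' patterns.  Suppression is computed against all matches, not only
#' visible ones: a match overshadowed by an itself-overshadowed match
#' stays suppressed.  Pure function of its inputs.
#'
#' @param matches Deduplicated match list from one molecule.
#' @param h A `ca_hierarchy` or `NULL`.
#' @return The match list with `suppression` and `suppressed_by` filled
#'   in; visible matches keep `suppression == "none"`.
#' @export
resolve_overshadowing <- function(matches, h = NULL) {
  n <- length(matches)
  if (n <= 1L) return(matches)
  for (j in seq_len(n)) {
    reasons <- character(0); by <- character(0)
    for (i in seq_len(n)) {
      if (i == j) next
      ov <- match_overshadows(matches[[i]], matches[[j]], h)
      if (ov$overshadows) {
        reasons <- c(reasons, ov$reason)
        by <- c(by, matches[[i]]$pattern_id)
      }
    }
    if (length(by) > 0L) {
      matches[[j]]$suppression <- reasons[1]
      matches[[j]]$suppressed_by <- unique(by)
    }
  }
  matches
}

#' Annotate one molecule with a pattern collection
#'
#' The full per-molecule pipeline: enumerate matches (with or without the
#' prefilter screen), deduplicate automorphic embeddings, and resolve
#' overshadowing against the supplied specificity hierarchy.  All matches,
#' visible and suppressed, are kept in the in-memory result; serialization
#' (see [write_annotations()]) omits suppressed ones unless asked.
#'
#' @param m A `ca_mol`, or a SMILES string.
#' @param c A `ca_pattern_collection`.
#' @param h A `ca_hierarchy` or `NULL`.
#' @param use_prefilter Apply the prefilter screen (default `TRUE`).
#' @return An object of class `ca_annotation`: `molecule_name` (`"No
#'   Name"` when absent), `smiles`, `matches`, `error` (`NULL`, or the
#'   parse/sanitize message for unusable input).
#' @examples
#' pats <- seed_pattern_collection()
#' h <- build_hierarchy(pats)
#' ann <- annotate_molecule("OC=O", pats, h)
#' vapply(visible_matches(ann), function(m) m$pattern_name, character(1))
#' @export
annotate_molecule <- function(m, c, h = NULL, use_prefilter = TRUE) {
  if (is.character(m)) {
    m <- tryCatch(parse_smiles(m), error = function(e) {
      structure(list(smiles = m, name = NA_character_,
                     error = conditionMessage(e)), class = "ca_badmol")
    })
  }
  if (inherits(m, "ca_badmol") || !is.null(m$error)) {
    return(structure(list(
      molecule_name = if (is.na(m$name)) "No Name" else m$name,
      smiles = m$smiles, matches = list(), error = m$error
    ), class = "ca_annotation"))
  }
  stopifnot(inherits(m, "ca_mol"))
  matches <- find_pattern_matches(m, c, use_prefilter = use_prefilter)
  matches <- dedupe_matches(matches)
  matches <- resolve_overshadowing(matches, h)
  structure(list(
    molecule_name = if (is.na(m$name)) "No Name" else m$name,
    smiles = m$smiles, matches = matches, error = NULL
  ), class = "ca_annotation")
}

#' Visible / suppressed partition of an annotation
#'
#' @param ann A `ca_annotation`.
#' @return The visible (`suppression == "none"`) or suppressed matches.
#' @export
visible_matches <- function(ann) {
  Filter(function(m) m$suppression == "none", ann$matches)
}

#' @rdname visible_matches
#' @export
suppressed_matches <- function(ann) {
  Filter(function(m) m$suppression != "none", ann$matches)
}

#' @export
print.ca_annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s  %s\n", x$molecule_name, x$smiles))
  if (!is.null(x$error)) {
    cat("  error:", x$error, "\n")
    return(invisible(x))
  }
  vis <- visible_matches(x); sup <- suppressed_matches(x)
  cat(sprintf("  %d match(es): %d visible, %d overshadowed\n",
              length(x$matches), length(vis), length(sup)))
  for (m in vis)
    cat(sprintf("    %-24s [%s]  atoms {%s}\n", m$pattern_name, m$category,
                paste(m$atom_indices, collapse = ",")))
  for (m in sup)
    cat(sprintf("    (%s overshadowed: %s by %s)\n", m$pattern_name,
                m$suppression, paste(m$suppressed_by, collapse = ",")))
  invisible(x)
}
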