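# Restricted SMARTS subsumption: decide when every structure matched by
# one pattern is necessarily matched by another (the second pattern is
# more general), and build the collection-wide specificity graph used to
# hide less specific matches at the same location.
#
# Atom and bond expressions are normalized to their allowed-tuple sets
# over a finite feature space (see pattern_store.R).  Expressions using
# primitives outside that space -- most importantly recursive
# environments -- are opaque: they compare equal only on identical text,
# and otherwise yield "unknown".  Unknown never creates an edge, so the
# only possible consequence of incompleteness is that an equally sized,
# less specific match is displayed, never that a match is wrongly hidden.

.BOND_FEATURE_SPACE <- expand.grid(type = c("1", "2", "3", "ar"),
                                   ring = c(FALSE, TRUE),
                                   stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE)

#' Tri-state subsumption between two atom expressions
#'
#' Decides whether every atom allowed by `specific` is allowed by
#' `general`, by enumeration over the finite feature space (supported
#' elements, aromaticity, charge \eqn{[-2,2]}, hydrogens \eqn{[0,4]},
#' heavy degree \eqn{[0,6]}, ring membership).  Expressions containing
#' recursive environments or other unsupported primitives are opaque:
#' identical raw text gives `"yes"`, anything else `"unknown"`.
#'
#' @param general,specific Atom expressions: raw bracket-content strings
#'   (e.g. `"F,Cl,Br,I"`), or AST nodes from a parsed pattern.
#' @return `"yes"`, `"no"`, or `"unknown"`.
#' @examples
#' atom_expr_subsumes("F,Cl,Br,I", "F")   # "yes"
#' atom_expr_subsumes("C", "CX3")         # "yes"
#' atom_expr_subsumes("CX3", "C")         # "no"
#' @export
atom_expr_subsumes <- function(general, specific) {
  gr <- if (is.character(general)) general else attr(general, "raw")
  sr <- if (is.character(specific)) specific else attr(specific, "raw")
  gast <- if (is.character(general)) .parse_atom_expr(general) else general
  sast <- if (is.character(specific)) .parse_atom_expr(specific) else specific
  g <- .atom_expr_tuples(gast)
  s <- .atom_expr_tuples(sast)
  if (g$opaque || s$opaque) {
    if (!is.null(gr) && !is.null(sr) && identical(gr, sr)) return("yes")
    return("unknown")
  }
  if (!any(s$allow & !g$allow)) "yes" else "no"
}

.bond_expr_tuples <- function(expr) {
  .eval_bond_expr(expr, .BOND_FEATURE_SPACE)
}

.bond_expr_subsumes <- function(general, specific) {
  g <- .bond_expr_tuples(general)
  s <- .bond_expr_tuples(specific)
  if (!any(s & !g)) "yes" else "no"
}

#' Tri-state subsumption between two patterns
#'
#' `"yes"` means every molecule (and location) matched by `specific` is
#' also matched by `general`: there is an injective mapping of the general
#' pattern's graph into the specific pattern's graph, preserving adjacency,
#' under which every mapped atom and bond expression of the general
#' pattern subsumes its image.  For patterns of equal atom and bond count
#' (the case consumed by overshadowing) the mapping is a bijection on
#' atoms and bonds.  This is a sound sufficient test: `"no"` is returned
#' when enumeration over the feature space disproves every candidate
#' mapping, `"unknown"` when opaque expressions prevent a decision.
#' Identical SMARTS text is always `"yes"`.
#'
#' @param general,specific `ca_pattern` objects (or SMARTS strings).
#' @return `"yes"`, `"no"`, or `"unknown"`.
#' @examples
#' pattern_subsumes("[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]",
#'                  "[CX4](F)(F)F")   # "yes": a trifluoromethyl is a trihalide
#' @export
pattern_subsumes <- function(general, specific) {
  gs <- if (inherits(general, "ca_pattern")) general$smarts else general
  ss <- if (inherits(specific, "ca_pattern")) specific$smarts else specific
  if (identical(gs, ss)) return("yes")
  g <- parse_smarts(gs)
  s <- parse_smarts(ss)
  if (g$n > s$n || length(g$bond_from) > length(s$bond_from)) return("no")

  # pairwise atom-expression subsumption, with opacity tracking
  amat <- matrix("no", nrow = g$n, ncol = s$n)
  any_unknown <- FALSE
  for (i in seq_len(g$n)) {
    ge <- g$atom_expr[[i]]
    attr(ge, "raw") <- g$atom_raw[i]
    for (j in seq_len(s$n)) {
      se <- s$atom_expr[[j]]
      attr(se, "raw") <- s$atom_raw[j]
      amat[i, j] <- atom_expr_subsumes(ge, se)
      if (amat[i, j] == "unknown") any_unknown <- TRUE
    }
  }

  # bond lookup in the specific pattern
  skey <- paste(pmin(s$bond_from, s$bond_to), pmax(s$bond_from, s$bond_to))
  ord <- g$dfs_order
  pos_of <- integer(g$n); pos_of[ord] <- seq_len(g$n)
  back <- vector("list", g$n)
  for (t in seq_len(g$n)) back[[t]] <- list()
  for (k in seq_along(g$bond_from)) {
    pa <- g$bond_from[k]; pb <- g$bond_to[k]
    if (pos_of[pa] < pos_of[pb]) { late <- pb; early <- pa } else { late <- pa; early <- pb }
    back[[pos_of[late]]][[length(back[[pos_of[late]]]) + 1L]] <- c(k, early)
  }
  s_adj <- vector("list", s$n)
  for (a in seq_len(s$n)) s_adj[[a]] <- integer(0)
  for (k in seq_along(s$bond_from)) {
    s_adj[[s$bond_from[k]]] <- c(s_adj[[s$bond_from[k]]], s$bond_to[k])
    s_adj[[s$bond_to[k]]] <- c(s_adj[[s$bond_to[k]]], s$bond_from[k])
  }

  mapping <- integer(g$n); used <- logical(s$n)
  found <- FALSE
  extend <- function(t) {
    if (found) return(invisible(NULL))
    if (t > g$n) { found <<- TRUE; return(invisible(NULL)) }
    p <- ord[t]
    bedges <- back[[t]]
    cands <- if (length(bedges) == 0L) which(amat[p, ] == "yes" & !used)
             else {
               cc <- s_adj[[mapping[bedges[[1]][2]]]]
               cc[!used[cc] & amat[p, cc] == "yes"]
             }
    for (cand in cands) {
      ok <- TRUE
      for (be in bedges) {
        k <- be[1]; early <- be[2]
        sb <- match(paste(min(mapping[early], cand), max(mapping[early], cand)), skey)
        if (is.na(sb) ||
            .bond_expr_subsumes(g$bond_expr[[k]], s$bond_expr[[sb]]) != "yes") {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      mapping[p] <<- cand; used[cand] <<- TRUE
      extend(t + 1L)
      used[cand] <<- FALSE
      if (found) return(invisible(NULL))
    }
    invisible(NULL)
  }
  extend(1L)
  if (found) "yes" else if (any_unknown) "unknown" else "no"
}

#' Build the specificity graph of a pattern collection
#'
#' Runs [pattern_subsumes()] over all ordered pattern pairs.  A decided
#' `"yes"` with distinct patterns adds a directed edge general -> specific.
#' Mutually subsuming pairs (equivalent patterns) are merged into
#' equivalence classes with a warning and contribute no edges between
#' their members; the class-level graph is closed transitively and is
#' acyclic by construction.
#'
#' @param c A `ca_pattern_collection`.
#' @return An object of class `ca_hierarchy`: `edges` (data frame with
#'   columns `general`, `specific`, transitively closed), and
#'   `equivalence_classes` (list of id groups with more than one member).
#' @export
build_hierarchy <- function(c) {
  stopifnot(inherits(c, "ca_pattern_collection"))
  ids <- vapply(c$patterns, function(p) p$id, character(1))
  np <- length(ids)
  yes <- matrix(FALSE, np, np, dimnames = list(ids, ids))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i == j) next
    if (pattern_subsumes(c$patterns[[i]], c$patterns[[j]]) == "yes")
      yes[i, j] <- TRUE
  }

  mutual <- yes & t(yes)
  classes <- list()
  if (any(mutual)) {
    gm <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
    comp <- igraph::components(gm)
    for (cid in seq_len(comp$no)) {
      members <- ids[comp$membership == cid]
      if (length(members) > 1L) classes[[length(classes) + 1L]] <- members
    }
    if (length(classes) > 0L)
      warning("mutually subsuming (equivalent) pattern groups: ",
              paste(vapply(classes, paste, character(1), collapse = " ~ "),
                    collapse = "; "))
    yes[mutual] <- FALSE
  }

  # transitive closure (Warshall on a small boolean matrix)
  for (k in seq_len(np)) {
    yk <- yes[, k]
    if (any(yk)) yes[yk, ] <- yes[yk, , drop = FALSE] | rep(yes[k, ], each = sum(yk))
  }
  diag(yes) <- FALSE

  idx <- which(yes, arr.ind = TRUE)
  edges <- data.frame(general = ids[idx[, 1]], specific = ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$general, edges$specific), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, equivalence_classes = classes, ids = ids),
            class = "ca_hierarchy")
}

#' @export
print.ca_hierarchy <- function(x, ...) {
  cat(sprintf("<pattern hierarchy> %d subsumption edge(s), %d equivalence class(es)\n",
              nrow(x$edges), length(x$equivalence_classes)))
  invisible(x)
}

.hierarchy_has_edge <- function(h, general_id, specific_id) {
  if (is.null(h) || nrow(h$edges) == 0L) return(FALSE)
  any(h$edges$general == general_id & h$edges$specific == specific_id)
}

.same_equivalence_class <- function(h, id_a, id_b) {
  if (is.null(h) || length(h$equivalence_classes) == 0L) return(FALSE)
  any(vapply(h$equivalence_classes,
             function(cl) id_a %in% cl && id_b %in% cl, logical(1)))
}

#' Save / load a hierarchy as JSON
#'
#' The serialized form is a JSON array of `{"general": id, "specific": id}`
#' objects (equivalence classes are stored under a separate key).
#'
#' @param h A `ca_hierarchy`.
#' @param path File path.
#' @export
save_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "ca_hierarchy"))
  obj <- list(
    edges = lapply(seq_len(nrow(h$edges)), function(i)
      list(general = h$edges$general[i], specific = h$edges$specific[i])),
    equivalence_classes = h$equivalence_classes
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(NULL)
}

#' @rdname save_hierarchy
#' @export
load_hierarchy <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  edges <- if (length(obj$edges) == 0L) {
    data.frame(general = character(0), specific = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      general = vapply(obj$edges, function(e) e$general, character(1)),
      specific = vapply(obj$edges, function(e) e$specific, character(1)),
      stringsAsFactors = FALSE)
  }
  classes <- lapply(obj$equivalence_classes, function(cl)
    vapply(cl, identity, character(1)))
  structure(list(edges = edges, equivalence_classes = classes,
                 ids = unique(c(edges$general, edges$specific))),
            class = "ca_hierarchy")
}

#' Empirical soundness audit of a hierarchy over a molecule corpus
#'
#' For every edge (general -> specific) and every corpus molecule, checks
#' that every match of the specific pattern contains a match of the
#' general pattern on a subset of its atoms (the same atom set when the
#' two patterns have equal atom counts).  An empty violation table means
#' the hierarchy is sound on the corpus.
#'
#' @param c A `ca_pattern_collection`.
#' @param corpus A list of `ca_mol` molecules.
#' @param h A `ca_hierarchy`; built from `c` when omitted.
#' @return A list with `violations` (data frame: `general`, `specific`,
#'   `molecule`, `atoms`), `n_edges`, `n_molecules`, `n_checked`.
#' @export
corpus_subsumption_audit <- function(c, corpus, h = NULL) {
  stopifnot(inherits(c, "ca_pattern_collection"))
  if (is.null(h)) h <- build_hierarchy(c)
  ids <- vapply(c$patterns, function(p) p$id, character(1))
  viol <- list()
  n_checked <- 0L
  if (nrow(h$edges) > 0L) {
    involved <- unique(c(h$edges$general, h$edges$specific))
    sub <- pattern_collection(c$patterns[match(involved, ids)])
    for (mi in seq_along(corpus)) {
      mol <- corpus[[mi]]
      matches <- find_pattern_matches(mol, sub)
      by_id <- split(matches, vapply(matches, function(m) m$pattern_id, character(1)))
      for (ei in seq_len(nrow(h$edges))) {
        gen <- h$edges$general[ei]; spec <- h$edges$specific[ei]
        smatches <- by_id[[spec]]
        if (is.null(smatches)) next
        gmatches <- by_id[[gen]]
        for (sm in smatches) {
          n_checked <- n_checked + 1L
          ok <- any(vapply(gmatches, function(gm)
            all(gm$atom_indices %in% sm$atom_indices), logical(1)))
          if (!isTRUE(ok)) {
            nm <- if (is.na(mol$name)) mol$smiles else mol$name
            viol[[length(viol) + 1L]] <- data.frame(
              general = gen, specific = spec, molecule = nm,
              atoms = paste(sm$atom_indices, collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  violations <- if (length(viol) > 0L) do.call(rbind, viol) else
    data.frame(general = character(0), specific = character(0),
               molecule = character(0), atoms = character(0),
               stringsAsFactors = FALSE)
  list(violations = violations, n_edges = nrow(h$edges),
       n_molecules = length(corpus), n_checked = n_checked)
}
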