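# Cyclic-pattern mining: select pure ring-system molecules from a table of
# named SMILES, filter by structure and name, and emit substitution-
# tolerant cyclic patterns.

.FILTER_REASONS <- c("ok", "not_ring_system", "radical", "isotope",
                     "too_large", "mixture", "name_numbers",
                     "name_yl_suffix", "name_cid_prefix", "unparseable")

.decision <- function(reason) {
  stopifnot(reason %in% .FILTER_REASONS)
  list(passed = reason == "ok", reason = reason)
}

#' Is a molecule a pure ring system?
#'
#' `TRUE` iff every atom is in a ring or is a terminal oxygen/sulfur
#' attached to a ring atom by an exocyclic double bond, and every bond is
#' a ring bond or such an exocyclic double bond.  Cyclohexanone qualifies;
#' toluene (methyl carbon) and phenol (single-bonded hydroxyl) do not.
#'
#' @param m A `ca_mol` (assumed a single fragment; see
#'   [passes_structure_filters()] for the mixture check).
#' @return Logical flag.
#' @export
is_ring_system_molecule <- function(m) {
  stopifnot(inherits(m, "ca_mol"))
  if (length(m$bond_from) == 0L) return(FALSE)
  exo_ok <- logical(m$n)   # terminal O/S on an exocyclic double bond
  bond_ok <- m$bond_ring
  for (k in seq_along(m$bond_from)) {
    if (bond_ok[k]) next
    u <- m$bond_from[k]; v <- m$bond_to[k]
    if (m$bond_order[k] == 2L && !m$bond_arom[k]) {
      term <- NULL; ringat <- NULL
      if (m$elem[u] %in% c("O", "S") && m$degree[u] == 1L && m$in_ring[v]) {
        term <- u; ringat <- v
      } else if (m$elem[v] %in% c("O", "S") && m$degree[v] == 1L && m$in_ring[u]) {
        term <- v; ringat <- u
      }
      if (!is.null(term)) { exo_ok[term] <- TRUE; bond_ok[k] <- TRUE }
    }
  }
  all(m$in_ring | exo_ok) && all(bond_ok)
}

#' Structure filters for cyclic-pattern extraction
#'
#' Skips molecules that cannot serve as communication patterns: mixtures
#' (multiple fragments), molecules with radical electrons (odd valence
#' deficit on an uncharged bracket atom), specified isotopes, or more than
#' 100 heavy atoms.  The first failing rule, in that fixed order, gives
#' the reason.
#'
#' @param m A `ca_mol`, or a SMILES string (unparseable input gives reason
#'   `"unparseable"`).
#' @return A filter decision: list with `passed` and `reason`.
#' @export
passes_structure_filters <- function(m) {
  if (is.character(m)) {
    m <- tryCatch(parse_smiles(m), error = function(e) NULL)
    if (is.null(m)) return(.decision("unparseable"))
  }
  stopifnot(inherits(m, "ca_mol"))
  if (m$nfrag > 1L) return(.decision("mixture"))
  if (any(m$radical)) return(.decision("radical"))
  if (any(m$isotope > 0L) || isTRUE(m$h_isotope)) return(.decision("isotope"))
  if (m$n > 100L) return(.decision("too_large"))
  .decision("ok")
}

#' Name filters for cyclic-pattern extraction
#'
#' Rejects names unusable for communication, in fixed order: names
#' beginning with the identifier `"CID"`, names ending with `"yl"`
#' (residues), and names containing more than four numbers, where a
#' number is one maximal run of consecutive digits (so
#' "1,2,3,4-tetrahydroquinazoline" has exactly four and passes).  Empty
#' or whitespace-only names are rejected with reason `"unparseable"`.
#'
#' @param name A character scalar.
#' @return A filter decision: list with `passed` and `reason`.
#' @examples
#' passes_name_filters("benzene")$passed                       # TRUE
#' passes_name_filters("phenyl")$reason                        # name_yl_suffix
#' passes_name_filters("1,2,3,4-tetrahydroquinazoline")$passed # TRUE
#' @export
passes_name_filters <- function(name) {
  if (is.null(name) || is.na(name) || !nzchar(trimws(name)))
    return(.decision("unparseable"))
  name <- trimws(name)
  if (startsWith(name, "CID")) return(.decision("name_cid_prefix"))
  if (endsWith(name, "yl")) return(.decision("name_yl_suffix"))
  runs <- gregexpr("[0-9]+", name)[[1]]
  n_runs <- if (runs[1] == -1L) 0L else length(runs)
  if (n_runs > 4L) return(.decision("name_numbers"))
  .decision("ok")
}

#' Build a substitution-tolerant SMARTS pattern from a ring system
#'
#' Constrains, per atom: atomic number, aromaticity and formal charge; per
#' bond: aromatic vs. bond order.  No hydrogen-count or degree constraint
#' is placed on ring atoms, so any substituted variant of the cycle still
#' matches (the xanthine scaffold pattern matches caffeine).  Terminal
#' exocyclic O/S keep a connectivity-1 constraint and their double bond,
#' so a cyclohexanone pattern does not match cyclohexanol.
#'
#' @param m A `ca_mol` for which [is_ring_system_molecule()] is `TRUE`.
#' @return A SMARTS string that matches `m` itself with a match covering
#'   all of its atoms.
#' @export
ring_pattern_from_molecule <- function(m) {
  stopifnot(inherits(m, "ca_mol"))
  if (!is_ring_system_molecule(m))
    stop("molecule is not a pure ring system")

  atom_token <- function(a) {
    num <- .ATOMIC_NUM[[m$elem[a]]]
    if (is.null(num) || is.na(num)) stop("unsupported element ", m$elem[a])
    exo <- !m$in_ring[a]
    parts <- paste0("#", num)
    parts <- c(parts, if (exo) "X1" else if (m$arom[a]) "a" else "A")
    if (m$charge[a] != 0L) {
      ch <- m$charge[a]
      parts <- c(parts, if (ch > 0) paste0("+", if (ch > 1) ch else "")
                        else paste0("-", if (ch < -1) -ch else ""))
    }
    paste0("[", paste(parts, collapse = ";"), "]")
  }
  bond_token <- function(k) {
    if (m$bond_arom[k]) ":" else switch(m$bond_order[k], "-", "=", "#")
  }

  # DFS spanning tree; non-tree edges become ring closures
  n <- m$n
  st <- new.env(parent = emptyenv())
  st$visited <- logical(n)
  st$closure_of <- vector("list", n)   # atom -> list of c(number, bond idx)
  st$bond_used <- logical(length(m$bond_from))
  st$counter <- 0L
  st$children <- vector("list", n)

  walk <- function(a) {
    st$visited[a] <- TRUE
    ks <- m$abond[[a]]; nbs <- m$adj[[a]]
    for (t in seq_along(nbs)) {
      k <- ks[t]; b <- nbs[t]
      if (st$bond_used[k]) next
      st$bond_used[k] <- TRUE
      if (st$visited[b]) {
        st$counter <- st$counter + 1L
        st$closure_of[[a]] <- c(st$closure_of[[a]], list(c(st$counter, k)))
        st$closure_of[[b]] <- c(st$closure_of[[b]], list(c(st$counter, k)))
      } else {
        st$children[[a]] <- c(st$children[[a]], list(c(b, k)))
        walk(b)
      }
    }
  }
  walk(1L)

  num_str <- function(num) if (num < 10L) as.character(num) else sprintf("%%%02d", num)
  emit <- function(a) {
    out <- atom_token(a)
    for (cl in st$closure_of[[a]])
      out <- paste0(out, bond_token(cl[2]), num_str(cl[1]))
    ch <- st$children[[a]]
    if (length(ch) > 0L) {
      for (t in seq_along(ch)) {
        piece <- paste0(bond_token(ch[[t]][2]), emit(ch[[t]][1]))
        out <- paste0(out, if (t < length(ch)) paste0("(", piece, ")") else piece)
      }
    }
    out
  }
  emit(1L)
}

#' Canonical structure key for deduplication
#'
#' Canonical SMILES computed with OpenBabel (via ChemmineOB), so Kekulé
#' and aromatic spellings of the same ring system collapse to one key.
#'
#' @param smiles A SMILES string.
#' @return A character scalar key.
#' @export
canonical_structure_key <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) NA_character_)
  out <- if (is.na(out)) NA_character_ else trimws(out)
  if (is.na(out) || !nzchar(out)) smiles else out
}

#' Extract cyclic patterns from a table of named SMILES
#'
#' The full mining pipeline: parse, structure filters, ring-system test,
#' name filters, pattern construction, deduplication by canonical
#' structure key.  One pattern is emitted per distinct ring system; when
#' several passing records share a structure, the shortest passing name
#' wins (ties broken lexicographically).  The decision log has one entry
#' per input record.
#'
#' @param records A data frame with columns `name` and `smiles` (a column
#'   `source_line` is honored if present, else row numbers are used).
#' @return A list with `collection` (a `ca_pattern_collection`, category
#'   `"cyclic"`) and `log` (data frame: `source_line`, `name`, `passed`,
#'   `reason`).
#' @export
extract_cyclic_patterns <- function(records) {
  stopifnot(is.data.frame(records), all(c("name", "smiles") %in% names(records)))
  nrec <- nrow(records)
  src <- if ("source_line" %in% names(records)) records$source_line else seq_len(nrec)

  reasons <- character(nrec)
  keys <- rep(NA_character_, nrec)
  mols <- vector("list", nrec)

  for (i in seq_len(nrec)) {
    sm <- records$smiles[i]
    if (is.na(sm) || !nzchar(trimws(sm))) { reasons[i] <- "unparseable"; next }
    mol <- tryCatch(parse_smiles(sm), error = function(e) NULL)
    if (is.null(mol)) { reasons[i] <- "unparseable"; next }
    d <- passes_structure_filters(mol)
    if (!d$passed) { reasons[i] <- d$reason; next }
    if (!is_ring_system_molecule(mol)) { reasons[i] <- "not_ring_system"; next }
    d <- passes_name_filters(records$name[i])
    if (!d$passed) { reasons[i] <- d$reason; next }
    reasons[i] <- "ok"
    keys[i] <- canonical_structure_key(sm)
    mols[[i]] <- mol
  }

  ok <- which(reasons == "ok")
  patterns <- list()
  if (length(ok) > 0L) {
    first_of_key <- ok[!duplicated(keys[ok])]
    ordinal <- 0L
    for (i in first_of_key) {
      members <- ok[keys[ok] == keys[i]]
      nms <- trimws(records$name[members])
      best <- nms[order(nchar(nms), nms)][1]
      ordinal <- ordinal + 1L
      patterns[[ordinal]] <- new_pattern(
        id = sprintf("%04d-%s", ordinal, .slug(best)),
        smarts = ring_pattern_from_molecule(mols[[i]]),
        name = best, category = "cyclic")
    }
  }

  log <- data.frame(source_line = src, name = records$name,
                    passed = reasons == "ok", reason = reasons,
                    stringsAsFactors = FALSE)
  list(collection = pattern_collection(patterns, version = "extracted"),
       log = log)
}
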