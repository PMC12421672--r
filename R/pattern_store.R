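# Pattern collections: the data model for named SMARTS patterns, flat-file
# serialization (JSON / TSV), validation, and prefilter signatures.

.CATEGORIES <- c("functional_group", "cyclic", "biological")

#' Create a single named pattern
#'
#' @param id Stable unique identifier within a collection.
#' @param smarts SMARTS expression (must parse under the supported subset).
#' @param name Human-readable substructure name.
#' @param category One of `"functional_group"`, `"cyclic"`, `"biological"`.
#' @return An object of class `ca_pattern` with `atom_count` and
#'   `bond_count` computed from the SMARTS graph.
#' @export
new_pattern <- function(id, smarts, name, category) {
  if (!is.character(category) || length(category) != 1L ||
      !(category %in% .CATEGORIES))
    stop("invalid category '", category, "' (must be one of ",
         paste(.CATEGORIES, collapse = ", "), ")")
  pg <- parse_smarts(smarts)
  structure(list(id = as.character(id), smarts = smarts,
                 name = as.character(name), category = category,
                 atom_count = pg$n, bond_count = length(pg$bond_from)),
            class = "ca_pattern")
}

#' Assemble patterns into a collection
#'
#' @param patterns A list of `ca_pattern` objects; iteration order is
#'   preserved everywhere (file order).
#' @param version Free-text provenance string.
#' @return An object of class `ca_pattern_collection`.
#' @export
pattern_collection <- function(patterns, version = "") {
  ids <- vapply(patterns, function(p) p$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate pattern id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- structure(list(patterns = patterns, version = version),
                   class = "ca_pattern_collection")
  attr(out, "cache") <- new.env(parent = emptyenv())
  out
}

#' @export
print.ca_pattern_collection <- function(x, ...) {
  cats <- table(factor(vapply(x$patterns, function(p) p$category, character(1)),
                       levels = .CATEGORIES))
  cat(sprintf("<pattern collection> %d patterns (%s)\n", length(x$patterns),
              paste(sprintf("%s: %d", names(cats), cats), collapse = ", ")))
  if (nzchar(x$version)) cat("  version:", x$version, "\n")
  invisible(x)
}

.slug <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "-", s)
  gsub("^-+|-+$", "", s)
}

#' Load a pattern collection from JSON or TSV
#'
#' JSON files hold an array of objects with keys `id` (optional), `smarts`,
#' `name`, `category`.  TSV files hold three tab-separated columns
#' (smarts, name, category), UTF-8, no quoting; tabs inside fields are a
#' validation error.  Missing ids are generated as zero-padded ordinal plus
#' a slug of the name.  Every SMARTS is parsed on load; atom and bond
#' counts are taken from the parsed graph.
#'
#' @param path File to read.
#' @param format `"json"`, `"tsv"`, or `"auto"` (by file extension).
#' @param permissive If `TRUE`, invalid records are skipped with a warning
#'   instead of failing the load.
#' @return A `ca_pattern_collection`.
#' @export
load_patterns <- function(path, format = c("auto", "json", "tsv"),
                          permissive = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read pattern file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"

  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    recs <- lapply(raw, function(r)
      list(id = r$id, smarts = r$smarts, name = r$name, category = r$category))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 3L)
        return(structure(list(msg = sprintf(
          "expected 3 tab-separated fields, got %d", length(f))),
          class = "ca_badrec"))
      list(id = NULL, smarts = f[1], name = f[2], category = f[3])
    })
  }

  patterns <- list()
  errors <- character(0)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (inherits(r, "ca_badrec")) {
      errors <- c(errors, sprintf("record %d: %s", i, r$msg))
      next
    }
    id <- if (is.null(r$id)) sprintf("%04d-%s", i, .slug(r$name)) else r$id
    p <- tryCatch(new_pattern(id, r$smarts, r$name, r$category),
                  error = function(e) {
                    errors <<- c(errors, sprintf("record %d (%s): %s", i,
                                                 r$name, conditionMessage(e)))
                    NULL
                  })
    if (!is.null(p)) patterns[[length(patterns) + 1L]] <- p
  }
  if (length(errors) > 0L) {
    msg <- paste(errors, collapse = "\n  ")
    if (permissive) warning("skipped invalid pattern record(s):\n  ", msg)
    else stop("invalid pattern record(s):\n  ", msg)
  }
  pattern_collection(patterns, version = basename(path))
}

#' Save a pattern collection to JSON or TSV
#'
#' Loading the written file reproduces ids, SMARTS, names and categories in
#' order (for TSV, ids are re-derived and reproduce the auto-generated
#' ones).  Fields containing tabs or newlines cannot be represented in the
#' TSV dialect and raise an error.
#'
#' @param c A `ca_pattern_collection`.
#' @param path Output file path.
#' @param format `"json"`, `"tsv"`, or `"auto"` (by file extension).
#' @export
save_patterns <- function(c, path, format = c("auto", "json", "tsv")) {
  stopifnot(inherits(c, "ca_pattern_collection"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    recs <- lapply(c$patterns, function(p)
      list(id = p$id, smarts = p$smarts, name = p$name, category = p$category))
    writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE), path)
  } else {
    for (p in c$patterns) {
      if (grepl("[\t\n]", p$smarts) || grepl("[\t\n]", p$name) ||
          grepl("[\t\n]", p$category))
        stop("field contains a tab or newline; not representable as TSV (pattern ",
             p$id, ")")
    }
    lines <- vapply(c$patterns, function(p)
      paste(p$smarts, p$name, p$category, sep = "\t"), character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(NULL)
}

# --- prefilter signatures ----------------------------------------------------

# Finite atom feature space over which SMARTS atom expressions are
# normalized: supported elements x aromaticity x formal charge [-2,2] x
# total H [0,4] x heavy degree [0,6] x ring membership.
.SUPPORTED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                         "Cl", "Br", "I")
.feature_space_env <- new.env(parent = emptyenv())
.atom_feature_space <- function() {
  sp <- get0("space", envir = .feature_space_env)
  if (!is.null(sp)) return(sp)
  sp <- expand.grid(elem = .SUPPORTED_ELEMENTS, arom = c(FALSE, TRUE),
                    charge = -2:2, h = 0:4, deg = 0:6, ring = c(FALSE, TRUE),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sp <- sp[!(sp$arom & !sp$ring), , drop = FALSE]  # aromatic implies in-ring
  rownames(sp) <- NULL
  sp$iso <- 0L
  assign("space", sp, envir = .feature_space_env)
  sp
}

# Allowed-tuple set of one atom expression over the feature space, as a
# logical vector; `flags$opaque` is set when the expression uses recursive
# environments or other primitives outside the finite space.
.atom_expr_tuples <- function(expr) {
  flags <- new.env(parent = emptyenv())
  flags$opaque <- FALSE
  allow <- .eval_atom_expr(expr, .atom_feature_space(), mol = NULL, flags = flags)
  list(allow = allow, opaque = flags$opaque)
}

#' Compute the prefilter signature of a pattern
#'
#' Derives a sound lower bound on what any matching molecule must contain:
#' the number of heavy atoms, per-element minimum counts (only from atoms
#' whose expression forces a single element in every disjunct; halogen
#' lists and similar disjunctions contribute nothing), and the number of
#' atoms forced to be in a ring or aromatic.  Recursive environments
#' contribute nothing beyond the rest of their expression.
#'
#' @param p A `ca_pattern`, or a SMARTS string.
#' @return A list with `min_heavy_atoms`, `required_elements` (named
#'   integer vector), `min_ring_atoms`, `min_aromatic_atoms`.
#' @examples
#' compute_prefilter_signature("c1ccncc1")
#' @export
compute_prefilter_signature <- function(p) {
  smarts <- if (inherits(p, "ca_pattern")) p$smarts else p
  pg <- parse_smarts(smarts)
  forced_elem <- character(0)
  ring_forced <- 0L; arom_forced <- 0L
  for (a in seq_len(pg$n)) {
    tt <- .atom_expr_tuples(pg$atom_expr[[a]])
    allow <- tt$allow
    if (!any(allow)) next   # unsatisfiable over the space: no requirement
    sp <- .atom_feature_space()
    els <- unique(sp$elem[allow])
    if (length(els) == 1L && els != "H") forced_elem <- c(forced_elem, els)
    if (all(sp$ring[allow])) ring_forced <- ring_forced + 1L
    if (all(sp$arom[allow])) arom_forced <- arom_forced + 1L
  }
  req <- if (length(forced_elem) > 0L) {
    tb <- table(forced_elem)
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  list(min_heavy_atoms = pg$n, required_elements = req,
       min_ring_atoms = ring_forced, min_aromatic_atoms = arom_forced)
}

.cached_prefilter_signature <- function(collection, i) {
  cache <- attr(collection, "cache")
  if (is.null(cache)) return(compute_prefilter_signature(collection$patterns[[i]]))
  key <- paste0("psig_", i)
  hit <- get0(key, envir = cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  sig <- compute_prefilter_signature(collection$patterns[[i]])
  assign(key, sig, envir = cache)
  sig
}
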