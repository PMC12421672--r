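# Molecule readers (SMILES string / SMILES file / SDF) and the JSON
# annotation writer.

#' Read molecules from a SMILES string, SMILES file, or SDF file
#'
#' A SMILES string may hold several newline-separated entries; in each,
#' the first whitespace-separated token is the SMILES and any remaining
#' text is the molecule name (a line whose tokens all parse as SMILES is
#' read as multiple unnamed molecules).  A SMILES file has one record per
#' line, `SMILES<whitespace>name...`.  An SDF (V2000) file takes the name
#' from the title line, falling back to a `name` data field.  Unparseable
#' records become error-carrying records rather than aborting the batch;
#' [annotate_molecule()] turns them into error annotations.
#'
#' @param source A SMILES string, or a path to a SMILES or SDF file.
#' @param format `"auto"` (file by extension, else literal string),
#'   `"smiles"`, `"smiles_file"`, or `"sdf"`.
#' @return A list of `ca_mol` records (unparseable entries are `ca_badmol`
#'   records carrying `smiles`, `name`, `error`).
#' @examples
#' read_molecules("CN1C=NC2=C1C(=O)N(C(=O)N2C)C caffeine")
#' @export
read_molecules <- function(source, format = c("auto", "smiles", "smiles_file", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(source)) {
      if (grepl("\\.sdf?$|\\.mol$", source, ignore.case = TRUE)) "sdf"
      else "smiles_file"
    } else "smiles"
  }
  if (format == "sdf") return(.read_sdf(source))
  lines <- if (format == "smiles_file") {
    if (!file.exists(source)) stop("cannot read file: ", source)
    readLines(source, warn = FALSE)
  } else {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    tokens <- strsplit(ln, "[[:space:]]+")[[1]]
    mols <- .parse_line_tokens(tokens)
    out <- c(out, mols)
  }
  out
}

.try_parse <- function(smiles, name = NA_character_) {
  tryCatch(parse_smiles(smiles, name = name), error = function(e)
    structure(list(smiles = smiles, name = name,
                   error = conditionMessage(e)), class = "ca_badmol"))
}

.parse_line_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(list())
  if (length(tokens) == 1L) return(list(.try_parse(tokens[1])))
  # all tokens parse as SMILES -> multiple unnamed molecules on one line
  all_mols <- lapply(tokens, function(t)
    tryCatch(parse_smiles(t), error = function(e) NULL))
  if (!any(vapply(all_mols, is.null, logical(1)))) return(all_mols)
  # first token is the SMILES, the rest is the name
  nm <- paste(tokens[-1], collapse = " ")
  list(.try_parse(tokens[1], name = nm))
}

# charge codes of the V2000 atom-block charge column
.V2000_CHARGE <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "5" = -1L,
                   "6" = -2L, "7" = -3L)

.read_sdf <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  sdfset <- ChemmineR::read.SDFset(path)
  lapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
    tryCatch(.sdf_to_mol(sdfset[[i]]), error = function(e)
      structure(list(smiles = NA_character_, name = NA_character_,
                     error = conditionMessage(e)), class = "ca_badmol"))
  })
}

.sdf_to_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  charge <- integer(n)
  if (ncol(ab) >= 5L) {
    code <- as.character(ab[, 5])
    known <- code %in% names(.V2000_CHARGE)
    charge[known] <- .V2000_CHARGE[code[known]]
  }
  raw <- ChemmineR::sdf2str(sdf)
  for (ln in grep("^M  CHG", raw, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    cnt <- f[1]
    for (k in seq_len(cnt)) charge[f[2 * k]] <- f[2 * k + 1L]
  }

  b_from <- as.integer(bb[, 1]); b_to <- as.integer(bb[, 2])
  btype <- as.integer(bb[, 3])
  b_order <- ifelse(btype == 4L, 1L, pmin(btype, 3L))
  b_aromsym <- btype == 4L

  hnum <- rep(NA_integer_, n)
  bracket <- rep(FALSE, n)
  unknown <- !(elem %in% names(.STD_VALENCE)) & elem != "H"
  hnum[unknown] <- 0L
  bracket[unknown] <- TRUE

  # fold explicit hydrogens into heavy-atom hydrogen counts
  hsel <- which(elem == "H")
  if (length(hsel) > 0L) {
    hnum[is.na(hnum)] <- NA_integer_
    extra <- integer(n)
    for (ai in hsel) {
      nb <- c(b_to[b_from == ai], b_from[b_to == ai])
      if (length(nb) == 1L) extra[nb] <- extra[nb] + 1L
    }
    keep <- setdiff(seq_len(n), hsel)
    remap <- match(seq_len(n), keep)
    bkeep <- !(b_from %in% hsel | b_to %in% hsel)
    b_from <- remap[b_from[bkeep]]; b_to <- remap[b_to[bkeep]]
    b_order <- b_order[bkeep]; b_aromsym <- b_aromsym[bkeep]
    # explicit H forces the hydrogen count (plus any implicit remainder)
    hnum <- hnum[keep]; elem <- elem[keep]; charge <- charge[keep]
    bracket <- bracket[keep]
    hforce <- extra[keep]
    sel <- hforce > 0L
    hnum[sel] <- ifelse(is.na(hnum[sel]), hforce[sel], hnum[sel] + hforce[sel])
    n <- length(elem)
  }

  name <- tryCatch({
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(nm) || !nzchar(trimws(nm))) NA_character_ else trimws(nm)
  }, error = function(e) NA_character_)
  if (is.na(name)) {
    db <- tryCatch(ChemmineR::datablock(sdf), error = function(e) character(0))
    hit <- which(tolower(names(db)) == "name")
    if (length(hit) > 0L && nzchar(trimws(db[hit[1]]))) name <- trimws(db[hit[1]])
  }
  smiles <- tryCatch(
    trimws(ChemmineOB::convertFormat("SDF", "CAN", paste(raw, collapse = "\n"))),
    error = function(e) NA_character_)

  .finish_molecule(elem, rep(FALSE, n), charge, hnum,
                   rep(0L, n), bracket, b_from, b_to, b_order, b_aromsym,
                   smiles = if (is.na(smiles) || !nzchar(smiles)) "" else smiles,
                   name = name)
}

# --- JSON annotation output --------------------------------------------------

.match_to_json_obj <- function(m) {
  list(
    pattern_id = m$pattern_id,
    pattern_name = m$pattern_name,
    category = m$category,
    atom_indices = I(as.integer(m$atom_indices)),
    bonds = lapply(seq_len(nrow(m$bonds)), function(k) I(as.integer(m$bonds[k, ]))),
    overshadowed = m$suppression != "none",
    suppression_reason = m$suppression,
    suppressed_by = I(as.character(m$suppressed_by))
  )
}

#' Serialize annotations to JSON
#'
#' Produces the stable JSON document consumed by downstream tooling:
#' `{"molecules": [...]}` with one object per molecule carrying `name`,
#' `smiles`, `error` and a `matches` array (see the shipped schema in
#' `inst/extdata/annotation_schema.json`).  Suppressed matches are
#' included only when `include_overshadowed` is set.  Serialization is
#' deterministic: identical inputs give byte-identical output.
#'
#' @param results A list of `ca_annotation` objects (a single annotation
#'   is accepted).
#' @param path Output file; when `NULL` the JSON text is returned.
#' @param include_overshadowed Include suppressed matches (default
#'   `FALSE`).
#' @return The JSON text, invisibly when written to a file.
#' @export
write_annotations <- function(results, path = NULL, include_overshadowed = FALSE) {
  if (inherits(results, "ca_annotation")) results <- list(results)
  mols <- lapply(results, function(ann) {
    stopifnot(inherits(ann, "ca_annotation"))
    matches <- ann$matches
    if (!include_overshadowed)
      matches <- Filter(function(m) m$suppression == "none", matches)
    list(
      name = ann$molecule_name,
      smiles = if (is.null(ann$smiles) || is.na(ann$smiles)) "" else ann$smiles,
      error = if (is.null(ann$error)) NA_character_ else ann$error,
      matches = lapply(matches, .match_to_json_obj)
    )
  })
  txt <- jsonlite::toJSON(list(molecules = mols), auto_unbox = TRUE,
                          digits = NA, na = "null", pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Validate an annotation JSON document against the shipped schema
#'
#' Structural validation of the contract documented in
#' `inst/extdata/annotation_schema.json`: required keys, types, category
#' and suppression-reason enumerations, bonds as pairs of non-negative
#' integers, and the rule that a visible match has reason `"none"` and no
#' suppressors.
#'
#' @param json JSON text, or a path to a JSON file.
#' @return A character vector of validation messages; empty when the
#'   document is valid.
#' @export
validate_annotations <- function(json) {
  txt <- if (length(json) == 1L && file.exists(json)) readLines(json, warn = FALSE) else json
  doc <- tryCatch(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                     simplifyVector = FALSE),
                  error = function(e) NULL)
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(doc)) return("not parseable as JSON")
  if (!is.list(doc) || is.null(doc$molecules)) return("missing 'molecules' array")
  for (i in seq_along(doc$molecules)) {
    mol <- doc$molecules[[i]]
    for (key in c("name", "smiles", "matches"))
      if (is.null(mol[[key]])) add(sprintf("molecule %d: missing '%s'", i, key))
    if (is.null(mol$matches)) next
    for (j in seq_along(mol$matches)) {
      m <- mol$matches[[j]]
      where <- sprintf("molecule %d match %d", i, j)
      for (key in c("pattern_id", "pattern_name", "category", "atom_indices",
                    "bonds", "overshadowed", "suppression_reason", "suppressed_by"))
        if (is.null(m[[key]])) add(sprintf("%s: missing '%s'", where, key))
      if (!is.null(m$category) && !(m$category %in% .CATEGORIES))
        add(sprintf("%s: bad category '%s'", where, m$category))
      reasons <- c("none", "match_containment", "fewer_bonds", "hierarchy")
      if (!is.null(m$suppression_reason) && !(m$suppression_reason %in% reasons))
        add(sprintf("%s: bad suppression_reason", where))
      if (!is.null(m$atom_indices)) {
        ai <- unlist(m$atom_indices)
        if (length(ai) == 0L || any(ai != floor(ai)) || any(ai < 0))
          add(sprintf("%s: atom_indices must be non-negative integers", where))
      }
      if (!is.null(m$bonds)) {
        for (b in m$bonds) {
          bv <- unlist(b)
          if (length(bv) != 2L || any(bv < 0))
            add(sprintf("%s: bond must be a pair of atom indices", where))
        }
      }
      if (isFALSE(m$overshadowed)) {
        if (!identical(m$suppression_reason, "none") || length(m$suppressed_by) > 0L)
          add(sprintf("%s: visible match must have reason 'none' and no suppressors", where))
      }
      if (isTRUE(m$overshadowed) && identical(m$suppression_reason, "none"))
        add(sprintf("%s: overshadowed match needs a reason", where))
    }
  }
  errs
}
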