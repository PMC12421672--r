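# Restricted SMARTS engine.
#
# Supported atom primitives: element symbols (aromatic/aliphatic case,
# two-letter halogens, #n atomic number), `*`, `a`, `A`, charge (+/-/+n),
# H<n> (total hydrogen count), X<n> (total connectivity incl. H), D<n>
# (heavy-atom degree), R / R0 / R1 (ring membership), isotope digits, and
# recursive environments $(...).  Boolean operators with Daylight
# precedence: `!` > `&` (and implicit adjacency) > `,` > `;`.
# Bond primitives: - = # : ~ @ / \ plus the same boolean operators; the
# default bond is "single or aromatic".
#
# Atom and bond expressions are parsed into small ASTs that are evaluated
# either against a molecule's atoms/bonds (matching) or against a finite
# feature space (subsumption; see hierarchy.R).

.ATOMIC_NUM <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L,
                 P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L, Se = 34L,
                 As = 33L)

.prim <- function(kind, value = NULL, raw = NULL)
  list(op = "prim", kind = kind, value = value, raw = raw)
.nand <- function(args) if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
.nor <- function(args) if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
.nnot <- function(arg) list(op = "not", args = list(arg))

# package-level compilation cache ("constructed patterns are saved during
# multimolecule queries"); purely an optimization, keyed by SMARTS text
.smarts_cache <- new.env(parent = emptyenv())

#' Compile a SMARTS expression into a pattern graph
#'
#' Parses a SMARTS string into the pattern-graph representation used by the
#' matcher and the subsumption engine: one constraint expression per atom
#' node and per bond edge.  Compilation results are cached per SMARTS text.
#'
#' @param smarts A single SMARTS string (connected; the supported primitive
#'   subset is documented in the package vignette).
#' @return An object of class `ca_pattern_graph` with `n` atom nodes and a
#'   bond table; used internally by [find_pattern_matches()] and
#'   [pattern_subsumes()].
#' @export
parse_smarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L, !is.na(smarts))
  key <- smarts
  hit <- get0(key, envir = .smarts_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  pg <- .parse_smarts_impl(smarts)
  assign(key, pg, envir = .smarts_cache)
  pg
}

.parse_smarts_impl <- function(smarts) {
  s <- trimws(smarts)
  if (nchar(s) == 0L) stop("empty SMARTS")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)

  atom_expr <- list(); atom_raw <- character(0)
  b_from <- integer(0); b_to <- integer(0)
  b_expr <- list(); b_raw <- character(0)

  prev <- NA_integer_; stack <- integer(0)
  pending <- ""; ring_open <- list()

  add_bond <- function(a, b, bondtxt) {
    b_from <<- c(b_from, a); b_to <<- c(b_to, b)
    b_expr[[length(b_expr) + 1L]] <<- .parse_bond_expr(bondtxt)
    b_raw <<- c(b_raw, bondtxt)
  }
  add_atom <- function(expr, raw) {
    atom_expr[[length(atom_expr) + 1L]] <<- expr
    atom_raw <<- c(atom_raw, raw)
    idx <- length(atom_expr)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- ""
    prev <<- idx
  }

  bond_chars <- c("-", "=", "#", ":", "~", "@", "/", "\\", "!", "&", ",", ";")

  i <- 1L
  while (i <= n_ch) {
    ch <- chars[i]
    if (ch %in% bond_chars) {
      j <- i
      while (j <= n_ch && chars[j] %in% bond_chars) j <- j + 1L
      pending <- paste(chars[i:(j - 1L)], collapse = "")
      i <- j
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch open with no preceding atom in SMARTS")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unmatched ')' in SMARTS")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      stop("disconnected SMARTS (dot) is not supported")
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        num <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { num <- ch; i <- i + 1L }
      if (is.na(prev)) stop("ring closure with no preceding atom in SMARTS")
      if (!is.null(ring_open[[num]])) {
        op <- ring_open[[num]]
        txt <- if (nzchar(pending)) pending else op$sym
        add_bond(op$atom, prev, txt)
        ring_open[[num]] <- NULL
      } else {
        ring_open[[num]] <- list(atom = prev, sym = pending)
      }
      pending <- ""
    } else if (ch == "[") {
      depth <- 0L; j <- i
      repeat {
        if (j > n_ch) stop("unterminated bracket atom in SMARTS")
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        if (chars[j] == "]" && depth == 0L) break
        j <- j + 1L
      }
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      add_atom(.parse_atom_expr(inner), inner)
      i <- j + 1L
    } else {
      two <- if (i < n_ch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(.nand(list(.prim("elem", list(elem = two, arom = FALSE)))), two)
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(.prim("elem", list(elem = ch, arom = FALSE)), ch)
        i <- i + 1L
      } else if (ch %in% .AROMATIC_ORGANIC) {
        add_atom(.prim("elem", list(elem = toupper(ch), arom = TRUE)), ch)
        i <- i + 1L
      } else if (ch == "*") {
        add_atom(.prim("true"), "*"); i <- i + 1L
      } else if (ch == "a") {
        add_atom(.prim("arom", TRUE), "a"); i <- i + 1L
      } else if (ch == "A") {
        add_atom(.prim("arom", FALSE), "A"); i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in SMARTS '", smarts, "'")
      }
    }
  }
  if (length(stack) > 0L) stop("unmatched '(' in SMARTS")
  if (length(ring_open) > 0L) stop("unclosed ring bond in SMARTS")
  n <- length(atom_expr)
  if (n == 0L) stop("SMARTS contains no atoms")

  # connectivity check + DFS matching order
  adj <- vector("list", n)
  for (a in seq_len(n)) adj[[a]] <- integer(0)
  for (k in seq_along(b_from)) {
    adj[[b_from[k]]] <- c(adj[[b_from[k]]], b_to[k])
    adj[[b_to[k]]] <- c(adj[[b_to[k]]], b_from[k])
  }
  order <- integer(0); seen <- logical(n); frontier <- 1L
  stack2 <- 1L
  while (length(stack2) > 0L) {
    v <- stack2[length(stack2)]; stack2 <- stack2[-length(stack2)]
    if (seen[v]) next
    seen[v] <- TRUE; order <- c(order, v)
    stack2 <- c(stack2, rev(adj[[v]]))
  }
  if (!all(seen)) stop("disconnected SMARTS is not supported")

  structure(list(
    n = n, atom_expr = atom_expr, atom_raw = atom_raw,
    bond_from = b_from, bond_to = b_to, bond_expr = b_expr, bond_raw = b_raw,
    adj = adj, dfs_order = order, smarts = smarts
  ), class = "ca_pattern_graph")
}

# --- atom expression parsing (bracket contents) ------------------------------

.parse_atom_expr <- function(txt) {
  st <- new.env(parent = emptyenv())
  st$txt <- txt; st$pos <- 1L
  expr <- .pa_semi(st)
  if (st$pos <= nchar(st$txt))
    stop("trailing characters in atom expression '[", txt, "]'")
  expr
}

.pa_peek <- function(st) if (st$pos > nchar(st$txt)) "" else substr(st$txt, st$pos, st$pos)
.pa_take <- function(st, n = 1L) {
  out <- substr(st$txt, st$pos, st$pos + n - 1L)
  st$pos <- st$pos + n
  out
}
.pa_digits <- function(st) {
  rest <- substr(st$txt, st$pos, nchar(st$txt))
  m <- regmatches(rest, regexpr("^[0-9]+", rest))
  if (length(m) == 0L || !nzchar(m)) return(NA_integer_)
  st$pos <- st$pos + nchar(m)
  as.integer(m)
}

.pa_semi <- function(st) {
  args <- list(.pa_comma(st))
  while (.pa_peek(st) == ";") { .pa_take(st); args <- c(args, list(.pa_comma(st))) }
  .nand(args)
}
.pa_comma <- function(st) {
  args <- list(.pa_amp(st))
  while (.pa_peek(st) == ",") { .pa_take(st); args <- c(args, list(.pa_amp(st))) }
  .nor(args)
}
.pa_amp <- function(st) {
  args <- list(.pa_unary(st))
  repeat {
    ch <- .pa_peek(st)
    if (ch == "&") { .pa_take(st); args <- c(args, list(.pa_unary(st))); next }
    if (ch == "" || ch %in% c(";", ",")) break
    args <- c(args, list(.pa_unary(st)))   # implicit AND
  }
  .nand(args)
}
.pa_unary <- function(st) {
  if (.pa_peek(st) == "!") { .pa_take(st); return(.nnot(.pa_unary(st))) }
  .pa_primitive(st)
}

.pa_primitive <- function(st) {
  ch <- .pa_peek(st)
  if (ch == "") stop("unexpected end of atom expression")
  if (grepl("[0-9]", ch)) {
    return(.prim("isotope", .pa_digits(st)))
  }
  if (ch == "#") {
    .pa_take(st)
    num <- .pa_digits(st)
    if (is.na(num)) stop("'#' must be followed by an atomic number")
    sym <- names(.ATOMIC_NUM)[match(num, .ATOMIC_NUM)]
    if (is.na(sym)) stop("unsupported atomic number #", num)
    return(.prim("elem", list(elem = sym, arom = NA)))
  }
  if (ch == "$") {
    .pa_take(st)
    if (.pa_take(st) != "(") stop("'$' must be followed by '('")
    depth <- 1L; start <- st$pos
    while (depth > 0L) {
      c2 <- .pa_take(st)
      if (c2 == "") stop("unterminated recursive SMARTS")
      if (c2 == "(") depth <- depth + 1L
      if (c2 == ")") depth <- depth - 1L
    }
    inner <- substr(st$txt, start, st$pos - 2L)
    return(.prim("recursive", parse_smarts(inner), raw = inner))
  }
  if (ch == "*") { .pa_take(st); return(.prim("true")) }
  two <- substr(st$txt, st$pos, st$pos + 1L)
  if (two %in% c("se", "as")) {
    .pa_take(st, 2L)
    el <- paste0(toupper(substr(two, 1, 1)), substr(two, 2, 2))
    return(.prim("elem", list(elem = el, arom = TRUE)))
  }
  if (two %in% .TWO_LETTER && two %in% names(.ATOMIC_NUM)) {
    .pa_take(st, 2L)
    return(.prim("elem", list(elem = two, arom = FALSE)))
  }
  if (ch == "H") {
    .pa_take(st); n <- .pa_digits(st)
    return(.prim("hcount", if (is.na(n)) 1L else n))
  }
  if (ch == "X") {
    .pa_take(st); n <- .pa_digits(st)
    return(.prim("connectivity", if (is.na(n)) 1L else n))
  }
  if (ch == "D") {
    .pa_take(st); n <- .pa_digits(st)
    return(.prim("degree", if (is.na(n)) 1L else n))
  }
  if (ch == "R") {
    .pa_take(st); n <- .pa_digits(st)
    if (is.na(n) || n == 1L) return(.prim("ring", TRUE))
    if (n == 0L) return(.prim("ring", FALSE))
    stop("R", n, " (multiple-ring membership) is not supported")
  }
  if (ch == "r") stop("ring-size primitive 'r' is not supported")
  if (ch %in% c("+", "-")) {
    sgn <- if (ch == "+") 1L else -1L
    .pa_take(st)
    n <- .pa_digits(st)
    if (!is.na(n)) return(.prim("charge", sgn * n))
    k <- 1L
    while (.pa_peek(st) == ch) { .pa_take(st); k <- k + 1L }
    return(.prim("charge", sgn * k))
  }
  if (ch == "a") { .pa_take(st); return(.prim("arom", TRUE)) }
  if (ch == "A") { .pa_take(st); return(.prim("arom", FALSE)) }
  if (grepl("[A-Z]", ch)) {
    .pa_take(st)
    if (!(ch %in% names(.ATOMIC_NUM))) stop("unsupported element '", ch, "'")
    return(.prim("elem", list(elem = ch, arom = FALSE)))
  }
  if (ch %in% .AROMATIC_ORGANIC) {
    .pa_take(st)
    return(.prim("elem", list(elem = toupper(ch), arom = TRUE)))
  }
  stop("unsupported atom primitive '", ch, "' in '", st$txt, "'")
}

# --- bond expression parsing -------------------------------------------------

.parse_bond_expr <- function(txt) {
  if (txt == "") return(.prim("bond_default"))
  st <- new.env(parent = emptyenv())
  st$txt <- txt; st$pos <- 1L
  expr <- .pb_semi(st)
  if (st$pos <= nchar(st$txt)) stop("trailing characters in bond expression '", txt, "'")
  expr
}
.pb_semi <- function(st) {
  args <- list(.pb_comma(st))
  while (.pa_peek(st) == ";") { .pa_take(st); args <- c(args, list(.pb_comma(st))) }
  .nand(args)
}
.pb_comma <- function(st) {
  args <- list(.pb_amp(st))
  while (.pa_peek(st) == ",") { .pa_take(st); args <- c(args, list(.pb_amp(st))) }
  .nor(args)
}
.pb_amp <- function(st) {
  args <- list(.pb_unary(st))
  repeat {
    ch <- .pa_peek(st)
    if (ch == "&") { .pa_take(st); args <- c(args, list(.pb_unary(st))); next }
    if (ch == "" || ch %in% c(";", ",")) break
    args <- c(args, list(.pb_unary(st)))
  }
  .nand(args)
}
.pb_unary <- function(st) {
  if (.pa_peek(st) == "!") { .pa_take(st); return(.nnot(.pb_unary(st))) }
  ch <- .pa_take(st)
  switch(ch,
    "-" = .prim("bond_order", "1"),
    "/" = .prim("bond_order", "1"),
    "\\" = .prim("bond_order", "1"),
    "=" = .prim("bond_order", "2"),
    "#" = .prim("bond_order", "3"),
    ":" = .prim("bond_order", "ar"),
    "~" = .prim("true"),
    "@" = .prim("bond_ring", TRUE),
    stop("unsupported bond primitive '", ch, "'"))
}

# --- evaluation --------------------------------------------------------------

# Atom feature frame for a molecule (one row per atom).
.mol_atom_feat <- function(mol) {
  data.frame(elem = mol$elem, arom = mol$arom, charge = mol$charge,
             h = mol$hcount, deg = mol$degree, ring = mol$in_ring,
             iso = mol$isotope, stringsAsFactors = FALSE)
}
# Bond feature frame (type: "1","2","3","ar").
.mol_bond_feat <- function(mol) {
  type <- ifelse(mol$bond_arom, "ar", as.character(mol$bond_order))
  data.frame(type = type, ring = mol$bond_ring, stringsAsFactors = FALSE)
}

# Evaluate an atom expression over the rows of a feature frame.
# `mol`: molecule context for recursive environments; when NULL (finite
# feature-space mode) recursive and isotope primitives are treated as
# always-true and flagged in `flags$opaque` / `flags$permissive`.
.eval_atom_expr <- function(node, feat, mol = NULL, flags = NULL) {
  nr <- nrow(feat)
  switch(node$op,
    and = {
      out <- rep(TRUE, nr)
      for (a in node$args) out <- out & .eval_atom_expr(a, feat, mol, flags)
      out
    },
    or = {
      out <- rep(FALSE, nr)
      for (a in node$args) out <- out | .eval_atom_expr(a, feat, mol, flags)
      out
    },
    not = !.eval_atom_expr(node$args[[1]], feat, mol, flags),
    prim = .eval_atom_prim(node, feat, mol, flags),
    stop("bad AST node"))
}

.eval_atom_prim <- function(node, feat, mol, flags) {
  nr <- nrow(feat)
  switch(node$kind,
    true = rep(TRUE, nr),
    elem = {
      v <- node$value
      out <- feat$elem == v$elem
      if (!is.na(v$arom)) out <- out & (feat$arom == v$arom)
      out
    },
    arom = feat$arom == node$value,
    charge = feat$charge == node$value,
    hcount = feat$h == node$value,
    connectivity = (feat$deg + feat$h) == node$value,
    degree = feat$deg == node$value,
    ring = feat$ring == node$value,
    isotope = {
      if (is.null(mol)) {
        if (!is.null(flags)) flags$opaque <- TRUE
        rep(TRUE, nr)
      } else feat$iso == node$value
    },
    recursive = {
      if (is.null(mol)) {
        if (!is.null(flags)) flags$opaque <- TRUE
        rep(TRUE, nr)
      } else {
        vapply(seq_len(nr), function(ai)
          .match_anchored(node$value, mol, ai), logical(1))
      }
    },
    stop("bad atom primitive kind ", node$kind))
}

.eval_bond_expr <- function(node, feat) {
  nr <- nrow(feat)
  switch(node$op,
    and = {
      out <- rep(TRUE, nr)
      for (a in node$args) out <- out & .eval_bond_expr(a, feat)
      out
    },
    or = {
      out <- rep(FALSE, nr)
      for (a in node$args) out <- out | .eval_bond_expr(a, feat)
      out
    },
    not = !.eval_bond_expr(node$args[[1]], feat),
    prim = switch(node$kind,
      true = rep(TRUE, nr),
      bond_order = feat$type == node$value,
      bond_ring = feat$ring == node$value,
      bond_default = feat$type %in% c("1", "ar"),
      stop("bad bond primitive kind ", node$kind)),
    stop("bad AST node"))
}
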