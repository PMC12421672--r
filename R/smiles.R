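# Molecular graphs parsed from SMILES.
#
# Internal representation (class "ca_mol"): parallel atom vectors (1-based
# internally; all exported indices are 0-based over parse order), a bond
# table, and perception results (ring membership, aromaticity, implicit
# hydrogens).  Explicit hydrogen atoms are folded into the heavy-atom
# hydrogen counts so that atom indices always enumerate heavy atoms.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
.TWO_LETTER <- c("Cl", "Br", "Si", "Se", "As", "Na", "Ca", "Li", "Mg", "Al",
                 "Fe", "Zn", "Cu", "Mn", "Co", "Ni", "Sn", "Te", "He", "Ne",
                 "Ar", "Kr", "Xe")

# lowest standard valences; aromatic atoms use only the first entry
.STD_VALENCE <- list(B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
                     S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L)

#' Parse a SMILES string into a molecular graph
#'
#' Builds the molecule representation used throughout the package: heavy
#' atoms in parse order with element, formal charge, hydrogen count and
#' isotope annotation; bonds with order and aromaticity; ring perception;
#' and aromaticity perception for rings written in Kekulé form.
#'
#' The aromaticity model marks a 5-7-membered ring aromatic when every ring
#' atom can carry a p-orbital (at most three connections for B/C/N/P, two
#' for O/S) and the Hückel electron count over the ring is 4n+2, counting 1
#' for atoms in a ring double bond, 0 for carbons with an exocyclic double
#' bond (so, e.g., the pyrimidinedione ring of caffeine is aromatic), and 2
#' for heteroatoms contributing a lone pair.  Rings written in lowercase
#' aromatic form are taken as aromatic directly.
#'
#' @param smiles A single SMILES string.
#' @param name Optional molecule name.
#' @return An object of class `ca_mol`.
#' @examples
#' m <- parse_smiles("CN1C=NC2=C1C(=O)N(C(=O)N2C)C", name = "caffeine")
#' m
#' @export
parse_smiles <- function(smiles, name = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)

  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hnum <- integer(0)        # NA = implicit, to be computed
  iso <- integer(0); bracket <- logical(0)
  b_from <- integer(0); b_to <- integer(0); b_order <- integer(0)
  b_aromsym <- logical(0)   # ':' or default bond between lowercase atoms

  prev <- NA_integer_
  stack <- integer(0)
  pending <- ""             # bond symbol waiting for next atom / ring digit
  ring_open <- list()       # ring number -> list(atom, sym)
  h_isotope <- FALSE

  add_bond <- function(a, b, sym) {
    if (any(b_from == a & b_to == b) || any(b_from == b & b_to == a))
      stop("duplicate bond between atoms ", a, " and ", b)
    order <- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L,
                    "/" = 1L, "\\" = 1L, 1L)
    aromsym <- identical(sym, ":") ||
      (sym == "" && arom[a] && arom[b])
    b_from <<- c(b_from, a); b_to <<- c(b_to, b)
    b_order <<- c(b_order, order); b_aromsym <<- c(b_aromsym, aromsym)
  }

  add_atom <- function(sym, ar, ch, h, is, br) {
    elem <<- c(elem, sym); arom <<- c(arom, ar); charge <<- c(charge, ch)
    hnum <<- c(hnum, h); iso <<- c(iso, is); bracket <<- c(bracket, br)
    idx <- length(elem)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- ""
    prev <<- idx
    idx
  }

  i <- 1L
  while (i <= n_ch) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch open with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n_ch || !grepl("^[0-9]{2}", paste(chars[(i + 1L):min(n_ch, i + 2L)], collapse = "")))
          stop("bad %nn ring closure")
        num <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        num <- ch; i <- i + 1L
      }
      if (is.na(prev)) stop("ring closure with no preceding atom")
      if (!is.null(ring_open[[num]])) {
        op <- ring_open[[num]]
        sym <- if (nzchar(pending)) pending else op$sym
        if (nzchar(op$sym) && nzchar(pending) && op$sym != pending)
          stop("conflicting ring-closure bond symbols for ring ", num)
        add_bond(op$atom, prev, sym)
        ring_open[[num]] <- NULL
      } else {
        ring_open[[num]] <- list(atom = prev, sym = pending)
      }
      pending <- ""
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n_ch && chars[j] != "]") j <- j + 1L
      if (j > n_ch) stop("unterminated bracket atom")
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(inner)
      add_atom(at$elem, at$arom, at$charge, at$h, at$iso, TRUE)
      i <- j + 1L
    } else {
      two <- if (i < n_ch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, 0L, FALSE); i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(ch, FALSE, 0L, NA_integer_, 0L, FALSE); i <- i + 1L
      } else if (ch %in% .AROMATIC_ORGANIC) {
        add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, FALSE); i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' at position ", i,
             " in SMILES '", smiles, "'")
      }
    }
  }
  if (length(stack) > 0L) stop("unmatched '(' in SMILES")
  if (length(ring_open) > 0L)
    stop("unclosed ring bond(s): ", paste(names(ring_open), collapse = ", "))
  if (length(elem) == 0L) stop("SMILES contains no atoms")

  # fold explicit hydrogen atoms into neighbour hydrogen counts
  hsel <- which(elem == "H")
  if (length(hsel) > 0L) {
    if (any(iso[hsel] > 0L)) h_isotope <- TRUE
    for (ai in hsel) {
      nb <- c(b_to[b_from == ai], b_from[b_to == ai])
      if (length(nb) == 1L) {
        if (is.na(hnum[nb])) hnum[nb] <- 0L
        hnum[nb] <- hnum[nb] + 1L + max(0L, hnum[ai])
      } else if (length(nb) > 1L) {
        stop("hydrogen atom with more than one bond")
      }
    }
    keep <- setdiff(seq_along(elem), hsel)
    remap <- match(seq_along(elem), keep)
    bkeep <- !(b_from %in% hsel | b_to %in% hsel)
    b_from <- remap[b_from[bkeep]]; b_to <- remap[b_to[bkeep]]
    b_order <- b_order[bkeep]; b_aromsym <- b_aromsym[bkeep]
    elem <- elem[keep]; arom <- arom[keep]; charge <- charge[keep]
    hnum <- hnum[keep]; iso <- iso[keep]; bracket <- bracket[keep]
    if (length(elem) == 0L) stop("SMILES contains no heavy atoms")
  }

  .finish_molecule(elem, arom, charge, hnum, iso, bracket,
                   b_from, b_to, b_order, b_aromsym,
                   smiles = smiles, name = name, h_isotope = h_isotope)
}

.parse_bracket_atom <- function(inner) {
  txt <- inner
  iso <- 0L
  m <- regmatches(txt, regexpr("^[0-9]+", txt))
  if (length(m) == 1L && nzchar(m)) {
    iso <- as.integer(m); txt <- sub("^[0-9]+", "", txt)
  }
  arom <- FALSE
  two <- substr(txt, 1, 2)
  one <- substr(txt, 1, 1)
  if (two %in% c("se", "as")) {
    el <- paste0(toupper(substr(two, 1, 1)), substr(two, 2, 2))
    arom <- TRUE; txt <- substr(txt, 3, nchar(txt))
  } else if (two %in% .TWO_LETTER) {
    el <- two; txt <- substr(txt, 3, nchar(txt))
  } else if (grepl("^[A-Z]$", one)) {
    el <- one; txt <- substr(txt, 2, nchar(txt))
  } else if (one %in% .AROMATIC_ORGANIC) {
    el <- toupper(one); arom <- TRUE; txt <- substr(txt, 2, nchar(txt))
  } else if (one == "*") {
    stop("wildcard atoms are not supported in SMILES input")
  } else {
    stop("cannot parse bracket atom '[", inner, "]'")
  }
  h <- 0L; ch <- 0L
  while (nzchar(txt)) {
    c1 <- substr(txt, 1, 1)
    if (c1 == "@") {
      txt <- sub("^@+", "", txt)            # stereo ignored
    } else if (c1 == "H") {
      txt <- substr(txt, 2, nchar(txt))
      d <- regmatches(txt, regexpr("^[0-9]+", txt))
      if (length(d) == 1L && nzchar(d)) {
        h <- as.integer(d); txt <- sub("^[0-9]+", "", txt)
      } else h <- 1L
    } else if (c1 %in% c("+", "-")) {
      sgn <- if (c1 == "+") 1L else -1L
      txt <- substr(txt, 2, nchar(txt))
      d <- regmatches(txt, regexpr("^[0-9]+", txt))
      if (length(d) == 1L && nzchar(d)) {
        ch <- sgn * as.integer(d); txt <- sub("^[0-9]+", "", txt)
      } else {
        ch <- sgn
        while (substr(txt, 1, 1) == c1) {
          ch <- ch + sgn; txt <- substr(txt, 2, nchar(txt))
        }
      }
    } else if (c1 == ":") {
      txt <- sub("^:[0-9]+", "", txt)       # atom map ignored
    } else {
      stop("unsupported token '", c1, "' in bracket atom '[", inner, "]'")
    }
  }
  list(elem = el, arom = arom, charge = ch, h = h, iso = iso)
}

# assemble the ca_mol object: implicit H, radicals, ring + aromaticity
# perception, adjacency
.finish_molecule <- function(elem, arom, charge, hnum, iso, bracket,
                             b_from, b_to, b_order, b_aromsym,
                             smiles, name, h_isotope = FALSE) {
  n <- length(elem)
  nb <- length(b_from)

  degree <- integer(n)
  bondsum <- numeric(n)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      v <- if (b_aromsym[k]) 1.5 else as.numeric(b_order[k])
      bondsum[b_from[k]] <- bondsum[b_from[k]] + v
      bondsum[b_to[k]] <- bondsum[b_to[k]] + v
      degree[b_from[k]] <- degree[b_from[k]] + 1L
      degree[b_to[k]] <- degree[b_to[k]] + 1L
    }
  }

  radical <- logical(n)
  for (a in seq_len(n)) {
    vals <- .STD_VALENCE[[elem[a]]]
    bs <- as.integer(ceiling(bondsum[a]))
    if (is.na(hnum[a])) {
      # organic-subset atom: fill valence; aromatic atoms use lowest valence
      if (is.null(vals)) stop("no default valence for element ", elem[a])
      vset <- if (arom[a]) vals[1] else vals
      v <- vset[vset >= bs][1]
      hnum[a] <- if (is.na(v)) 0L else as.integer(v - bs)
    } else if (bracket[a] && !arom[a] && charge[a] == 0L && !is.null(vals)) {
      tot <- hnum[a] + bs
      v <- vals[vals >= tot][1]
      if (!is.na(v) && (v - tot) %% 2L == 1L) radical[a] <- TRUE
    }
  }

  # ring perception
  bond_ring <- logical(nb)
  nfrag <- 1L
  if (nb > 0L) {
    g <- igraph::graph_from_edgelist(cbind(b_from, b_to), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    nfrag <- igraph::components(g)$no
    br <- igraph::bridges(g)
    bond_ring <- !(seq_len(nb) %in% as.integer(br))
  } else {
    nfrag <- n
  }
  in_ring <- logical(n)
  in_ring[c(b_from[bond_ring], b_to[bond_ring])] <- TRUE

  bond_arom <- logical(nb)
  # input-aromatic rings: ':' or default bonds between lowercase atoms
  bond_arom[b_aromsym & bond_ring] <- TRUE

  rings <- .small_rings(n, b_from, b_to, bond_ring, max_size = 7L)
  if (length(rings) > 0L) {
    input_arom <- arom   # lowercase flags as written, before perception
    pi_e <- .pi_contribution(n, elem, input_arom, charge, hnum, degree, in_ring,
                             b_from, b_to, b_order, bond_arom)
    bkey <- paste(pmin(b_from, b_to), pmax(b_from, b_to))
    for (ring in rings) {
      if (all(input_arom[ring])) { isar <- TRUE }
      else if (any(input_arom[ring])) { isar <- FALSE }  # mixed notation: leave as written
      else {
        contrib <- pi_e[ring]
        isar <- !anyNA(contrib) && sum(contrib) %% 4 == 2
      }
      if (isar) {
        arom[ring] <- TRUE
        rk <- length(ring)
        pairs <- cbind(ring, ring[c(2:rk, 1L)])
        sel <- match(paste(pmin(pairs[, 1], pairs[, 2]),
                           pmax(pairs[, 1], pairs[, 2])), bkey)
        bond_arom[sel[!is.na(sel)]] <- TRUE
      }
    }
  }

  arom[!in_ring] <- FALSE   # aromaticity requires ring membership

  adj <- vector("list", n); abond <- vector("list", n)
  for (a in seq_len(n)) { adj[[a]] <- integer(0); abond[[a]] <- integer(0) }
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      adj[[b_from[k]]] <- c(adj[[b_from[k]]], b_to[k])
      abond[[b_from[k]]] <- c(abond[[b_from[k]]], k)
      adj[[b_to[k]]] <- c(adj[[b_to[k]]], b_from[k])
      abond[[b_to[k]]] <- c(abond[[b_to[k]]], k)
    }
  }

  structure(list(
    n = n, elem = elem, arom = arom, charge = charge, hcount = hnum,
    isotope = iso, radical = radical, degree = degree, in_ring = in_ring,
    bond_from = b_from, bond_to = b_to, bond_order = b_order,
    bond_arom = bond_arom, bond_ring = bond_ring,
    nfrag = nfrag, h_isotope = h_isotope,
    adj = adj, abond = abond,
    smiles = smiles, name = name
  ), class = "ca_mol")
}

# smallest ring through every ring bond (BFS on the graph minus that bond);
# unique rings up to max_size, used by aromaticity perception
.small_rings <- function(n, b_from, b_to, bond_ring, max_size = 7L) {
  ks <- which(bond_ring)
  if (length(ks) == 0L) return(list())
  g <- igraph::graph_from_edgelist(cbind(b_from, b_to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  seen <- character(0)
  rings <- list()
  for (k in ks) {
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = b_from[k],
                                                  to = b_to[k], output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) == 0L || length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- path
  }
  rings
}

# Hückel pi-electron contribution per atom; NA = cannot sit in an aromatic
# ring.  Exocyclic double bonds to non-ring atoms contribute 0 (carbon only).
.pi_contribution <- function(n, elem, arom, charge, hnum, degree, in_ring,
                             b_from, b_to, b_order, bond_arom) {
  out <- rep(NA_real_, n)
  for (a in seq_len(n)) {
    if (!in_ring[a]) next
    conn <- degree[a] + hnum[a]
    el <- elem[a]
    limit <- if (el %in% c("O", "S", "Se")) 2L else
             if (el %in% c("B", "C", "N", "P")) 3L else -1L
    if (limit < 0L || conn > limit) next
    ks <- which((b_from == a | b_to == a))
    dbl <- ks[b_order[ks] == 2L & !bond_arom[ks]]
    trp <- ks[b_order[ks] == 3L]
    if (length(trp) > 0L) next
    if (length(dbl) > 0L) {
      partners <- ifelse(b_from[dbl] == a, b_to[dbl], b_from[dbl])
      if (any(in_ring[partners])) { out[a] <- 1 }
      else if (el == "C") { out[a] <- 0 }
      # heteroatom with exocyclic double bond: not handled, stays NA
    } else if (el == "C") {
      if (charge[a] == -1L) out[a] <- 2
      else if (charge[a] == 1L) out[a] <- 0
    } else if (el %in% c("N", "P")) {
      out[a] <- if (charge[a] >= 1L) 0 else 2
    } else if (el %in% c("O", "S", "Se")) {
      out[a] <- 2
    }
  }
  out
}

#' @export
print.ca_mol <- function(x, ...) {
  nm <- if (is.na(x$name)) "<unnamed>" else x$name
  cat(sprintf("<molecule> %s  %s\n", nm, x$smiles))
  cat(sprintf("  %d heavy atoms, %d bonds, %d fragment(s), %d aromatic atoms\n",
              x$n, length(x$bond_from), x$nfrag, sum(x$arom)))
  invisible(x)
}

# 0-based unordered bond pair matrix (two columns, sorted within rows)
.mol_bond_pairs <- function(mol) {
  if (length(mol$bond_from) == 0L)
    return(matrix(integer(0), ncol = 2))
  cbind(pmin(mol$bond_from, mol$bond_to), pmax(mol$bond_from, mol$bond_to)) - 1L
}
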