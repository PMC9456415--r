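# Minimal SMILES reader used by the fingerprint layer.
#
# Scope: the organic subset (B C N O P S F Cl Br I and their aromatic
# lowercase forms), bracket atoms with isotope/charge/H-count, branches,
# ring-closure digits (including %nn and digit reuse), '.' separated
# components, and the bond symbols - = # : (stereo markers / \ @ are accepted
# and ignored). Kekule 6-rings of C/N with alternating single/double bonds
# are promoted to aromatic so that equivalent spellings of e.g. benzene give
# identical fingerprints. This is deliberately not a general-purpose
# cheminformatics kit; it covers the structures this package generates and
# the TCMSP-style natural products the workflow screens.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s", "se", "as")

.default_valences <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecular graph
#'
#' Returns the atom and bond tables used by [fingerprint()]. Aromaticity is
#' taken from lowercase atoms and additionally perceived on six-membered
#' C/N rings written in alternating Kekule form, so different spellings of
#' the same molecule parse to the same graph.
#'
#' @param smiles A single SMILES string.
#' @return A list of class `smiles_mol` with elements `atoms` (data.frame:
#'   `symbol`, `aromatic`, `charge`, `hcount`) and `bonds` (data.frame:
#'   `a1`, `a2`, `order`; aromatic bonds have order 1.5).
#' @examples
#' mol <- parse_smiles("c1ccccc1O")  # phenol
#' nrow(mol$atoms)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("SMILES must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(symbol, aromatic, charge, hcount (NA=implicit))
  bonds <- list()   # each: c(a1, a2, order)
  prev <- NA_integer_        # previous atom index awaiting a bond
  pending_bond <- NA_real_   # bond symbol seen since last atom
  branch_stack <- integer()
  ring_open <- list()        # ring number -> list(atom, order)

  add_atom <- function(symbol, aromatic, charge = 0L, hcount = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(
      symbol = symbol, aromatic = aromatic, charge = charge, hcount = hcount
    )
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && aromatic) 1.5 else 1
      }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    prev <<- idx
    pending_bond <<- NA_real_
    idx
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.na(prev)) stop("ring bond before any atom in '", smiles, "'",
                          call. = FALSE)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, order = pending_bond)
      pending_bond <<- NA_real_
    } else {
      opener <- ring_open[[key]]
      ord <- pending_bond
      if (is.na(ord)) ord <- opener$order
      if (is.na(ord)) {
        ord <- if (atoms[[opener$atom]]$aromatic && atoms[[prev]]$aromatic)
          1.5 else 1
      }
      if (opener$atom == prev)
        stop("self-loop ring bond in '", smiles, "'", call. = FALSE)
      bonds[[length(bonds) + 1L]] <<- c(opener$atom, prev, ord)
      ring_open[[key]] <<- NULL
      pending_bond <<- NA_real_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in '", smiles, "'",
                            call. = FALSE)
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L)
        stop("unmatched ')' in '", smiles, "'", call. = FALSE)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_real_
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1
      i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2
      i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- 3
      i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- 1.5
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        stop("malformed %nn ring bond in '", smiles, "'", call. = FALSE)
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in '", smiles, "'",
                      call. = FALSE)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(body, smiles)
      add_atom(at$symbol, at$aromatic, at$charge, at$hcount)
      i <- j + 1L
    } else if (grepl("[A-Z]", ch)) {
      sym <- ch
      if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
        sym <- paste0(ch, chars[i + 1L])
        i <- i + 1L
      }
      if (!(sym %in% .ORGANIC_SUBSET))
        stop("atom '", sym, "' outside the organic subset needs brackets in '",
             smiles, "'", call. = FALSE)
      add_atom(sym, aromatic = FALSE)
      i <- i + 1L
    } else if (grepl("[a-z]", ch)) {
      if (!(ch %in% .AROMATIC_OK))
        stop("unknown aromatic atom '", ch, "' in '", smiles, "'",
             call. = FALSE)
      add_atom(toupper(ch), aromatic = TRUE)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES '", smiles, "'",
           call. = FALSE)
    }
  }

  if (length(branch_stack) > 0L)
    stop("unmatched '(' in '", smiles, "'", call. = FALSE)
  if (length(ring_open) > 0L)
    stop("unclosed ring bond(s) ", paste(names(ring_open), collapse = ", "),
         " in '", smiles, "'", call. = FALSE)
  if (length(atoms) == 0L)
    stop("no atoms parsed from '", smiles, "'", call. = FALSE)

  atom_df <- data.frame(
    symbol = vapply(atoms, `[[`, "", "symbol"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 1L),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), 1L),
    stringsAsFactors = FALSE
  )
  bond_df <- if (length(bonds) > 0L) {
    m <- do.call(rbind, bonds)
    data.frame(a1 = as.integer(m[, 1]), a2 = as.integer(m[, 2]),
               order = m[, 3])
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = numeric())
  }

  mol <- list(atoms = atom_df, bonds = bond_df)
  mol <- .perceive_aromatic_rings(mol)
  mol$atoms$hcount <- .implicit_hydrogens(mol)
  class(mol) <- "smiles_mol"
  mol
}

.parse_bracket_atom <- function(body, smiles) {
  m <- regmatches(
    body,
    regexec(
      "^([0-9]*)([A-Z][a-z]?|as|se|[bcnops])(@{0,2})(H([0-9]*))?([+-]+[0-9]*|[+-]?[0-9]*)?.*$",
      body
    )
  )[[1]]
  if (length(m) == 0L || !nzchar(m[3]))
    stop("cannot parse bracket atom '[", body, "]' in '", smiles, "'",
         call. = FALSE)
  raw_sym <- m[3]
  aromatic <- raw_sym %in% .AROMATIC_OK && raw_sym == tolower(raw_sym)
  symbol <- if (aromatic) {
    paste0(toupper(substr(raw_sym, 1, 1)), substring(raw_sym, 2))
  } else raw_sym
  hcount <- 0L
  if (nzchar(m[5])) {
    hcount <- if (nzchar(m[6])) as.integer(m[6]) else 1L
  }
  charge <- 0L
  cs <- m[7]
  if (!is.null(cs) && nzchar(cs)) {
    sign <- if (grepl("-", cs)) -1L else if (grepl("\\+", cs)) 1L else 0L
    digits <- gsub("[^0-9]", "", cs)
    mag <- if (nzchar(digits)) as.integer(digits) else
      nchar(gsub("[^+-]", "", cs))
    charge <- sign * max(mag, if (sign != 0L) 1L else 0L)
  }
  list(symbol = symbol, aromatic = aromatic, charge = charge, hcount = hcount)
}

# Promote Kekule-form 6-rings (all C/N, strictly alternating single/double)
# to aromatic atoms and 1.5-order bonds. Fundamental cycles from a DFS tree.
.perceive_aromatic_rings <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(mol)
  na <- nrow(mol$atoms)
  adj <- vector("list", na)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  parent <- rep(NA_integer_, na)
  parent_edge <- rep(NA_integer_, na)
  depth <- rep(NA_integer_, na)
  tree_edge <- rep(FALSE, nb)
  for (root in seq_len(na)) {
    if (!is.na(depth[root])) next
    depth[root] <- 0L
    stack <- root
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (is.null(adj[[v]])) next
      for (r in seq_len(nrow(adj[[v]]))) {
        w <- adj[[v]][r, 1]; e <- adj[[v]][r, 2]
        if (is.na(depth[w])) {
          depth[w] <- depth[v] + 1L
          parent[w] <- v
          parent_edge[w] <- e
          tree_edge[e] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
  }
  back_edges <- which(!tree_edge)
  for (e in back_edges) {
    u <- mol$bonds$a1[e]; v <- mol$bonds$a2[e]
    # walk up to common ancestor
    pu <- u; pv <- v
    path_u <- u; path_v <- v
    eu <- integer(); ev <- integer()
    while (pu != pv) {
      if (depth[pu] >= depth[pv]) {
        eu <- c(eu, parent_edge[pu]); pu <- parent[pu]; path_u <- c(path_u, pu)
      } else {
        ev <- c(ev, parent_edge[pv]); pv <- parent[pv]; path_v <- c(path_v, pv)
      }
    }
    ring_atoms <- c(path_u, rev(path_v[-length(path_v)]))
    ring_edges <- c(e, eu, rev(ev))
    if (length(ring_atoms) != 6L) next
    syms <- mol$atoms$symbol[ring_atoms]
    if (!all(syms %in% c("C", "N"))) next
    orders <- mol$bonds$order[ring_edges]
    if (all(orders == 1.5)) next  # already aromatic
    # alternating Kekule pattern around the closed cycle
    ok <- all(orders %in% c(1, 2)) &&
      all(abs(diff(c(orders, orders[1]))) == 1)
    if (ok) {
      mol$atoms$aromatic[ring_atoms] <- TRUE
      mol$bonds$order[ring_edges] <- 1.5
    }
  }
  mol
}

# Implicit hydrogen counts for organic-subset atoms; bracket atoms keep
# their explicit count. Aromatic bond order contributes 1.5, the total is
# rounded up before subtracting from the smallest fitting default valence.
.implicit_hydrogens <- function(mol) {
  h <- mol$atoms$hcount
  bsum <- rep(0, nrow(mol$atoms))
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + mol$bonds$order[k]
      bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + mol$bonds$order[k]
    }
  }
  for (i in seq_len(nrow(mol$atoms))) {
    if (!is.na(h[i])) next  # bracket atom: explicit
    vs <- .default_valences[[mol$atoms$symbol[i]]]
    if (is.null(vs)) { h[i] <- 0L; next }
    used <- ceiling(bsum[i])
    fit <- vs[vs >= used]
    v <- if (length(fit) > 0L) fit[1] else used
    h[i] <- as.integer(max(0L, v - used))
  }
  h
}

#' @export
print.smiles_mol <- function(x, ...) {
  cat("<smiles_mol> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds (",
      sum(x$atoms$aromatic), " aromatic atoms)\n", sep = "")
  invisible(x)
}
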