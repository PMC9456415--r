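# Fingerprints and Tanimoto similarity.
#
# Two descriptor schemes are provided, mirroring the two families used in
# ligand-based virtual screening: "path" (linear atom/bond paths up to 7
# atoms, FP2-like) and "circular" (iterative Morgan environments to radius
# 2, ECFP4-like). Both hash substructure codes into a fixed bit space and
# are invariant to SMILES atom ordering because they operate on the parsed
# molecular graph with order-independent canonical codes.

.FP_NBITS <- 2048L
.HASH_MOD <- 2147483647  # 2^31 - 1; keeps intermediate products exact doubles

.hash_ints <- function(xs, seed = 5381) {
  h <- seed
  for (x in xs) h <- (h * 33 + (x %% .HASH_MOD)) %% .HASH_MOD
  h
}

.hash_string <- function(s) .hash_ints(utf8ToInt(s))

.atom_code <- function(atoms, i) {
  # element (2 chars worth), aromatic flag, charge, H count folded together
  .hash_ints(c(utf8ToInt(atoms$symbol[i]),
               as.integer(atoms$aromatic[i]),
               atoms$charge[i] + 8L,
               atoms$hcount[i]))
}

.bond_sym <- function(order) {
  if (order == 1) "-" else if (order == 2) "=" else if (order == 3) "#"
  else ":"
}

.mol_adjacency <- function(mol) {
  na <- nrow(mol$atoms)
  adj <- rep(list(NULL), na)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  adj
}

# Linear-path codes: every simple path of 1..max_atoms atoms, encoded as a
# symbol/bond string read in its lexicographically smaller direction (so the
# code does not depend on which end the walk started from).
.path_codes <- function(mol, max_atoms = 7L) {
  atoms <- mol$atoms
  adj <- .mol_adjacency(mol)
  sym <- ifelse(atoms$aromatic, tolower(atoms$symbol), atoms$symbol)
  sym <- ifelse(atoms$charge == 0L, sym,
                paste0(sym, ifelse(atoms$charge > 0, "+", "-"),
                       abs(atoms$charge)))
  codes <- new.env(parent = emptyenv())
  walk <- function(path_atoms, fwd, rev) {
    key <- if (fwd <= rev) fwd else rev
    assign(as.character(.hash_string(key)), TRUE, envir = codes)
    if (length(path_atoms) >= max_atoms) return(invisible())
    tip <- path_atoms[length(path_atoms)]
    nb <- adj[[tip]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% path_atoms) next
      bs <- .bond_sym(nb[r, 2])
      walk(c(path_atoms, nxt),
           paste0(fwd, bs, sym[nxt]),
           paste0(sym[nxt], bs, rev))
    }
    invisible()
  }
  for (a in seq_len(nrow(atoms))) walk(a, sym[a], sym[a])
  as.numeric(ls(envir = codes))
}

# Morgan environment codes to the given radius (radius 2 = ECFP4-like).
.circular_codes <- function(mol, radius = 2L) {
  atoms <- mol$atoms
  adj <- .mol_adjacency(mol)
  code <- vapply(seq_len(nrow(atoms)), function(i) .atom_code(atoms, i), 0)
  all_codes <- code
  for (r in seq_len(radius)) {
    nxt <- numeric(length(code))
    for (i in seq_along(code)) {
      nb <- adj[[i]]
      if (is.null(nb)) {
        nxt[i] <- .hash_ints(c(r, code[i]))
      } else {
        pair <- nb[, 1, drop = TRUE]
        ord <- order(code[pair], nb[, 2])
        nxt[i] <- .hash_ints(c(r, code[i],
                               as.vector(rbind(nb[ord, 2] * 10,
                                               code[pair][ord]))))
      }
    }
    code <- nxt
    all_codes <- c(all_codes, code)
  }
  unique(all_codes)
}

#' Compute a molecular fingerprint from a SMILES string
#'
#' @param smiles A SMILES string (parsed with [parse_smiles()]; invalid input
#'   is an error).
#' @param scheme `"path"` for a linear path descriptor (FP2-like) or
#'   `"circular"` for an iterative Morgan descriptor of radius 2 (ECFP4-like).
#' @param nbits Size of the hashed bit space.
#' @return An integer vector of set bit positions (sorted, zero-based), with
#'   attributes `scheme` and `nbits`. Deterministic for a given molecule and
#'   scheme, and invariant to the atom ordering of the input SMILES.
#' @examples
#' fp1 <- fingerprint("CCO", "circular")
#' fp2 <- fingerprint("OCC", "circular")
#' identical(fp1, fp2)
#' @export
fingerprint <- function(smiles, scheme = c("circular", "path"),
                        nbits = .FP_NBITS) {
  scheme <- match.arg(scheme)
  mol <- if (inherits(smiles, "smiles_mol")) smiles else parse_smiles(smiles)
  codes <- switch(scheme,
    path = .path_codes(mol),
    circular = .circular_codes(mol)
  )
  bits <- sort(unique(as.integer(codes %% nbits)))
  structure(bits, scheme = scheme, nbits = as.integer(nbits))
}

#' Tanimoto coefficient of two bit-set fingerprints
#'
#' `|a intersect b| / |a union b|`. Both fingerprints must come from the same
#' scheme; two empty bit sets are undefined and raise an error.
#'
#' @param a,b Integer vectors of set bits, as returned by [fingerprint()].
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("fingerprints come from different schemes (", sa, " vs ", sb, ")",
         call. = FALSE)
  }
  if (length(a) == 0L && length(b) == 0L) {
    stop("Tanimoto undefined for two empty bit sets", call. = FALSE)
  }
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

#' Combined similarity score of a query and a library compound
#'
#' A convex combination of per-scheme Tanimoto similarities. This is the
#' package's offline stand-in for proprietary "combined" web-platform scores:
#' a single similarity in `[0, 1]` with the weights exposed rather than
#' hidden.
#'
#' @param query,hit SMILES strings, or lists with a `smiles` element (and
#'   optionally `id` / `cid`).
#' @param weights Named non-negative weights over schemes, summing to 1.
#' @return A one-row data.frame (`query_id`, `cid`, `score`, `descriptor`).
#' @examples
#' combined_score("c1ccccc1", "c1ccccc1")$score  # 1
#' @export
combined_score <- function(query, hit,
                           weights = c(path = 0.5, circular = 0.5)) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  q_sm <- if (is.list(query)) query$smiles else query
  h_sm <- if (is.list(hit)) hit$smiles else hit
  q_id <- if (is.list(query) && !is.null(query$id)) query$id else NA_character_
  h_id <- if (is.list(hit) && !is.null(hit$cid)) hit$cid else NA_character_
  score <- 0
  used <- character()
  for (sc in names(weights)) {
    if (weights[[sc]] == 0) next
    score <- score + weights[[sc]] *
      tanimoto(fingerprint(q_sm, sc), fingerprint(h_sm, sc))
    used <- c(used, sprintf("%s:%g", sc, weights[[sc]]))
  }
  data.frame(query_id = q_id, cid = h_id, score = score,
             descriptor = paste(used, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Screen a compound dataset against an annotated reference library
#'
#' Computes the combined similarity of every active compound against every
#' library compound and returns ranked hits. Hits are sorted per query by
#' descending score with ties broken by ascending `cid`, so output order is
#' deterministic.
#'
#' @param dataset A [herb_dataset] (or a data.frame with `id` and `smiles`).
#' @param library A data.frame with columns `cid` and `smiles` (optional
#'   `name`).
#' @param floor Minimum reported score, in `[0, 1]`; default 0 reports all
#'   pairs so that thresholding can happen downstream.
#' @param weights Passed to [combined_score()].
#' @return A data.frame of similarity hits (`query_id`, `cid`, `score`,
#'   `descriptor`).
#' @export
screen_library <- function(dataset, library, floor = 0,
                           weights = c(path = 0.5, circular = 0.5)) {
  stopifnot(floor >= 0, floor <= 1)
  compounds <- if (inherits(dataset, "herb_dataset")) dataset$compounds
               else dataset
  if (is.null(library) || nrow(library) == 0L) {
    warning("empty library: no hits", call. = FALSE)
    return(data.frame(query_id = character(), cid = character(),
                      score = numeric(), descriptor = character(),
                      stringsAsFactors = FALSE))
  }
  library$cid <- as.character(library$cid)
  schemes <- names(weights)[weights > 0]
  fp_of <- function(smiles_vec) {
    lapply(smiles_vec, function(s) {
      lapply(stats::setNames(schemes, schemes),
             function(sc) fingerprint(s, sc))
    })
  }
  qfp <- fp_of(compounds$smiles)
  lfp <- fp_of(library$smiles)
  rows <- vector("list", nrow(compounds) * nrow(library))
  idx <- 0L
  desc_label <- paste(sprintf("%s:%g", schemes, weights[schemes]),
                      collapse = "+")
  for (i in seq_len(nrow(compounds))) {
    for (j in seq_len(nrow(library))) {
      s <- 0
      for (sc in schemes) {
        s <- s + weights[[sc]] * tanimoto(qfp[[i]][[sc]], lfp[[j]][[sc]])
      }
      if (s >= floor) {
        idx <- idx + 1L
        rows[[idx]] <- list(query_id = compounds$id[i], cid = library$cid[j],
                            score = s)
      }
    }
  }
  if (idx == 0L) {
    return(data.frame(query_id = character(), cid = character(),
                      score = numeric(), descriptor = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(rows[seq_len(idx)], as.data.frame))
  out$descriptor <- desc_label
  out <- out[order(out$query_id, -out$score, out$cid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a similarity hit table
#'
#' Plain CSV with columns `query_id`, `cid`, `score`, `descriptor`.
#' @param hits A hit data.frame from [screen_library()].
#' @param path File path.
#' @export
write_hits <- function(hits, path) {
  utils::write.csv(hits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cid = "character"))
  out
}
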