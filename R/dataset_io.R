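# Compound table I/O and the ADME active-compound screen.
#
# Input tables are TCMSP-style CSVs: one row per (compound, herb) pair with
# a molecule name, isomeric SMILES, oral-bioavailability (OB) and
# drug-likeness (DL) scores. The screen keeps rows with OB >= 0.3 and
# DL >= 0.18 (boundary inclusive) and collapses duplicate compound names
# across herbs into one record with a merged herb set.

.normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Construct a herb dataset
#'
#' @param compounds A data.frame with columns `id`, `name`, `smiles`, `ob`,
#'   `dl` and a list-column `herbs` (character vector of herb names per
#'   compound).
#' @param herbs Character vector of all herb names in the dataset; defaults
#'   to the union over compounds.
#' @param provenance Free-text source note.
#' @return An object of class `herb_dataset`.
#' @export
herb_dataset <- function(compounds, herbs = NULL, provenance = "") {
  stopifnot(is.data.frame(compounds),
            all(c("id", "name", "smiles", "ob", "dl", "herbs") %in%
                  names(compounds)))
  if (anyDuplicated(compounds$id))
    stop("compound ids must be unique within a dataset", call. = FALSE)
  if (any(!is.finite(compounds$ob)) || any(!is.finite(compounds$dl)) ||
      any(compounds$ob < 0) || any(compounds$dl < 0))
    stop("ob and dl must be finite non-negative numbers", call. = FALSE)
  comp_herbs <- unique(unlist(compounds$herbs))
  if (is.null(herbs)) herbs <- comp_herbs
  if (!all(comp_herbs %in% herbs))
    stop("every compound's herbs must be a subset of the dataset herbs",
         call. = FALSE)
  structure(list(herbs = sort(herbs), compounds = compounds,
                 provenance = provenance),
            class = "herb_dataset")
}

#' @export
print.herb_dataset <- function(x, ...) {
  cat("<herb_dataset> ", nrow(x$compounds), " distinct compounds across ",
      length(x$herbs), " herbs\n", sep = "")
  counts <- herb_counts(x)
  for (h in names(counts)) cat("  ", h, ": ", counts[[h]], "\n", sep = "")
  invisible(x)
}

#' Per-herb compound counts and total/distinct summary
#' @param dataset A `herb_dataset`.
#' @return Named integer vector of compounds per herb, with attributes
#'   `total` (sum of per-herb memberships) and `distinct` (rows).
#' @export
herb_counts <- function(dataset) {
  memb <- unlist(dataset$compounds$herbs)
  counts <- if (length(memb) > 0) table(memb) else table(character())
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "total") <- length(memb)
  attr(out, "distinct") <- nrow(dataset$compounds)
  out
}

#' Read a TCMSP-style compound table
#'
#' Accepts header variants `Molecule Name`/`name`, `isomeric_smiles`/
#' `smiles`, `OB`/`ob`, `DL`/`dl`, `Herb`/`herb` and returns a raw
#' data.frame with canonical lowercase column names. No screening is applied.
#'
#' @param path CSV file path.
#' @return data.frame with columns `name`, `smiles`, `ob`, `dl`, `herb`.
#' @export
read_compound_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  nm <- tolower(names(raw))
  pick <- function(...) {
    cand <- c(...)
    hit <- match(cand, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L)
      stop("missing column (any of: ", paste(cand, collapse = ", "),
           ") in ", path, call. = FALSE)
    raw[[hit[1]]]
  }
  data.frame(
    name = as.character(pick("molecule.name", "molecule_name", "name")),
    smiles = as.character(pick("isomeric_smiles", "smiles")),
    ob = suppressWarnings(as.numeric(pick("ob", "oral.bioavailability"))),
    dl = suppressWarnings(as.numeric(pick("dl", "drug.likeness"))),
    herb = as.character(pick("herb", "herb_name")),
    stringsAsFactors = FALSE
  )
}

#' Screen raw compound rows for active compounds
#'
#' Keeps rows with `ob >= ob_min` and `dl >= dl_min` (both boundaries
#' inclusive), drops rows whose SMILES does not parse or whose OB/DL is
#' missing (with a warning, never an error: the pipeline is batch-oriented),
#' and merges duplicate compound names across herbs.
#'
#' @param table data.frame with columns `name`, `smiles`, `ob`, `dl`,
#'   `herb` (see [read_compound_table()]).
#' @param ob_min Oral-bioavailability threshold (default 0.3).
#' @param dl_min Drug-likeness threshold (default 0.18).
#' @param provenance Source note stored on the dataset.
#' @return A [herb_dataset] of active compounds; per-herb counts via
#'   [herb_counts()].
#' @export
screen_active_compounds <- function(table, ob_min = 0.3, dl_min = 0.18,
                                    provenance = "") {
  stopifnot(all(c("name", "smiles", "ob", "dl", "herb") %in% names(table)))
  n0 <- nrow(table)
  bad_score <- !is.finite(table$ob) | !is.finite(table$dl)
  if (any(bad_score)) {
    warning(sum(bad_score), " row(s) dropped: missing or non-finite OB/DL",
            call. = FALSE)
    table <- table[!bad_score, , drop = FALSE]
  }
  parses <- vapply(table$smiles, function(s) {
    !inherits(tryCatch(parse_smiles(s), error = identity), "error")
  }, TRUE, USE.NAMES = FALSE)
  if (any(!parses)) {
    warning(sum(!parses), " row(s) dropped: unparseable SMILES (",
            paste(utils::head(table$name[!parses], 5), collapse = ", "), ")",
            call. = FALSE)
    table <- table[parses, , drop = FALSE]
  }
  keep <- table$ob >= ob_min & table$dl >= dl_min
  active <- table[keep, , drop = FALSE]
  message("screened ", n0, " rows: ", nrow(active),
          " active compound rows retained")
  comp <- data.frame(
    id = sprintf("AC%04d", seq_len(nrow(active))),
    name = active$name,
    smiles = active$smiles,
    ob = active$ob,
    dl = active$dl,
    stringsAsFactors = FALSE
  )
  comp$herbs <- as.list(active$herb)
  ds <- herb_dataset(comp, herbs = sort(unique(table$herb)),
                     provenance = provenance)
  merge_duplicates(ds)
}

#' Collapse duplicate compound records
#'
#' One record per distinct compound name (case-insensitive,
#' whitespace-normalized); herb memberships are unioned. Two records with
#' the same name but different SMILES keep the first structure and log a
#' conflict. Idempotent.
#'
#' @param dataset A [herb_dataset].
#' @return A [herb_dataset] with distinct compound names.
#' @export
merge_duplicates <- function(dataset) {
  stopifnot(inherits(dataset, "herb_dataset"))
  comp <- dataset$compounds
  if (nrow(comp) == 0L) return(dataset)
  key <- .normalize_name(comp$name)
  first_idx <- !duplicated(key)
  groups <- split(seq_len(nrow(comp)), key)
  merged_rows <- lapply(groups, function(ix) {
    ix <- sort(ix)
    smi <- unique(comp$smiles[ix])
    if (length(smi) > 1L) {
      warning("name '", comp$name[ix[1]],
              "' maps to ", length(smi),
              " different SMILES; keeping the first", call. = FALSE)
    }
    row <- comp[ix[1], c("id", "name", "smiles", "ob", "dl"), drop = FALSE]
    row$herbs <- list(sort(unique(unlist(comp$herbs[ix]))))
    row
  })
  # preserve first-occurrence order
  ord <- order(vapply(groups, min, 1L))
  out <- do.call(rbind, merged_rows[ord])
  rownames(out) <- NULL
  total <- nrow(comp)
  if (total != nrow(out)) {
    message(total, " records -> ", nrow(out), " distinct compounds")
  }
  herb_dataset(out, herbs = dataset$herbs, provenance = dataset$provenance)
}

#' Write / read a herb dataset as CSV
#'
#' Column order is fixed (`id`, `name`, `smiles`, `ob`, `dl`, `herbs`) with
#' herb memberships collapsed by `";"`; `read_herb_dataset()` inverts the
#' encoding, so write-then-read round-trips field for field.
#'
#' @param dataset A [herb_dataset].
#' @param path CSV file path.
#' @export
write_herb_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "herb_dataset"))
  df <- dataset$compounds
  out <- data.frame(
    id = df$id, name = df$name, smiles = df$smiles, ob = df$ob, dl = df$dl,
    herbs = vapply(df$herbs, function(h) paste(h, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_herb_dataset
#' @export
read_herb_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  herbs <- strsplit(df$herbs, ";", fixed = TRUE)
  comp <- df[, c("id", "name", "smiles", "ob", "dl"), drop = FALSE]
  comp$herbs <- herbs
  herb_dataset(comp)
}
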