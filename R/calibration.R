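# Similarity-threshold calibration from annotation retrieves.
#
# For each (active compound, toxicity endpoint) pair the reference library
# yields a list of similar compounds with similarity scores and trichotomous
# verdicts: +1 toxic, 0 ambiguous, -1 non-toxic/anti-toxic, NA not
# applicable. Reading that list from the most similar record downward, two
# statistics locate where the evidence stops being trustworthy:
#
#   FEP-SS - the largest (i.e. first-met) score at which a record becomes
#            elusive relative to the anchor verdict: an ambiguous record when
#            the anchor is definite, or any definite record when the anchor
#            is itself ambiguous;
#   FCP-SS - the largest score at which a record directly contradicts a
#            definite anchor verdict (defined only for definite anchors).
#
# The anchor is the highest-scoring record with a non-NA verdict. Both scans
# are independent (an elusive record does not stop the contrast scan), skip
# NA verdicts throughout, and consider only records strictly below the
# anchor score. The calibrated prediction threshold is the mean FCP-SS after
# excluding low-information values (<= 0.3 by default).

.VERDICT_LEVELS <- c(-1L, 0L, 1L)

.coerce_verdict <- function(v) {
  if (is.numeric(v)) {
    out <- as.integer(v)
  } else {
    v <- trimws(as.character(v))
    v[v %in% c("N.A.", "NA", "na", "n.a.", "")] <- NA
    out <- suppressWarnings(as.integer(gsub("−", "-", v)))
  }
  bad <- !is.na(out) & !(out %in% .VERDICT_LEVELS)
  if (any(bad))
    stop("verdicts must be one of +1, 0, -1, NA; got ",
         paste(unique(out[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Build a retrieve sequence for one (compound, endpoint) pair
#'
#' Records are sorted by descending similarity score; exact duplicate
#' (`cid`, `score`, `verdict`) records are dropped before any statistic is
#' computed (annotation mining can return verbatim duplicates).
#'
#' @param query_id Active-compound identifier.
#' @param endpoint Toxicity section label (e.g. `"Hepatotoxicity"`).
#' @param score Similarity scores in `[0, 1]`.
#' @param verdict Verdicts: `+1` toxic, `0` ambiguous, `-1` non-toxic,
#'   `NA` not applicable (also accepts `"N.A."` strings).
#' @param cid Optional library-compound ids (used for deduplication).
#' @return A data.frame of class `retrieve_sequence`, sorted by descending
#'   score, with attributes `query_id` and `endpoint`.
#' @export
retrieve_sequence <- function(query_id, endpoint, score, verdict,
                              cid = NULL) {
  verdict <- .coerce_verdict(verdict)
  score <- as.numeric(score)
  if (length(score) != length(verdict))
    stop("score and verdict lengths differ", call. = FALSE)
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop("scores must be finite and in [0, 1]", call. = FALSE)
  if (is.null(cid)) cid <- rep(NA_character_, length(score))
  df <- data.frame(cid = as.character(cid), score = score, verdict = verdict,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("cid", "score", "verdict")]), , drop = FALSE]
  df <- df[order(-df$score, df$cid), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, query_id = as.character(query_id),
            endpoint = as.character(endpoint),
            class = c("retrieve_sequence", "data.frame"))
}

#' Anchor verdict of a retrieve sequence
#'
#' The verdict of the highest-scoring record whose verdict is not NA. If
#' several records tie at that score with different verdicts, the most
#' cautionary one wins (`+1` over `0` over `-1`).
#'
#' @param seq A [retrieve_sequence()].
#' @return `+1`, `0`, `-1`, or `NA` if no record carries a verdict.
#' @export
anchor_verdict <- function(seq) {
  known <- seq[!is.na(seq$verdict), , drop = FALSE]
  if (nrow(known) == 0L) return(NA_integer_)
  top <- known[known$score == max(known$score), , drop = FALSE]
  max(top$verdict)  # +1 > 0 > -1: cautionary tie-break
}

.anchor_score <- function(seq) {
  known <- seq[!is.na(seq$verdict), , drop = FALSE]
  if (nrow(known) == 0L) return(NA_real_)
  max(known$score)
}

#' First elusive prediction-similarity score (FEP-SS)
#'
#' Scanning down from the anchor, the score of the first record whose
#' verdict is elusive relative to the anchor: ambiguous (`0`) when the
#' anchor is definite (`+1`/`-1`), or definite when the anchor is ambiguous.
#' Formally the maximum qualifying score strictly below the anchor score;
#' NA-verdict records are skipped.
#'
#' @param seq A [retrieve_sequence()].
#' @return The FEP-SS, or `NA` if no qualifying record exists.
#' @export
compute_fep_ss <- function(seq) {
  v0 <- anchor_verdict(seq)
  if (is.na(v0)) return(NA_real_)
  s0 <- .anchor_score(seq)
  below <- seq[!is.na(seq$verdict) & seq$score < s0, , drop = FALSE]
  qual <- if (v0 %in% c(-1L, 1L)) below$verdict == 0L
          else below$verdict %in% c(-1L, 1L)
  if (!any(qual)) return(NA_real_)
  max(below$score[qual])
}

#' First contrast prediction-similarity score (FCP-SS)
#'
#' Scanning down from a definite anchor (`+1` or `-1`), the score of the
#' first record carrying the opposite definite verdict. Undefined (NA) when
#' the anchor is ambiguous or absent, or when no contradicting record
#' exists.
#'
#' @param seq A [retrieve_sequence()].
#' @return The FCP-SS, or `NA`.
#' @export
compute_fcp_ss <- function(seq) {
  v0 <- anchor_verdict(seq)
  if (is.na(v0) || v0 == 0L) return(NA_real_)
  s0 <- .anchor_score(seq)
  below <- seq[!is.na(seq$verdict) & seq$score < s0, , drop = FALSE]
  qual <- below$verdict == -v0
  if (!any(qual)) return(NA_real_)
  max(below$score[qual])
}

#' Read an annotation-retrieve table
#'
#' CSV with columns `query_id`, `cid`, `score`, `endpoint`, `verdict`
#' (verdict accepts `1`, `0`, `-1`, `N.A.`).
#'
#' @param path File path.
#' @return data.frame of retrieves.
#' @export
read_retrieves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cid = "character"))
  stopifnot(all(c("query_id", "cid", "score", "endpoint", "verdict") %in%
                  names(df)))
  df$verdict <- .coerce_verdict(df$verdict)
  df$score <- as.numeric(df$score)
  df
}

#' Per-pair FEP-SS / FCP-SS table from a retrieve table
#'
#' Splits a long retrieve table by (query_id, endpoint) and computes both
#' statistics for every pair.
#'
#' @param retrieves data.frame with columns `query_id`, `cid`, `score`,
#'   `endpoint`, `verdict` (see [read_retrieves()]).
#' @return data.frame with columns `query_id`, `endpoint`, `fep_ss`,
#'   `fcp_ss`.
#' @export
pair_scores <- function(retrieves) {
  keys <- interaction(retrieves$query_id, retrieves$endpoint, drop = TRUE,
                      sep = "\r")
  parts <- split(retrieves, keys)
  rows <- lapply(parts, function(p) {
    s <- retrieve_sequence(p$query_id[1], p$endpoint[1], p$score, p$verdict,
                           cid = p$cid)
    data.frame(query_id = p$query_id[1], endpoint = p$endpoint[1],
               fep_ss = compute_fep_ss(s), fcp_ss = compute_fcp_ss(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id, out$endpoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the global similarity-score threshold
#'
#' Summarizes per-pair FEP-SS/FCP-SS values after excluding low-information
#' values (`<= cutoff`, which typically reflect sparse annotation rather
#' than a real contrast) and sets the prediction threshold to the mean of
#' the surviving FCP-SS values. The third quartile uses linear interpolation
#' between order statistics (`stats::quantile` type 7), pinned so the
#' summary is well-defined.
#'
#' @param results data.frame with columns `fep_ss` and `fcp_ss` (one row per
#'   compound-endpoint pair, NAs allowed), as from [pair_scores()].
#' @param cutoff Exclusion cutoff applied to the summary only (default 0.3;
#'   per-pair values are reported in full).
#' @return An object of class `calibration_result`: list with `per_pair`,
#'   `exclusion_cutoff`, `summary` (`mean_fcp`, `mean_fep`, `q3_fcp`,
#'   `counts`) and `chosen_threshold` (= `mean_fcp`).
#' @export
calibrate_threshold <- function(results, cutoff = 0.3) {
  stopifnot(is.data.frame(results),
            all(c("fep_ss", "fcp_ss") %in% names(results)))
  fcp <- results$fcp_ss[!is.na(results$fcp_ss) & results$fcp_ss > cutoff]
  fep <- results$fep_ss[!is.na(results$fep_ss) & results$fep_ss > cutoff]
  if (length(fcp) == 0L && length(fep) == 0L) {
    warning("no FEP-SS/FCP-SS values survive the cutoff; summary is NA",
            call. = FALSE)
  }
  summ <- list(
    mean_fcp = if (length(fcp) > 0) mean(fcp) else NA_real_,
    mean_fep = if (length(fep) > 0) mean(fep) else NA_real_,
    q3_fcp = if (length(fcp) > 0)
      unname(stats::quantile(fcp, 0.75, type = 7)) else NA_real_,
    counts = c(n_fcp = length(fcp), n_fep = length(fep))
  )
  structure(list(per_pair = results, exclusion_cutoff = cutoff,
                 summary = summ, chosen_threshold = summ$mean_fcp),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat("  pairs:              ", nrow(x$per_pair), "\n")
  cat("  exclusion cutoff:   <= ", x$exclusion_cutoff, "\n", sep = "")
  cat("  mean FCP-SS:        ", format(x$summary$mean_fcp), " (n = ",
      x$summary$counts[["n_fcp"]], ")\n", sep = "")
  cat("  mean FEP-SS:        ", format(x$summary$mean_fep), " (n = ",
      x$summary$counts[["n_fep"]], ")\n", sep = "")
  cat("  Q3 FCP-SS:          ", format(x$summary$q3_fcp), "\n", sep = "")
  cat("  chosen threshold:   ", format(x$chosen_threshold), "\n", sep = "")
  invisible(x)
}

#' Write a calibration result to a directory
#'
#' Emits `pair_scores.csv` (per-pair table) and `calibration_summary.txt`
#' (key:value lines, machine-parseable).
#'
#' @param result A `calibration_result`.
#' @param dir Output directory (created if needed).
#' @export
write_calibration <- function(result, dir) {
  stopifnot(inherits(result, "calibration_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$per_pair, file.path(dir, "pair_scores.csv"),
                   row.names = FALSE)
  lines <- c(
    sprintf("exclusion_cutoff: %g", result$exclusion_cutoff),
    sprintf("mean_fcp: %s", format(result$summary$mean_fcp, digits = 10)),
    sprintf("mean_fep: %s", format(result$summary$mean_fep, digits = 10)),
    sprintf("q3_fcp: %s", format(result$summary$q3_fcp, digits = 10)),
    sprintf("n_fcp: %d", result$summary$counts[["n_fcp"]]),
    sprintf("n_fep: %d", result$summary$counts[["n_fep"]]),
    sprintf("chosen_threshold: %s",
            format(result$chosen_threshold, digits = 10))
  )
  writeLines(lines, file.path(dir, "calibration_summary.txt"))
  invisible(dir)
}

#' Worked-example retrieve table
#'
#' A small annotation-retrieve table for three phytosterol-like compounds
#' (hepatotoxicity and carcinogenicity endpoints), shipped with the package
#' as a desk-scale worked example of the calibration statistics; it
#' includes an exact duplicated row, an NA-verdict top record, and all
#' three anchor situations. See the methods vignette for the walk-through.
#'
#' @return data.frame of retrieves (see [read_retrieves()]).
#' @export
example_retrieves <- function() {
  read_retrieves(system.file("extdata", "sterol_retrieves_example.csv",
                             package = "herbscreen", mustWork = TRUE))
}

#' Default prediction threshold
#'
#' The similarity-score threshold shipped as the package default: the mean
#' first-contrast prediction-similarity score observed across a 20-herb
#' calibration study. Recomputable from any user-supplied retrieve table via
#' [calibrate_threshold()].
#' @export
DEFAULT_SIMILARITY_THRESHOLD <- 0.6171
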