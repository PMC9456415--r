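# Dose-response synergy quantification.
#
# Three layers: (1) four-parameter logistic (4PL) fits of single-agent
# dose-response curves on a log10-dose axis; (2) the Combination Index
# CI = D1/Dx1 + D2/Dx2 (< 1 synergistic, = 1 additive, > 1 antagonistic);
# (3) zero-interaction-potency (ZIP) delta scoring of two-drug inhibition
# matrices, where the null expectation for inhibition fractions is
# y1 + y2 - y1*y2 and the reported delta is observed minus expected in
# percentage points, with a 3x3 most-synergistic-area (MSA) scan.

#' Construct a dose-response curve
#'
#' @param doses Strictly positive concentrations.
#' @param responses Response fractions in `[0, 1]` (clipped values slightly
#'   outside are tolerated up to 0.05).
#' @param orientation `"inhibition"` (rises with dose) or `"viability"`
#'   (falls with dose).
#' @param units Unit label carried through reports (e.g. `"nM"`,
#'   `"ug/mL"`).
#' @return Object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(doses, responses,
                                orientation = c("inhibition", "viability"),
                                units = "") {
  orientation <- match.arg(orientation)
  stopifnot(length(doses) == length(responses))
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("doses must be strictly positive (log-dose model)", call. = FALSE)
  if (any(!is.finite(responses)) || any(responses < -0.05) ||
      any(responses > 1.05))
    stop("responses must be fractions in [0, 1]", call. = FALSE)
  structure(list(doses = as.numeric(doses),
                 responses = pmin(pmax(as.numeric(responses), 0), 1),
                 orientation = orientation, units = units),
            class = "dose_response_curve")
}

.fourpl <- function(logd, bottom, top, logIC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logIC50 - logd) * hill))
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((logIC50 - log10(dose)) * hill))`
#' with deterministic data-driven initialization: asymptotes from the data
#' extremes, logIC50 from the dose bracketing the half-range, and Hill
#' slope of magnitude 1 signed by the orientation. Degenerate flat data and
#' non-convergent fits are explicit errors, never a spurious IC50.
#'
#' @param curve A [dose_response_curve()] (needs >= 4 distinct doses).
#' @return Object of class `fourpl_fit`: `bottom`, `top`, `logIC50`,
#'   `hill`, `ic50`, `r_squared`, `in_range` (whether the IC50 lies within
#'   the tested dose range), plus the input curve.
#' @examples
#' d <- 10^seq(-2, 2, length.out = 8)
#' y <- 1 / (1 + (2 / d))       # ic50 = 2, hill = 1
#' fit <- fit_4pl(dose_response_curve(d, y))
#' fit$ic50
#' @export
fit_4pl <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  d <- curve$doses; y <- curve$responses
  if (length(unique(d)) < 4L)
    stop("4PL fit needs at least 4 distinct doses", call. = FALSE)
  if (stats::sd(y) < 1e-8)
    stop("degenerate flat dose-response data: no IC50 estimable",
         call. = FALSE)
  logd <- log10(d)
  rising <- curve$orientation == "inhibition"
  b0 <- min(y); t0 <- max(y)
  h0 <- if (rising) 1 else -1
  mid <- (b0 + t0) / 2
  ord <- order(logd)
  cross <- which(diff(sign(y[ord] - mid)) != 0)
  l0 <- if (length(cross) > 0) {
    mean(logd[ord][c(cross[1], cross[1] + 1L)])
  } else stats::median(logd)
  fit_once <- function(start) {
    stats::nls(
      y ~ .fourpl(logd, bottom, top, logIC50, hill),
      data = data.frame(logd = logd, y = y),
      start = start, algorithm = "port",
      lower = c(bottom = -0.5, top = 0, logIC50 = min(logd) - 4,
                hill = if (rising) 1e-3 else -50),
      upper = c(bottom = 1, top = 1.5, logIC50 = max(logd) + 4,
                hill = if (rising) 50 else -1e-3),
      control = stats::nls.control(maxiter = 500, warnOnly = FALSE)
    )
  }
  start <- list(bottom = b0, top = t0, logIC50 = l0, hill = h0)
  fit <- tryCatch(fit_once(start), error = identity)
  if (inherits(fit, "error")) {
    # deterministic fallback: direct least squares over the same box
    obj <- function(p) sum((y - .fourpl(logd, p[1], p[2], p[3], p[4]))^2)
    op <- stats::optim(unlist(start), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    if (op$convergence != 0)
      stop("4PL fit did not converge: ", conditionMessage(fit),
           call. = FALSE)
    coefs <- op$par
  } else {
    coefs <- stats::coef(fit)
  }
  names(coefs) <- c("bottom", "top", "logIC50", "hill")
  if (coefs[["bottom"]] > coefs[["top"]]) {
    stop("degenerate 4PL fit: bottom exceeds top", call. = FALSE)
  }
  pred <- .fourpl(logd, coefs[["bottom"]], coefs[["top"]],
                  coefs[["logIC50"]], coefs[["hill"]])
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  ic50 <- 10^coefs[["logIC50"]]
  structure(list(bottom = unname(coefs[["bottom"]]),
                 top = unname(coefs[["top"]]),
                 logIC50 = unname(coefs[["logIC50"]]),
                 hill = unname(coefs[["hill"]]),
                 ic50 = ic50, r_squared = r2,
                 in_range = ic50 >= min(d) && ic50 <= max(d),
                 curve = curve),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("<fourpl_fit> IC50 = ", format(x$ic50, digits = 4),
      if (nzchar(x$curve$units)) paste0(" ", x$curve$units) else "",
      " (hill = ", format(x$hill, digits = 3),
      ", R^2 = ", format(x$r_squared, digits = 4), ")",
      if (!x$in_range) " [IC50 outside tested dose range]", "\n", sep = "")
  invisible(x)
}

#' Combination Index of a two-drug combination
#'
#' `CI = D1/Dx1 + D2/Dx2`, where `Dx1`, `Dx2` are the single-agent doses of
#' drug 1 and drug 2 producing a given effect level, and `D1`, `D2` are the
#' doses in combination producing the same effect. `CI < 1` is called
#' synergistic, `= 1` additive, `> 1` antagonistic. Unit labels, when
#' supplied, must match within each drug; the index itself is unitless and
#' invariant to rescaling any one drug's dose axis.
#'
#' @param dx1,dx2 Single-agent equi-effective doses (> 0).
#' @param d1,d2 Combination doses (>= 0) in the same units as the matching
#'   `dx`.
#' @param units1,units2 Optional length-2 character vectors `c(dx, d)` of
#'   unit labels for drug 1 and drug 2.
#' @return Object of class `combination_index`: `ci` and `call`
#'   (`"synergistic"` / `"additive"` / `"antagonistic"`).
#' @examples
#' combination_index(70.48, 1.85, 4.73, 1.18)$ci  # ~0.70
#' @export
combination_index <- function(dx1, dx2, d1, d2,
                              units1 = NULL, units2 = NULL) {
  check_units <- function(u, drug) {
    if (!is.null(u) && length(u) == 2L && !identical(u[[1]], u[[2]]))
      stop("unit mismatch within drug ", drug, ": ", u[[1]], " vs ", u[[2]],
           call. = FALSE)
  }
  check_units(units1, 1); check_units(units2, 2)
  stopifnot(is.finite(dx1), is.finite(dx2), dx1 > 0, dx2 > 0,
            is.finite(d1), is.finite(d2), d1 >= 0, d2 >= 0)
  ci <- d1 / dx1 + d2 / dx2
  call <- if (ci < 1) "synergistic" else if (ci > 1) "antagonistic"
          else "additive"
  structure(list(ci = ci, call = call), class = "combination_index")
}

#' @export
print.combination_index <- function(x, ...) {
  cat("Combination Index = ", format(x$ci, digits = 3), " (", x$call, ")\n",
      sep = "")
  invisible(x)
}

#' Construct a two-drug dose-response (inhibition) matrix
#'
#' Rows are doses of drug 1, columns doses of drug 2. The first row and the
#' first column must be the monotherapy margins, i.e. `row_doses[1] == 0`
#' and `col_doses[1] == 0`.
#'
#' @param row_doses,col_doses Dose vectors including the leading 0.
#' @param inhibition Matrix of inhibition fractions in `[0, 1]`,
#'   `length(row_doses)` x `length(col_doses)`.
#' @param units Length-2 unit labels `c(drug1, drug2)`.
#' @return Object of class `dose_response_matrix`.
#' @export
dose_response_matrix <- function(row_doses, col_doses, inhibition,
                                 units = c("", "")) {
  inhibition <- as.matrix(inhibition)
  stopifnot(nrow(inhibition) == length(row_doses),
            ncol(inhibition) == length(col_doses))
  if (row_doses[1] != 0 || col_doses[1] != 0)
    stop("first row and first column must be the 0-dose monotherapy margins",
         call. = FALSE)
  if (any(row_doses[-1] <= 0) || any(col_doses[-1] <= 0))
    stop("non-margin doses must be strictly positive", call. = FALSE)
  if (any(!is.finite(inhibition)) || any(inhibition < -0.05) ||
      any(inhibition > 1.05))
    stop("inhibition values must be fractions in [0, 1]", call. = FALSE)
  structure(list(row_doses = as.numeric(row_doses),
                 col_doses = as.numeric(col_doses),
                 inhibition = pmin(pmax(inhibition, 0), 1),
                 units = units),
            class = "dose_response_matrix")
}

#' Read / write a dose-response matrix as CSV
#'
#' The grid layout mirrors plate exports: first column holds the drug-1
#' doses, the header row the drug-2 doses, the top-left cell the label
#' `dose`.
#'
#' @param path File path.
#' @param mat A `dose_response_matrix`.
#' @export
read_dose_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  row_doses <- as.numeric(df[[1]])
  col_doses <- as.numeric(names(df)[-1])
  dose_response_matrix(row_doses, col_doses,
                       as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_dose_matrix
#' @export
write_dose_matrix <- function(mat, path) {
  df <- as.data.frame(mat$inhibition)
  names(df) <- as.character(mat$col_doses)
  df <- cbind(dose = mat$row_doses, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# 3-parameter logistic (bottom = 0) monotherapy fit on the inhibition scale.
.fit_margin <- function(doses, inhib) {
  logd <- log10(doses)
  t0 <- max(max(inhib), 0.05)
  mid <- t0 / 2
  ord <- order(logd)
  cross <- which(diff(sign(inhib[ord] - mid)) != 0)
  l0 <- if (length(cross) > 0) mean(logd[ord][c(cross[1], cross[1] + 1L)])
        else stats::median(logd)
  # port needs more observations than parameters (and can spin on
  # degenerate margins); short margins go straight to direct least squares
  fit <- if (length(logd) < 4L) simpleError("margin too short for nls")
  else
  # port reports benign "false convergence" on near-perfect data; keep the
  # fit and judge it by its residuals instead
  suppressWarnings(tryCatch(
    stats::nls(
      inhib ~ top / (1 + 10^((logIC50 - logd) * hill)),
      data = data.frame(logd = logd, inhib = inhib),
      start = list(top = t0, logIC50 = l0, hill = 1),
      algorithm = "port",
      lower = c(top = 1e-6, logIC50 = min(logd) - 4, hill = 1e-3),
      upper = c(top = 1, logIC50 = max(logd) + 4, hill = 50),
      control = stats::nls.control(maxiter = 500, warnOnly = TRUE)
    ),
    error = identity
  ))
  if (inherits(fit, "error")) {
    obj <- function(p) {
      p <- pmin(pmax(p, c(1e-6, min(logd) - 4, 1e-3)), c(1, max(logd) + 4, 50))
      sum((inhib - p[1] / (1 + 10^((p[2] - logd) * p[3])))^2)
    }
    par <- stats::optim(c(t0, l0, 1), obj, method = "Nelder-Mead",
                        control = list(maxit = 5000))$par
    par <- pmin(pmax(par, c(1e-6, min(logd) - 4, 1e-3)),
                c(1, max(logd) + 4, 50))
    coefs <- c(top = par[1], logIC50 = par[2], hill = par[3])
  } else {
    coefs <- stats::coef(fit)
  }
  function(d) {
    unname(coefs[["top"]] /
             (1 + 10^((coefs[["logIC50"]] - log10(d)) * coefs[["hill"]])))
  }
}

#' ZIP delta scoring of a two-drug inhibition matrix
#'
#' Fits a logistic monotherapy curve to each margin (bottom fixed at 0, top
#' in (0, 1]), forms the zero-interaction expectation
#' `y_zip = y1 + y2 - y1*y2` on every combination cell, and reports
#' `delta = observed - y_zip` in percentage points (no smoothing of the
#' observed cells). The most synergistic area is the maximum mean delta
#' over all contiguous 3x3 windows of the combination block; smaller
#' blocks fall back to the largest available window with a warning.
#'
#' @param mat A [dose_response_matrix()].
#' @return Object of class `synergy_result`: `zip_delta` (delta matrix in
#'   percentage points over combination cells, with dose dimnames),
#'   `zip_mean`, `msa` (list `score`, `window` = top-left row/col dose
#'   indices within the combination block, `size`), and the margin fit
#'   functions.
#' @export
zip_delta <- function(mat) {
  stopifnot(inherits(mat, "dose_response_matrix"))
  rd <- mat$row_doses[-1]; cd <- mat$col_doses[-1]
  if (length(rd) < 1L || length(cd) < 1L)
    stop("no combination cells in matrix", call. = FALSE)
  f1 <- .fit_margin(rd, mat$inhibition[-1, 1])  # drug 1 alone (column margin)
  f2 <- .fit_margin(cd, mat$inhibition[1, -1])  # drug 2 alone (row margin)
  y1 <- f1(rd); y2 <- f2(cd)
  null <- outer(y1, y2, function(a, b) a + b - a * b)
  obs <- mat$inhibition[-1, -1, drop = FALSE]
  delta <- (obs - null) * 100
  dimnames(delta) <- list(as.character(rd), as.character(cd))
  msa <- .max_window_mean(delta, 3L)
  structure(list(zip_delta = delta, zip_mean = mean(delta), msa = msa,
                 margin_fit_1 = f1, margin_fit_2 = f2, matrix = mat),
            class = "synergy_result")
}

.max_window_mean <- function(delta, w = 3L) {
  nr <- nrow(delta); nc <- ncol(delta)
  wr <- min(w, nr); wc <- min(w, nc)
  if (wr < w || wc < w) {
    warning("combination block smaller than ", w, "x", w,
            "; MSA computed over a ", wr, "x", wc, " window", call. = FALSE)
  }
  best <- -Inf; at <- c(1L, 1L)
  for (i in seq_len(nr - wr + 1L)) {
    for (j in seq_len(nc - wc + 1L)) {
      m <- mean(delta[i:(i + wr - 1L), j:(j + wc - 1L)])
      if (m > best) { best <- m; at <- c(i, j) }
    }
  }
  list(score = best, window = at, size = c(wr, wc))
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("<synergy_result> ", nrow(x$zip_delta), "x", ncol(x$zip_delta),
      " combination block\n", sep = "")
  cat("  mean ZIP delta: ", format(x$zip_mean, digits = 4),
      " percentage points\n", sep = "")
  cat("  most synergistic area: ", format(x$msa$score, digits = 4),
      " (", x$msa$size[1], "x", x$msa$size[2], " window at [",
      x$msa$window[1], ",", x$msa$window[2], "])\n", sep = "")
  invisible(x)
}

#' Write a synergy result to a directory
#'
#' Emits `zip_delta.csv` (delta matrix) and `synergy_summary.txt`
#' (key:value lines: zip_mean, msa score and window).
#'
#' @param result A `synergy_result`.
#' @param dir Output directory.
#' @export
write_synergy <- function(result, dir) {
  stopifnot(inherits(result, "synergy_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(result$zip_delta),
                   file.path(dir, "zip_delta.csv"))
  writeLines(c(
    sprintf("zip_mean: %s", format(result$zip_mean, digits = 10)),
    sprintf("msa_score: %s", format(result$msa$score, digits = 10)),
    sprintf("msa_window: %d,%d", result$msa$window[1], result$msa$window[2]),
    sprintf("msa_size: %dx%d", result$msa$size[1], result$msa$size[2])
  ), file.path(dir, "synergy_summary.txt"))
  invisible(dir)
}
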