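test_that("4PL fit recovers exact model parameters", {
  d <- 10^seq(-2, 2, length.out = 8)
  y <- .0 + (1 - 0) / (1 + 10^((log10(2) - log10(d)) * 1))
  fit <- fit_4pl(dose_response_curve(d, y))
  expect_lt(abs(fit$bottom - 0), 1e-6)
  expect_lt(abs(fit$top - 1), 1e-6)
  expect_lt(abs(fit$ic50 - 2), 1e-6)
  expect_lt(abs(fit$hill - 1), 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("4PL fit is scale-equivariant in dose", {
  d <- 10^seq(-1, 3, length.out = 8)
  y <- 0.05 + 0.9 / (1 + 10^((log10(30) - log10(d)) * 1.5))
  f1 <- fit_4pl(dose_response_curve(d, y))
  f2 <- fit_4pl(dose_response_curve(d * 7, y))
  expect_equal(f2$ic50 / f1$ic50, 7, tolerance = 1e-5)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-5)
})

test_that("hill sign follows orientation and degenerate input errors", {
  d <- 10^seq(-2, 2, length.out = 8)
  viab <- 1 - 1 / (1 + 10^((log10(2) - log10(d)) * 1))  # falls with dose
  fit <- fit_4pl(dose_response_curve(d, viab, orientation = "viability"))
  expect_lt(fit$hill, 0)
  expect_error(fit_4pl(dose_response_curve(d, rep(0.5, 8))), "flat")
  expect_error(fit_4pl(dose_response_curve(d[1:3], viab[1:3])), "4 distinct")
  expect_error(dose_response_curve(c(0, 1, 2, 3), rep(0.2, 4)),
               "strictly positive")
})

test_that("combination index matches hand arithmetic and unit rules", {
  ci <- combination_index(70.48, 1.85, 4.73, 1.18)
  expect_equal(round(ci$ci, 2), 0.70)
  expect_equal(ci$call, "synergistic")
  expect_equal(combination_index(10, 5, 10, 0)$ci, 1)        # single-agent
  expect_equal(combination_index(10, 5, 10, 5)$ci, 2)        # full doses
  expect_equal(combination_index(10, 5, 10, 0)$call, "additive")
  # unit invariance: rescaling one drug's axis leaves CI unchanged
  expect_equal(combination_index(70.48, 1.85, 4.73, 1.18)$ci,
               combination_index(70.48 * 1000, 1.85, 4730, 1.18)$ci)
  expect_error(combination_index(1, 1, 1, 1, units1 = c("nM", "uM")),
               "unit mismatch")
})

test_that("zip_delta is near zero on exact null matrices", {
  mat <- gen_zip_matrix(hill1 = list(top = 0.9, ic50 = 2, hill = 1.2),
                        hill2 = list(top = 0.8, ic50 = 5, hill = 0.8),
                        sigma = 0, seed = 1)
  res <- zip_delta(mat)
  expect_lt(abs(res$zip_mean), 0.5)           # percentage points
  expect_lt(max(abs(res$zip_delta)), 0.5)
})

test_that("per-cell delta matches the cellwise oracle", {
  mat <- gen_zip_matrix(sigma = 0.02, seed = 12)
  res <- zip_delta(mat)
  rd <- mat$row_doses[-1]; cd <- mat$col_doses[-1]
  y1 <- res$margin_fit_1(rd); y2 <- res$margin_fit_2(cd)
  # brute-force spreadsheet-style loop over every combination cell
  for (i in seq_along(rd)) {
    for (j in seq_along(cd)) {
      expected <- (mat$inhibition[i + 1, j + 1] -
                     (y1[i] + y2[j] - y1[i] * y2[j])) * 100
      expect_equal(res$zip_delta[i, j], expected, tolerance = 1e-9)
    }
  }
  # same margins recomputed from the true generating curves
  true1 <- 1 / (1 + (1 / rd)^1); true2 <- 1 / (1 + (1 / cd)^1)
  expect_equal(y1, true1, tolerance = 0.05)
  expect_equal(y2, true2, tolerance = 0.05)
})

# plant-and-recover worlds use sub-saturating monotherapy curves so the
# +10-point plant never clips at 100% inhibition
.headroom <- list(top = 0.6, ic50 = 20, hill = 1)

test_that("a planted uniform delta is recovered in mean and MSA", {
  mat <- gen_zip_matrix(.headroom, .headroom, delta_field = 0.10,
                        sigma = 0, seed = 2)
  res <- zip_delta(mat)
  expect_lt(abs(res$zip_mean - 10), 1)
  expect_lt(abs(res$msa$score - 10), 1)
})

test_that("MSA localizes a planted corner block", {
  delta <- matrix(0, 5, 5)
  delta[1:3, 1:3] <- 0.10
  mat <- gen_zip_matrix(.headroom, .headroom, delta_field = delta,
                        sigma = 0, seed = 3)
  res <- zip_delta(mat)
  expect_equal(res$msa$window, c(1L, 1L))
  expect_lt(abs(res$msa$score - 10), 1)
})

test_that("small matrices fall back to the largest window with a warning", {
  mat <- gen_zip_matrix(row_doses = c(1, 10), col_doses = c(1, 10),
                        sigma = 0, seed = 4)
  expect_warning(res <- zip_delta(mat), "MSA")
  expect_equal(res$msa$size, c(2L, 2L))
})

test_that("dose matrices round-trip through CSV and validate margins", {
  mat <- gen_zip_matrix(sigma = 0.01, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_matrix(mat, path)
  back <- read_dose_matrix(path)
  expect_equal(back$inhibition, mat$inhibition, ignore_attr = TRUE)
  expect_equal(back$row_doses, mat$row_doses)
  expect_error(dose_response_matrix(c(1, 2), c(0, 1), matrix(0, 2, 2)),
               "margins")
})
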