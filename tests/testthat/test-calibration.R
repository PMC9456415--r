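test_that("anchor verdict is the highest-scoring non-NA record", {
  expect_equal(anchor_verdict(sterol_seq("sitosterol")), -1L)   # -1 at 0.804
  expect_equal(anchor_verdict(sterol_seq("hydroxystigmast")), 0L)
  all_na <- retrieve_sequence("q", "Hepatotoxicity",
                              score = c(0.9, 0.5), verdict = c(NA, NA))
  expect_true(is.na(anchor_verdict(all_na)))
  single <- retrieve_sequence("q", "Hepatotoxicity", 0.9, 1)
  expect_equal(anchor_verdict(single), 1L)
})

test_that("FEP-SS follows the first-elusive rule on the worked sequences", {
  expect_equal(compute_fep_ss(sterol_seq("hydroxystigmast")), 0.498)
  expect_true(is.na(compute_fep_ss(sterol_seq("sitosterol"))))
  s <- retrieve_sequence("q", "Hepatotoxicity",
                         score = c(0.9, 0.7, 0.5), verdict = c(1, 0, -1))
  expect_equal(compute_fep_ss(s), 0.7)
})

test_that("FCP-SS follows the first-contrast rule on the worked sequences", {
  expect_equal(compute_fcp_ss(sterol_seq("sitosterol")), 0.588)
  expect_equal(compute_fcp_ss(sterol_seq("campesterol")), 0.594)
  expect_true(is.na(compute_fcp_ss(sterol_seq("hydroxystigmast"))))
})

test_that("duplicated records do not change either statistic", {
  s_dup <- sterol_seq("sitosterol")  # contains the duplicated 0.588 row
  s_clean <- retrieve_sequence("beta-sitosterol", "Hepatotoxicity",
                               score = c(0.999, 0.804, 0.588),
                               verdict = c(NA, -1, 1),
                               cid = c("5997", "5280453", "445354"))
  expect_equal(nrow(s_dup), 3L)
  expect_equal(compute_fcp_ss(s_dup), compute_fcp_ss(s_clean))
  expect_equal(compute_fep_ss(s_dup), compute_fep_ss(s_clean))
})

test_that("independent scans allow FEP-SS below FCP-SS", {
  # digoxin-analog style sequence: contrast met before the elusive record
  s <- retrieve_sequence("olitoriside-like", "Hepatotoxicity",
                         score = c(0.992, 0.449, 0.337),
                         verdict = c(1, -1, 0))
  expect_equal(compute_fcp_ss(s), 0.449)
  expect_equal(compute_fep_ss(s), 0.337)
  expect_lt(compute_fep_ss(s), compute_fcp_ss(s))
})

test_that("statistics are members of the score list and below the anchor", {
  for (seed in 1:50) {
    n <- sample(3:10, 1)
    anchor <- sample(c(-1L, 0L, 1L), 1)
    depths <- sample(2:n, min(2, n - 1))
    sc <- annotation_scenario(
      anchor, n,
      elusive_depth = depths[1],
      contrast_depth = if (anchor != 0L && length(depths) > 1) depths[2],
      seed = seed
    )
    s <- gen_annotation_sequence(sc)
    a_score <- max(s$score[!is.na(s$verdict)])
    for (v in c(compute_fep_ss(s), compute_fcp_ss(s))) {
      if (!is.na(v)) {
        expect_true(v %in% s$score)
        expect_lt(v, a_score)
      }
    }
  }
})

test_that("verdict coercion accepts table-style codes and rejects others", {
  s <- retrieve_sequence("q", "Hepatotoxicity",
                         score = c(0.9, 0.8, 0.7),
                         verdict = c("1", "N.A.", "−1"))  # minus sign
  expect_equal(s$verdict, c(1L, NA, -1L))
  expect_error(retrieve_sequence("q", "e", 0.5, 7), "verdicts")
  expect_error(retrieve_sequence("q", "e", 1.2, 1), "\\[0, 1\\]")
})

test_that("calibrate_threshold excludes low values and pins the quartile", {
  one <- calibrate_threshold(data.frame(fep_ss = NA, fcp_ss = 0.6171))
  expect_equal(one$chosen_threshold, 0.6171)

  res <- calibrate_threshold(
    data.frame(fep_ss = NA, fcp_ss = c(0.2, 0.5, 0.7)), cutoff = 0.3)
  expect_equal(res$summary$mean_fcp, 0.6)  # mean over {0.5, 0.7}
  expect_equal(res$summary$counts[["n_fcp"]], 2L)

  # type-7 linear interpolation, frozen from quantile(c(.4,.5,.6,.7), .75)
  q <- calibrate_threshold(
    data.frame(fep_ss = NA, fcp_ss = c(0.4, 0.5, 0.6, 0.7)), cutoff = 0.3)
  expect_equal(q$summary$q3_fcp, 0.625)

  # cutoff is strictly "<=": a value exactly at the cutoff is excluded
  at <- calibrate_threshold(
    data.frame(fep_ss = NA, fcp_ss = c(0.3, 0.5)), cutoff = 0.3)
  expect_equal(at$summary$counts[["n_fcp"]], 1L)

  expect_warning(
    empty <- calibrate_threshold(data.frame(fep_ss = 0.1, fcp_ss = 0.2)),
    "survive")
  expect_true(is.na(empty$chosen_threshold))
})

test_that("pair_scores reproduces per-sequence statistics from a long table", {
  ret <- example_retrieves()
  ps <- pair_scores(ret)
  hep <- ps[ps$endpoint == "Hepatotoxicity", ]
  expect_equal(hep$fep_ss[hep$query_id == "3-Hydroxystigmast-5-en-7-one"],
               0.498)
  expect_equal(hep$fcp_ss[hep$query_id == "beta-sitosterol"], 0.588)
  expect_equal(hep$fcp_ss[hep$query_id == "campesterol"], 0.594)
  # write/read of the calibration bundle
  dir <- withr::local_tempdir()
  res <- calibrate_threshold(ps)
  write_calibration(res, dir)
  expect_true(file.exists(file.path(dir, "pair_scores.csv")))
  lines <- readLines(file.path(dir, "calibration_summary.txt"))
  expect_true(any(grepl("^chosen_threshold:", lines)))
})

test_that("anchor ties resolve toward the cautionary verdict", {
  s <- retrieve_sequence("q", "e", score = c(0.9, 0.9, 0.5),
                         verdict = c(-1, 1, -1))
  expect_equal(anchor_verdict(s), 1L)
  expect_equal(compute_fcp_ss(s), 0.5)
})
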