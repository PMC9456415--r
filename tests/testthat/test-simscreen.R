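test_that("fingerprints are invariant to SMILES atom ordering", {
  spellings <- list(
    ethanol = c("CCO", "OCC", "C(O)C"),
    benzene = c("c1ccccc1", "C1=CC=CC=C1"),
    phenol = c("c1ccccc1O", "Oc1ccccc1")
  )
  for (scheme in c("path", "circular")) {
    for (sp in spellings) {
      fps <- lapply(sp, fingerprint, scheme = scheme)
      for (k in seq_along(fps)[-1]) {
        expect_identical(as.integer(fps[[1]]), as.integer(fps[[k]]))
      }
    }
  }
  expect_error(fingerprint("c1ccccc1("), "unmatched")
})

test_that("tanimoto matches direct set arithmetic", {
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)  # 2 / 4
  expect_equal(tanimoto(c(5L, 9L), c(5L, 9L)), 1)
  expect_equal(tanimoto(c(1L, 2L), c(3L, 4L)), 0)
  expect_error(tanimoto(integer(), integer()), "empty")
  a <- fingerprint("CCO", "path"); b <- fingerprint("CCO", "circular")
  expect_error(tanimoto(a, b), "schemes")
})

test_that("dissimilar molecules score near zero, identical score one", {
  steroid <- "CC12CCC3C(CCC4CC(O)CCC34C)C1CCC2O"
  expect_lt(tanimoto(fingerprint("C", "path"), fingerprint(steroid, "path")),
            0.1)
  expect_equal(tanimoto(fingerprint("C", "circular"),
                        fingerprint(steroid, "circular")), 0)
  expect_equal(combined_score("c1ccccc1", "c1ccccc1")$score, 1)
})

test_that("combined score is a convex combination and symmetric", {
  q <- "c1ccccc1O"; h <- "c1ccccc1N"
  tp <- tanimoto(fingerprint(q, "path"), fingerprint(h, "path"))
  tc <- tanimoto(fingerprint(q, "circular"), fingerprint(h, "circular"))
  w <- c(path = 0.3, circular = 0.7)
  expect_equal(combined_score(q, h, w)$score, 0.3 * tp + 0.7 * tc)
  expect_equal(combined_score(q, h, c(path = 1, circular = 0))$score, tp)
  expect_equal(combined_score(q, h, w)$score, combined_score(h, q, w)$score)
  expect_error(combined_score(q, h, c(path = 0.5, circular = 0.6)), "sum")
})

test_that("screen_library matches a brute-force double loop and ranks deterministically", {
  set <- gen_compound_set(6, seed = 7, n_extra = 4)
  ds <- set$dataset; lib <- set$library
  hits <- screen_library(ds, lib)
  # independent oracle: explicit double loop over all pairs
  w <- c(path = 0.5, circular = 0.5)
  for (i in seq_len(nrow(ds$compounds))) {
    for (j in seq_len(nrow(lib))) {
      expected <- 0.5 * tanimoto(fingerprint(ds$compounds$smiles[i], "path"),
                                 fingerprint(lib$smiles[j], "path")) +
        0.5 * tanimoto(fingerprint(ds$compounds$smiles[i], "circular"),
                       fingerprint(lib$smiles[j], "circular"))
      got <- hits$score[hits$query_id == ds$compounds$id[i] &
                          hits$cid == lib$cid[j]]
      expect_equal(got, expected)
    }
  }
  # per-query ordering: descending score, ties by ascending cid
  for (q in unique(hits$query_id)) {
    hq <- hits[hits$query_id == q, ]
    expect_true(all(diff(hq$score) <= 0))
    ties <- split(hq$cid, hq$score)
    for (tt in ties) expect_equal(tt, sort(tt))
  }
  # the library contains every query structure, so every top hit is exact
  top <- do.call(rbind, lapply(split(hits, hits$query_id),
                               function(h) h[1, ]))
  expect_true(all(top$score == 1))
})

test_that("floor filters and empty library is handled", {
  set <- gen_compound_set(3, seed = 5, n_extra = 2)
  expect_warning(
    none <- screen_library(set$dataset,
                           data.frame(cid = "1", smiles = "[He]",
                                      stringsAsFactors = FALSE)[0, ],
                           floor = 0),
    "empty library")
  expect_equal(nrow(none), 0L)
  lib <- data.frame(cid = c("8", "9"), smiles = c("CCO", "CCCCN"),
                    stringsAsFactors = FALSE)
  strict <- screen_library(set$dataset, lib, floor = 1)
  expect_true(all(strict$score == 1) || nrow(strict) == 0L)
})

test_that("hit yield is non-increasing in the similarity threshold", {
  set <- gen_compound_set(15, seed = 21, n_extra = 10)
  hits <- screen_library(set$dataset, set$library)
  yield <- vapply(seq(0, 1, by = 0.05), function(t) {
    length(unique(hits$query_id[hits$score > t]))
  }, 1L)
  expect_true(all(diff(yield) <= 0))
})

test_that("hit tables round-trip through CSV", {
  set <- gen_compound_set(3, seed = 2, n_extra = 2)
  hits <- screen_library(set$dataset, set$library, floor = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hits(hits, path)
  expect_equal(read_hits(path), hits)
})
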