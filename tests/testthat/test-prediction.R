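make_hits <- function(scores, cids = as.character(seq_along(scores)),
                      query = "q1") {
  data.frame(query_id = query, cid = cids, score = scores,
             stringsAsFactors = FALSE)
}
make_ann <- function(verdicts, cids = as.character(seq_along(verdicts)),
                     endpoint = "Hepatotoxicity") {
  data.frame(cid = cids, endpoint = endpoint, verdict = as.integer(verdicts),
             stringsAsFactors = FALSE)
}

test_that("predict_endpoint applies the strict-majority rule", {
  ret <- example_retrieves()
  hits <- unique(ret[, c("query_id", "cid", "score")])
  ann <- unique(ret[, c("cid", "endpoint", "verdict")])
  p <- predict_endpoint("beta-sitosterol", "Carcinogenicity", hits, ann,
                        threshold = 0.6171)
  expect_equal(p$verdict, "NONTOXIC")
  expect_equal(p$indicators$cid, "5997")
  expect_equal(p$indicators$score, 0.999)

  expect_equal(predict_endpoint("q1", "Hepatotoxicity",
                                make_hits(c(0.9, 0.8, 0.7)),
                                make_ann(c(1, 1, -1)), 0.5)$verdict, "TOXIC")
  expect_equal(predict_endpoint("q1", "Hepatotoxicity",
                                make_hits(c(0.9, 0.8)),
                                make_ann(c(-1, -1)), 0.5)$verdict, "NONTOXIC")
  expect_equal(predict_endpoint("q1", "Hepatotoxicity",
                                make_hits(c(0.9, 0.8)),
                                make_ann(c(1, 0)), 0.5)$verdict, "AMBIGUOUS")
  # singleton indicator yields its own verdict
  expect_equal(predict_endpoint("q1", "Hepatotoxicity", make_hits(0.9),
                                make_ann(0), 0.5)$verdict, "AMBIGUOUS")
})

test_that("no indicators above threshold gives NA, and '>' is strict", {
  hits <- make_hits(c(0.6171, 0.5))
  ann <- make_ann(c(1, 1))
  p <- predict_endpoint("q1", "Hepatotoxicity", hits, ann, 0.6171)
  expect_true(is.na(p$verdict))   # score == threshold does not count
  expect_equal(nrow(p$indicators), 0L)
})

test_that("prediction is invariant to indicator order", {
  hits <- make_hits(c(0.9, 0.8, 0.7), cids = c("a", "b", "c"))
  ann <- make_ann(c(1, -1, 1), cids = c("a", "b", "c"))
  perm <- sample(3)
  p1 <- predict_endpoint("q1", "Hepatotoxicity", hits, ann, 0.5)
  p2 <- predict_endpoint("q1", "Hepatotoxicity", hits[perm, ], ann[perm, ],
                         0.5)
  expect_equal(p1$verdict, p2$verdict)
  expect_equal(p1$indicators, p2$indicators)
})

test_that("prediction yield is non-increasing in the threshold", {
  set <- gen_compound_set(15, seed = 31, n_extra = 10)
  hits <- screen_library(set$dataset, set$library)
  ann <- gen_annotation_table(set$library$cid, seed = 31)
  yields <- vapply(seq(0, 1, by = 0.1), function(t) {
    prediction_yield(predict_all(hits, ann, threshold = t))
  }, 1L)
  expect_true(all(diff(yields) <= 0))
})

test_that("split_interactions separates statements and keeps provenance", {
  three <- split_interactions("a; b; c", cid = "42", mode = "separator")
  expect_equal(nrow(three), 3L)
  expect_equal(three$text, c("a", "b", "c"))
  expect_equal(unique(three$cid), "42")

  one <- split_interactions("Quercetin increases docetaxel exposure")
  expect_equal(one$text, "Quercetin increases docetaxel exposure")
  expect_equal(nrow(split_interactions("")), 0L)
  expect_equal(nrow(split_interactions(NA_character_)), 0L)

  fx <- gen_interaction_text(seed = 4)
  rows <- split_interactions(fx$payload)
  expect_equal(rows$text, fx$statements)   # hand-split oracle
})

test_that("classification is first-match with full accounting", {
  lex <- interaction_lexicon()
  r1 <- classify_interaction(
    "potentiate the sensitivity of cancer cells to ionizing radiation", lex)
  expect_equal(r1$category, "Enhanced radiotherapy")
  expect_equal(r1$direction, "synergistic")
  r2 <- classify_interaction("weakened target therapy of bortezomib may occur",
                             lex)
  expect_equal(r2$category, "Weakened target therapy")
  expect_equal(r2$direction, "antagonistic")
  r3 <- classify_interaction("the moon is made of cheese", lex)
  expect_false(r3$classified)
  # the genotoxicity rule is a safety alert, not a benefit
  r4 <- classify_interaction("co-exposure with cisplatin enhanced genotoxicity",
                             lex)
  expect_equal(r4$category, "Enhanced genotoxicity")
  expect_true(r4$alert)

  fx <- gen_interaction_text(seed = 8)
  rows <- classify_interactions(split_interactions(fx$payload))
  expect_equal(rows$category[rows$classified],
               fx$categories[!is.na(fx$categories)])
  expect_equal(sum(rows$classified) + sum(!rows$classified), nrow(rows))
  expect_true(all(rows$category[rows$classified] %in%
                    interaction_categories()))
})

test_that("interaction network counts, collapses duplicates, and exports", {
  nine <- data.frame(
    compound = sprintf("c%d", 1:9), partner = "docetaxel",
    category = "Enhanced chemotherapy", direction = "synergistic",
    stringsAsFactors = FALSE
  )
  g <- suppressMessages(build_interaction_network(nine))
  expect_equal(igraph::vcount(g), 10L)
  expect_equal(igraph::ecount(g), 9L)

  empty <- build_interaction_network(nine[0, ])
  expect_equal(igraph::vcount(empty), 0L)

  five <- data.frame(
    compound = c("a", "a", "b", "b", "c"),
    partner = c("x", "x", "y", "z", "x"),
    category = "Metastasis inhibition", direction = "synergistic",
    stringsAsFactors = FALSE
  )
  g5 <- suppressMessages(build_interaction_network(five))
  expect_equal(igraph::ecount(g5), 4L)
  mult <- igraph::edge_attr(g5, "multiplicity")
  expect_equal(sort(mult), c(1, 1, 1, 2))

  expect_error(build_interaction_network(transform(nine, category = "Bogus")),
               "vocabulary")

  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  nodes <- withr::local_tempfile(fileext = ".csv")
  write_network_sif(g5, sif)
  expect_length(readLines(sif), 4L)
  write_network_graphml(g5, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 4L)
  write_node_attributes(g5, nodes)
  natt <- utils::read.csv(nodes)
  expect_setequal(natt$type, c("compound", "partner"))
})
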