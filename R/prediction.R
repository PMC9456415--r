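# Endpoint prediction and interaction-text handling.
#
# Above-threshold similar compounds ("indicators") lend their per-endpoint
# verdicts to the active compound. The aggregation rule is a strict
# majority: toxic only if toxic indicators outnumber all others combined;
# non-toxic only if every indicator is non-toxic; mixed evidence without a
# toxic majority is ambiguous; no indicators at all is NA.

.VERDICT_LABELS <- c(`-1` = "NONTOXIC", `0` = "AMBIGUOUS", `1` = "TOXIC")

#' Predict one toxicity endpoint for one active compound
#'
#' @param query_id Active-compound id.
#' @param endpoint Toxicity section label.
#' @param hits Similarity hits data.frame (`query_id`, `cid`, `score`).
#' @param annotations Annotation data.frame (`cid`, `endpoint`, `verdict`
#'   with verdicts `+1`/`0`/`-1`/`NA`).
#' @param threshold Similarity threshold; indicators must score strictly
#'   above it (default [DEFAULT_SIMILARITY_THRESHOLD]).
#' @return An object of class `endpoint_prediction`: list with `query_id`,
#'   `endpoint`, `verdict` (`"TOXIC"`, `"AMBIGUOUS"`, `"NONTOXIC"`, or
#'   `NA`), `indicators` (data.frame `cid`, `score`, `verdict`), and
#'   `threshold`.
#' @export
predict_endpoint <- function(query_id, endpoint, hits, annotations,
                             threshold = DEFAULT_SIMILARITY_THRESHOLD) {
  stopifnot(threshold >= 0, threshold <= 1)
  h <- hits[hits$query_id == query_id & hits$score > threshold, ,
            drop = FALSE]
  ann <- annotations[annotations$endpoint == endpoint &
                       !is.na(annotations$verdict), , drop = FALSE]
  ind <- merge(h[, c("cid", "score")], ann[, c("cid", "verdict")],
               by = "cid")
  ind <- ind[order(-ind$score, ind$cid), , drop = FALSE]
  rownames(ind) <- NULL
  verdict <- if (nrow(ind) == 0L) {
    NA_character_
  } else {
    n_tox <- sum(ind$verdict == 1L)
    n_non <- sum(ind$verdict == -1L)
    n_amb <- sum(ind$verdict == 0L)
    if (n_tox > n_non + n_amb) "TOXIC"
    else if (n_non == nrow(ind)) "NONTOXIC"
    else "AMBIGUOUS"
  }
  structure(list(query_id = query_id, endpoint = endpoint, verdict = verdict,
                 indicators = ind, threshold = threshold),
            class = "endpoint_prediction")
}

#' @export
print.endpoint_prediction <- function(x, ...) {
  cat("<endpoint_prediction> ", x$query_id, " / ", x$endpoint, ": ",
      if (is.na(x$verdict)) "NA (no indicators)" else x$verdict,
      " [", nrow(x$indicators), " indicator(s) above ", x$threshold, "]\n",
      sep = "")
  invisible(x)
}

#' Predict all endpoints for all queried compounds
#'
#' @inheritParams predict_endpoint
#' @param queries Optional character vector of query ids (default: all ids
#'   present in `hits`).
#' @param endpoints Optional endpoint labels (default: all in
#'   `annotations`).
#' @return data.frame (`query_id`, `endpoint`, `verdict`, `n_indicators`,
#'   `threshold`).
#' @export
predict_all <- function(hits, annotations,
                        threshold = DEFAULT_SIMILARITY_THRESHOLD,
                        queries = NULL, endpoints = NULL) {
  if (is.null(queries)) queries <- sort(unique(hits$query_id))
  if (is.null(endpoints)) endpoints <- sort(unique(annotations$endpoint))
  grid <- expand.grid(query_id = queries, endpoint = endpoints,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    p <- predict_endpoint(grid$query_id[k], grid$endpoint[k], hits,
                          annotations, threshold)
    data.frame(query_id = p$query_id, endpoint = p$endpoint,
               verdict = p$verdict, n_indicators = nrow(p$indicators),
               threshold = threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Number of compounds with at least one non-NA prediction
#'
#' The "prediction yield" of a run: how many active compounds receive at
#' least one definite or ambiguous endpoint verdict at the given threshold.
#'
#' @param predictions data.frame from [predict_all()].
#' @return Integer count.
#' @export
prediction_yield <- function(predictions) {
  length(unique(predictions$query_id[!is.na(predictions$verdict)]))
}

# ---- interaction text handling -------------------------------------------

.SENTENCE_ABBREVS <- c("e.g.", "i.e.", "et al.", "vs.", "ca.", "approx.",
                       "i.p.", "p.o.", "no.", "fig.", "spp.", "wt.")

#' Split a free-text interactions payload into single-interaction rows
#'
#' Each retrieved interactions section may describe several independent
#' interaction statements; downstream classification needs one statement
#' per row. Splitting is on sentence boundaries (default) with a small
#' abbreviation guard, or on an explicit record separator.
#'
#' @param payload A single character string.
#' @param cid Provenance: the library compound the text belongs to.
#' @param mode `"sentence"` or `"separator"`.
#' @param sep Record separator used when `mode = "separator"`.
#' @return data.frame with columns `row` (1-based original order), `text`,
#'   `cid`; zero rows for an empty payload.
#' @export
split_interactions <- function(payload, cid = NA_character_,
                               mode = c("sentence", "separator"),
                               sep = ";") {
  mode <- match.arg(mode)
  empty <- data.frame(row = integer(), text = character(),
                      cid = character(), stringsAsFactors = FALSE)
  if (is.null(payload) || length(payload) != 1L || is.na(payload) ||
      !nzchar(trimws(payload))) {
    return(empty)
  }
  if (mode == "separator") {
    parts <- strsplit(payload, sep, fixed = TRUE)[[1]]
  } else {
    guard <- payload
    # protect abbreviation dots so they do not end a sentence
    for (ab in .SENTENCE_ABBREVS) {
      esc <- gsub(".", "\\.", ab, fixed = TRUE)
      repl <- gsub(".", "\x01", ab, fixed = TRUE)
      guard <- gsub(esc, repl, guard, ignore.case = TRUE)
    }
    parts <- strsplit(guard, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    parts <- gsub("\x01", ".", parts, fixed = TRUE)
  }
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return(empty)
  data.frame(row = seq_along(parts), text = parts,
             cid = as.character(cid), stringsAsFactors = FALSE)
}

#' The seven cancer-management interaction categories
#' @return Character vector of the fixed category vocabulary.
#' @export
interaction_categories <- function() {
  c("Enhanced radiotherapy", "Metastasis inhibition",
    "Carcinogenesis inhibition", "Enhanced chemotherapy",
    "Enhanced genotoxicity", "Enhanced bioavailability",
    "Weakened target therapy")
}

#' Default keyword lexicon for interaction classification
#'
#' Loaded from `inst/extdata/interaction_lexicon.csv` (user-editable);
#' rules fire in file order, first match wins. Each rule is a
#' case-insensitive regular expression mapped to one of the seven
#' categories plus a direction and a safety-alert flag.
#'
#' @param path Optional path to an alternative lexicon CSV (`pattern`,
#'   `category`, `direction`, `alert` columns).
#' @return data.frame lexicon.
#' @export
interaction_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "interaction_lexicon.csv",
                        package = "herbscreen", mustWork = TRUE)
  }
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pattern", "category", "direction", "alert") %in%
                  names(lex)))
  bad <- !(lex$category %in% interaction_categories())
  if (any(bad))
    stop("lexicon categories outside the fixed vocabulary: ",
         paste(unique(lex$category[bad]), collapse = ", "), call. = FALSE)
  lex$alert <- as.logical(lex$alert)
  lex
}

#' Classify a single-interaction text row
#'
#' First-matching-rule assignment against the keyword lexicon. Rows that
#' match no rule are returned as unclassified (never silently dropped) so a
#' human can review them.
#'
#' @param text One interaction statement.
#' @param lexicon A lexicon data.frame (default [interaction_lexicon()]).
#' @return list with `classified` (logical), `category`, `direction`,
#'   `alert`, `pattern` (the rule that fired, NA if none).
#' @export
classify_interaction <- function(text, lexicon = interaction_lexicon()) {
  for (k in seq_len(nrow(lexicon))) {
    if (grepl(lexicon$pattern[k], text, ignore.case = TRUE, perl = TRUE)) {
      return(list(classified = TRUE, category = lexicon$category[k],
                  direction = lexicon$direction[k],
                  alert = isTRUE(lexicon$alert[k]),
                  pattern = lexicon$pattern[k]))
    }
  }
  list(classified = FALSE, category = NA_character_,
       direction = NA_character_, alert = FALSE, pattern = NA_character_)
}

#' Classify many interaction rows
#'
#' @param rows data.frame from [split_interactions()] (needs a `text`
#'   column).
#' @param lexicon See [classify_interaction()].
#' @return `rows` with added columns `classified`, `category`, `direction`,
#'   `alert`.
#' @export
classify_interactions <- function(rows, lexicon = interaction_lexicon()) {
  res <- lapply(rows$text, classify_interaction, lexicon = lexicon)
  rows$classified <- vapply(res, `[[`, TRUE, "classified")
  rows$category <- vapply(res, `[[`, "", "category")
  rows$direction <- vapply(res, `[[`, "", "direction")
  rows$alert <- vapply(res, `[[`, TRUE, "alert")
  rows
}

# ---- interaction network --------------------------------------------------

#' Build a compound-partner interaction network
#'
#' Bipartite-flavored graph: active-compound nodes on one side, interaction
#' partners (drugs, carcinogens, radiation) on the other, edges labeled by
#' category and direction. Duplicate edges (same compound, partner,
#' category, direction) are collapsed with their multiplicity recorded.
#' Node ordering in the graph and all exports is deterministic
#' (compounds sorted, then partners sorted).
#'
#' @param edges data.frame with columns `compound`, `partner`, `category`,
#'   `direction` and optionally `evidence_cid`, `score`.
#' @return An `igraph` graph with vertex attribute `type` (`"compound"` /
#'   `"partner"`) and edge attributes `category`, `direction`,
#'   `multiplicity`.
#' @export
build_interaction_network <- function(edges) {
  req <- c("compound", "partner", "category", "direction")
  stopifnot(is.data.frame(edges), all(req %in% names(edges)))
  if (nrow(edges) > 0) {
    bad <- !(edges$category %in% interaction_categories())
    if (any(bad))
      stop("edge categories outside the fixed vocabulary: ",
           paste(unique(edges$category[bad]), collapse = ", "),
           call. = FALSE)
  }
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  key <- interaction(edges$compound, edges$partner, edges$category,
                     edges$direction, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(edges, key), function(p) {
    data.frame(compound = p$compound[1], partner = p$partner[1],
               category = p$category[1], direction = p$direction[1],
               multiplicity = nrow(p), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$compound, agg$partner, agg$category,
                   agg$direction), , drop = FALSE]
  comp_nodes <- sort(unique(agg$compound))
  part_nodes <- sort(unique(setdiff(agg$partner, agg$compound)))
  vertices <- data.frame(
    name = c(comp_nodes, part_nodes),
    type = c(rep("compound", length(comp_nodes)),
             rep("partner", length(part_nodes))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    agg[, c("compound", "partner", "category", "direction",
            "multiplicity")],
    directed = FALSE, vertices = vertices
  )
  message("interaction network: ", igraph::vcount(g), " nodes, ",
          igraph::ecount(g), " edges")
  g
}

#' Export an interaction network
#'
#' `write_network_sif()` writes Cytoscape simple-interaction-format lines
#' (`compound <category/direction> partner`); `write_network_graphml()`
#' writes GraphML via igraph; `write_node_attributes()` writes the node
#' table as CSV.
#'
#' @param graph An igraph graph from [build_interaction_network()].
#' @param path Output file path.
#' @export
write_network_sif <- function(graph, path) {
  if (igraph::ecount(graph) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  lines <- sprintf("%s\t%s (%s)\t%s", el$from, el$category, el$direction,
                   el$to)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_node_attributes <- function(graph, path) {
  v <- igraph::as_data_frame(graph, what = "vertices")
  utils::write.csv(v, path, row.names = FALSE)
  invisible(path)
}
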