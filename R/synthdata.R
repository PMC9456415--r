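# Seeded generators for every fixture the pipeline consumes: compound sets
# with a reference library, annotation retrieve sequences with planted
# elusive/contrast structure, interaction texts, and two-drug inhibition
# matrices built from Hill curves with a planted delta field. All
# generators are pure functions of their parameters and seed (the caller's
# RNG state is restored on exit).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Chemically valid SMILES built from template cores with enumerated
# substituents ({R} marks the attachment point). Templates cover aromatic
# rings, fused bicyclics, simple chains/acids and a tetracyclic
# sterol-like scaffold, so the similarity layer sees realistic structural
# spread without a generative model.
.SMILES_CORES <- c(
  "c1ccc({R})cc1",                     # monosubstituted benzene
  "c1ccc(-c2ccc({R})cc2)cc1",          # biphenyl
  "c1cc({R})ccc1O",                    # phenol series
  "c1cc2ccccc2cc1{R}",                 # naphthalene
  "C({R})C(=O)O",                      # alpha-substituted acetic acid
  "CC(C)CC({R})C(=O)O",               # branched acid
  "c1ccc(-c2cc(=O)c3c(O)cc({R})cc3o2)cc1",  # flavone scaffold
  "C1CCC2(CCC({R})C2)CC1"             # spiro-fused aliphatic
)
.SMILES_SUBS <- c(
  "O", "N", "C", "CC", "CCC", "CCCC", "OC", "OCC", "C(=O)O", "C(=O)OC",
  "Cl", "Br", "F", "C#N", "C=C", "CO", "CN", "C(C)C", "S", "SC",
  "C(=O)N", "CCO", "CC(=O)O", "N(C)C", "C(F)(F)F"
)
.SMILES_EXTRAS <- c(
  "CC12CCC3C(CCC4CC(O)CCC34C)C1CCC2O",  # sterol-like tetracycle
  "c1ccc2c(c1)oc1ccccc12",              # dibenzofuran
  "OCC1OC(O)C(O)C(O)C1O",               # pyranose
  "CCCCCCCCC(=O)O", "CCCCCCCCCC(=O)O",  # fatty acids
  "c1ccc(C=Cc2ccccc2)cc1"               # stilbene
)

.smiles_pool <- function() {
  core_expanded <- unlist(lapply(.SMILES_CORES, function(core) {
    vapply(.SMILES_SUBS, function(s) sub("{R}", s, core, fixed = TRUE), "")
  }))
  unique(c(core_expanded, .SMILES_EXTRAS))
}

#' Generate a seeded compound dataset plus reference library
#'
#' Draws `n` structures from a packaged template pool (all SMILES valid by
#' construction), assigns each compound to one or two of three synthetic
#' herbs, and draws OB/DL scores such that roughly 70% pass the default
#' ADME screen. The companion library contains every query structure
#' (guaranteeing at least one similarity-1 duplicate pair) plus `n_extra`
#' decoys, under PubChem-style numeric cids.
#'
#' @param n Number of compounds (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_extra Extra decoy library structures (default `min(n, 50)`).
#' @return list with `table` (raw rows: `name`, `smiles`, `ob`, `dl`,
#'   `herb` - ready for [screen_active_compounds()]), `dataset` (the
#'   screened [herb_dataset]), and `library` (data.frame `cid`, `smiles`,
#'   `name`).
#' @export
gen_compound_set <- function(n, seed = 1L, n_extra = min(n, 50L)) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    pool <- .smiles_pool()
    if (n + n_extra > length(pool)) {
      pool <- rep_len(pool, n + n_extra)
    }
    picks <- sample(length(pool), n + n_extra)
    q_smiles <- pool[picks[seq_len(n)]]
    herbs <- c("Herba alpha", "Herba beta", "Herba gamma")
    rows <- lapply(seq_len(n), function(i) {
      nm <- sprintf("compound-%03d", i)
      nh <- sample(1:2, 1, prob = c(0.85, 0.15))
      hs <- sample(herbs, nh)
      data.frame(name = nm, smiles = q_smiles[i],
                 ob = round(stats::runif(1, 0, 1), 3),
                 dl = round(stats::runif(1, 0, 0.6), 3),
                 herb = hs, stringsAsFactors = FALSE)
    })
    table <- do.call(rbind, rows)
    # bias toward the active region so screens retain a usable majority
    lift <- stats::runif(nrow(table)) < 0.7
    table$ob[lift] <- pmax(table$ob[lift], 0.3)
    table$dl[lift] <- pmax(table$dl[lift], 0.18)
    dataset <- suppressMessages(
      screen_active_compounds(table, provenance = sprintf("synthetic seed %d", seed))
    )
    lib_smiles <- c(q_smiles, pool[picks[n + seq_len(n_extra)]])
    library <- data.frame(
      cid = as.character(10000L + seq_along(lib_smiles)),
      smiles = lib_smiles,
      name = sprintf("lib-%04d", seq_along(lib_smiles)),
      stringsAsFactors = FALSE
    )
    list(table = table, dataset = dataset, library = library)
  })
}

#' Specify an annotation scenario
#'
#' Parameterizes a synthetic retrieve sequence: a run of records sharing
#' the anchor verdict, with an elusive and/or a contrast record planted at
#' stated depths (1 = the anchor itself, so depths must be >= 2).
#'
#' @param anchor_verdict `+1`, `0`, or `-1`.
#' @param n_records Number of records (>= 1).
#' @param elusive_depth Position of the planted elusive record, or `NULL`.
#' @param contrast_depth Position of the planted contrast record, or
#'   `NULL`; only meaningful for definite anchors (`+1`/`-1`) - an
#'   ambiguous anchor has no opposite, so this combination is an error.
#' @param score_range Similarity range the descending scores are drawn
#'   from.
#' @param seed Integer seed.
#' @return list of class `annotation_scenario`.
#' @export
annotation_scenario <- function(anchor_verdict, n_records,
                                elusive_depth = NULL, contrast_depth = NULL,
                                score_range = c(0.3, 1), seed = 1L) {
  stopifnot(anchor_verdict %in% c(-1L, 0L, 1L), n_records >= 1)
  if (!is.null(contrast_depth) && anchor_verdict == 0L)
    stop("a contrast record contradicts a definite anchor; anchor 0 has none",
         call. = FALSE)
  for (d in c(elusive_depth, contrast_depth)) {
    if (d < 2 || d > n_records)
      stop("planted depths must lie in [2, n_records]", call. = FALSE)
  }
  if (!is.null(elusive_depth) && !is.null(contrast_depth) &&
      elusive_depth == contrast_depth)
    stop("elusive and contrast depths must differ", call. = FALSE)
  structure(list(anchor_verdict = as.integer(anchor_verdict),
                 n_records = as.integer(n_records),
                 elusive_depth = elusive_depth,
                 contrast_depth = contrast_depth,
                 score_range = score_range, seed = as.integer(seed)),
            class = "annotation_scenario")
}

#' Generate a retrieve sequence from an annotation scenario
#'
#' Scores are strictly decreasing draws from `score_range`; every verdict
#' equals the anchor verdict except the planted records. The planted
#' ground-truth scores are attached so recovery tests can compare
#' [compute_fep_ss()] / [compute_fcp_ss()] against construction.
#'
#' @param scenario An [annotation_scenario()].
#' @return A [retrieve_sequence()] with attributes `truth_fep` and
#'   `truth_fcp` (NA when nothing was planted).
#' @export
gen_annotation_sequence <- function(scenario) {
  stopifnot(inherits(scenario, "annotation_scenario"))
  sc <- scenario
  .with_seed(sc$seed, {
    repeat {
      scores <- sort(stats::runif(sc$n_records, sc$score_range[1],
                                  sc$score_range[2]), decreasing = TRUE)
      if (!anyDuplicated(scores)) break
    }
    verdicts <- rep(sc$anchor_verdict, sc$n_records)
    truth_fep <- NA_real_; truth_fcp <- NA_real_
    if (!is.null(sc$elusive_depth)) {
      verdicts[sc$elusive_depth] <- if (sc$anchor_verdict == 0L)
        sample(c(-1L, 1L), 1) else 0L
      truth_fep <- scores[sc$elusive_depth]
    }
    if (!is.null(sc$contrast_depth)) {
      verdicts[sc$contrast_depth] <- -sc$anchor_verdict
      truth_fcp <- scores[sc$contrast_depth]
    }
    seq <- retrieve_sequence(
      query_id = sprintf("synthetic-%d", sc$seed), endpoint = "Hepatotoxicity",
      score = scores, verdict = verdicts,
      cid = as.character(seq_len(sc$n_records))
    )
    attr(seq, "truth_fep") <- truth_fep
    attr(seq, "truth_fcp") <- truth_fcp
    seq
  })
}

.hill_inhibition <- function(d, top, ic50, hill) {
  top / (1 + (ic50 / d)^hill)
}

#' Generate a two-drug inhibition matrix under a planted ZIP deviation
#'
#' Margins follow the two supplied Hill curves; combination cells are the
#' zero-interaction expectation `y1 + y2 - y1*y2` plus the planted delta
#' field plus Gaussian noise, clipped to `[0, 1]`. The planted truth is
#' attached for plant-and-recover tests.
#'
#' @param hill1,hill2 Monotherapy parameters for drug 1 / drug 2: lists
#'   with `top` (max inhibition fraction), `ic50`, `hill` (slope).
#' @param row_doses,col_doses Positive dose grids (a leading 0 margin is
#'   added automatically). Defaults: 5 doses log-spaced around each IC50.
#' @param delta_field Planted per-cell delta (fractions, not percentage
#'   points): scalar or `length(row_doses) x length(col_doses)` matrix.
#' @param sigma Gaussian noise SD on every cell (fractions).
#' @param seed Integer seed.
#' @return A [dose_response_matrix()] with attribute `truth_delta`
#'   (fraction matrix over the combination block).
#' @export
gen_zip_matrix <- function(hill1 = list(top = 1, ic50 = 1, hill = 1),
                           hill2 = list(top = 1, ic50 = 1, hill = 1),
                           row_doses = NULL, col_doses = NULL,
                           delta_field = 0, sigma = 0, seed = 1L) {
  stopifnot(sigma >= 0)
  if (is.null(row_doses))
    row_doses <- hill1$ic50 * 10^seq(-2, 2, length.out = 5)
  if (is.null(col_doses))
    col_doses <- hill2$ic50 * 10^seq(-2, 2, length.out = 5)
  stopifnot(all(row_doses > 0), all(col_doses > 0))
  nr <- length(row_doses); nc <- length(col_doses)
  if (is.matrix(delta_field)) {
    stopifnot(nrow(delta_field) == nr, ncol(delta_field) == nc)
  } else {
    delta_field <- matrix(delta_field, nr, nc)
  }
  .with_seed(seed, {
    y1 <- .hill_inhibition(row_doses, hill1$top, hill1$ic50, hill1$hill)
    y2 <- .hill_inhibition(col_doses, hill2$top, hill2$ic50, hill2$hill)
    null <- outer(y1, y2, function(a, b) a + b - a * b)
    full <- matrix(0, nr + 1L, nc + 1L)
    full[-1, 1] <- y1
    full[1, -1] <- y2
    full[-1, -1] <- null + delta_field
    noise <- matrix(stats::rnorm((nr + 1L) * (nc + 1L), 0, sigma),
                    nr + 1L, nc + 1L)
    if (sigma == 0) noise[] <- 0
    full <- pmin(pmax(full + noise, 0), 1)
    full[1, 1] <- 0
    mat <- dose_response_matrix(c(0, row_doses), c(0, col_doses), full)
    attr(mat, "truth_delta") <- delta_field
    mat
  })
}

#' Generate an interaction-text fixture
#'
#' Seven-statement payloads exercising the keyword classifier (one per
#' category, with embedded abbreviations to stress sentence splitting) plus
#' an always-unclassifiable statement.
#'
#' @param seed Integer seed (shuffles statement order).
#' @return list with `payload` (single string), `statements` (the
#'   hand-split truth), `categories` (expected category per statement, NA
#'   for the unclassifiable one).
#' @export
gen_interaction_text <- function(seed = 1L) {
  stmts <- c(
    "This flavonoid may potentiate the sensitivity of cancer cells to ionizing radiation.",
    "Co-treatment inhibited lung metastasis in tumor-bearing mice (ca. 40% fewer nodules).",
    "Pretreatment suppressed azoxymethane-induced carcinogenesis in the colon.",
    "The compound showed synergistic cytotoxicity with docetaxel in chemotherapy models.",
    "Combined exposure with cisplatin enhanced genotoxicity, e.g. increased micronucleus frequency.",
    "Oral dosing raised the bioavailability of co-administered drugs via P-gp inhibition.",
    "Weakened target therapy of bortezomib may occur under combined treatment.",
    "The sample was stored at 4 degrees until analysis."
  )
  cats <- c("Enhanced radiotherapy", "Metastasis inhibition",
            "Carcinogenesis inhibition", "Enhanced chemotherapy",
            "Enhanced genotoxicity", "Enhanced bioavailability",
            "Weakened target therapy", NA)
  .with_seed(seed, {
    ord <- sample(length(stmts))
    list(payload = paste(stmts[ord], collapse = " "),
         statements = stmts[ord], categories = cats[ord])
  })
}

#' Generate a random per-endpoint annotation table for a library
#'
#' Utility plumbing for end-to-end runs: each (cid, endpoint) pair receives
#' a verdict drawn from (+1, 0, -1, NA) with the given probabilities.
#'
#' @param cids Library compound ids.
#' @param endpoints Endpoint labels.
#' @param seed Integer seed.
#' @param probs Probabilities of (+1, 0, -1, NA).
#' @return data.frame (`cid`, `endpoint`, `verdict`).
#' @export
gen_annotation_table <- function(cids, endpoints = c("Hepatotoxicity",
                                                     "Carcinogenicity"),
                                 seed = 1L,
                                 probs = c(0.25, 0.15, 0.3, 0.3)) {
  .with_seed(seed, {
    grid <- expand.grid(cid = as.character(cids), endpoint = endpoints,
                        stringsAsFactors = FALSE)
    grid$verdict <- sample(c(1L, 0L, -1L, NA_integer_), nrow(grid),
                           replace = TRUE, prob = probs)
    grid
  })
}

#' Write the full demo fixture set to a directory
#'
#' Materializes one seeded run of every generator: the compound table and
#' screened dataset, the library, a hit table, an annotation table, and a
#' ZIP-null dose-response matrix.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n Number of compounds.
#' @return Invisibly, the directory.
#' @export
make_fixtures <- function(dir, seed = 1L, n = 30L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set <- gen_compound_set(n, seed = seed)
  utils::write.csv(set$table, file.path(dir, "compound_table.csv"),
                   row.names = FALSE)
  write_herb_dataset(set$dataset, file.path(dir, "active_compounds.csv"))
  utils::write.csv(set$library, file.path(dir, "library.csv"),
                   row.names = FALSE)
  hits <- screen_library(set$dataset, set$library, floor = 0.1)
  write_hits(hits, file.path(dir, "hits.csv"))
  ann <- gen_annotation_table(set$library$cid, seed = seed)
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  mat <- gen_zip_matrix(sigma = 0.03, seed = seed)
  write_dose_matrix(mat, file.path(dir, "zip_matrix.csv"))
  invisible(dir)
}
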