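# herbscreen

Similarity-based toxicity and drug-interaction screening for herbal
compound mixtures.

## The problem

A herbal medicine is a mixture of dozens to hundreds of natural products.
Most of them have no measured toxicity and no curated drug-interaction
record, so neither QSAR models trained on approved drugs nor pairwise
drug–drug interaction predictors cover them well. A practical alternative
is *evidence borrowing by chemical similarity*: screen every active
constituent against a library of annotated bioactive compounds, and let
sufficiently similar library compounds ("indicators") lend their toxicity
and interaction annotations to the constituent.

The crux is *sufficiently similar*. `herbscreen` implements the full
workflow offline and, at its core, a calibration statistic pair that turns
ranked annotation retrieves into a defensible similarity threshold:

- **FEP-SS** (first elusive prediction-similarity score): reading the
  retrieves of one compound–endpoint pair from the highest similarity
  score downward, the score at which a record first becomes *equivocal*
  relative to the top ("anchor") verdict.
- **FCP-SS** (first contrast prediction-similarity score): the score at
  which a record first *contradicts* a definite anchor verdict.

With per-pair verdicts coded +1 (toxic), 0 (ambiguous), −1
(non-toxic/anti-toxic) and NA (no evidence), and records sorted by
descending similarity *s*:

```
anchor  v0  = verdict of the highest-scoring non-NA record
FEP-SS      = max { s_i : s_i < s_anchor,  v_i elusive w.r.t. v0 }
FCP-SS      = max { s_i : s_i < s_anchor,  v_i = −v0 },  v0 ∈ {+1, −1}
threshold   = mean of FCP-SS values > 0.3 across all pairs
```

Predictions then use only indicators with similarity strictly above the
threshold (packaged default 0.6171, from a 20-herb calibration study), with
a strict-majority rule: toxic if toxic indicators outnumber all others,
non-toxic only if all indicators agree, ambiguous otherwise, NA with no
indicators.

Around that core the package provides: the ADME active-compound screen
(oral bioavailability ≥ 0.3 and drug-likeness ≥ 0.18), path and circular
fingerprint Tanimoto screening, interaction-text splitting and keyword
classification into seven cancer-management categories, Cytoscape
SIF/GraphML network export, and dose–response synergy analysis — 4PL curve
fits, the Combination Index `CI = D1/Dx1 + D2/Dx2`, and ZIP delta scores
(`y_zip = y1 + y2 − y1·y2`) with 3×3 most-synergistic-area detection.
Seeded generators produce every fixture, so everything runs with no
database access.

## Worked example

The package ships a small annotation-retrieve table for three
phytosterol-like compounds (`example_retrieves()`):

```r
library(herbscreen)
ps <- pair_scores(example_retrieves())
subset(ps, endpoint == "Hepatotoxicity")
#>                       query_id       endpoint fep_ss fcp_ss
#> 2 3-Hydroxystigmast-5-en-7-one Hepatotoxicity  0.498     NA
#> 4              beta-sitosterol Hepatotoxicity     NA  0.588
#> 6                  campesterol Hepatotoxicity     NA  0.594
```

3-Hydroxystigmast-5-en-7-one has an ambiguous anchor, so only an elusive
point exists: consistency ends at similarity 0.498. The two sterols have
definite (non-toxic) anchors that are directly contradicted by a toxic
record at 0.588 / 0.594 — below those scores the borrowed evidence
conflicts. Feeding the per-pair table to `calibrate_threshold(ps)` averages
the surviving FCP-SS values into the prediction threshold.

Synergy of a drug pair, e.g. a plant extract with docetaxel, from the
measured IC50s (70.48 µg/mL and 1.85 nM alone; 4.73 µg/mL and 1.18 nM in
combination):

```r
combination_index(70.48, 1.85, 4.73, 1.18)
#> Combination Index = 0.705 (synergistic)
```

And a plant-and-recover ZIP run on a generated 6×6 inhibition matrix with
a planted +10-point deviation:

```r
mat <- gen_zip_matrix(list(top = 0.6, ic50 = 20, hill = 1),
                      list(top = 0.6, ic50 = 20, hill = 1),
                      delta_field = 0.1, sigma = 0.02, seed = 7)
zip_delta(mat)
#> <synergy_result> 5x5 combination block
#>   mean ZIP delta: 10.84 percentage points
#>   most synergistic area: 11.57 (3x3 window at [3,1])
```

The mean delta recovers the planted +10 points (up to noise); deltas are
in percentage points of inhibition, positive = more inhibition than the
zero-interaction expectation.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/herbscreen", package = "herbscreen"))')
Rscript "$CLI" make-fixtures --out demo --seed 1
Rscript "$CLI" screen --in demo/compound_table.csv --out demo/active.csv
Rscript "$CLI" calibrate --retrieves <retrieves.csv> --cutoff 0.3 --out demo/cal
Rscript "$CLI" synergy-ci --dx1 70.48 --dx2 1.85 --d1 4.73 --d2 1.18
```

## Scope notes

The packaged similarity score is a weighted convex combination of two open
fingerprint Tanimoto scores — a reproducible stand-in for proprietary
web-platform "combined" scores, not a numerical replica of them. The
shipped 0.6171 default threshold is a documented constant; recalibrate with
`calibrate_threshold()` on your own retrieve table. See the methods
vignette (`vignettes/herbscreen-methods.Rmd`) for models, assumptions, and
limitations.
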