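---
title: "Methods: similarity-borrowed toxicity evidence and synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-borrowed toxicity evidence and synergy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbscreen)
```

## The model in one paragraph

`herbscreen` predicts toxicity and drug-interaction liabilities of herbal
constituents by *evidence borrowing*: a constituent inherits the
annotations of reference-library compounds that are chemically similar to
it. Because borrowed evidence degrades as similarity falls, the package's
central statistical object is the point at which ranked annotation
retrieves stop agreeing with their own top record — formalized as the
FEP-SS and FCP-SS statistics — and the prediction threshold is set from
the distribution of those points. Everything downstream (verdict
aggregation, interaction networks) conditions on similarity being strictly
above that threshold. Synergy of the resulting extract–drug hypotheses is
quantified independently from dose–response data.

## Active-compound screen

TCMSP-style tables give per-compound oral bioavailability (OB) and
drug-likeness (DL) scores, both unitless and non-negative. The screen
keeps rows with OB ≥ 0.3 **and** DL ≥ 0.18 — boundaries inclusive, which
matters for compounds sitting exactly at a cutoff. Rows with unparseable
SMILES or missing scores are dropped with a warning rather than aborting:
the pipeline is batch-oriented over hundreds of rows, and one malformed
entry must not kill a run. Duplicate names (case-insensitive,
whitespace-normalized — database capitalization varies) are merged with
herb sets unioned; a name mapping to two different structures keeps the
first and logs the conflict, since the original resolution policy for such
collisions is unknowable from the data alone.

## Similarity scores

Two descriptor schemes are computed from a built-in SMILES reader:

* **path** — all linear atom/bond paths of 1–7 atoms, hashed into 2048
  bits (the FP2 family);
* **circular** — iterative Morgan environments to radius 2, i.e. the
  ECFP4 family.

Both operate on the parsed molecular graph with order-independent codes,
so every spelling of a molecule yields the same bit set; Kekulé-form
six-membered C/N rings with alternating bonds are promoted to aromatic so
`C1=CC=CC=C1` and `c1ccccc1` agree. The reported score is a convex
combination of per-scheme Tanimoto coefficients (default equal weights).
This is a deliberate, declared approximation: proprietary "combined"
web-platform similarity models are not published, so the package preserves
the workflow's contract — one deterministic score in [0, 1], equal to 1
for identical structures — while staying reproducible offline. Printed
scores from external platforms are treated as *inputs* downstream, never
regenerated. Two empty bit sets have no defined Tanimoto value and raise
an error rather than returning a conventional 1 or 0.

The SMILES reader covers the organic subset, bracket atoms, ring closures,
and branches; it does not perceive aromaticity in five-membered
heteroaromatic Kekulé forms (the packaged templates write those rings in
lowercase aromatic form). This is a documented boundary, not a silent
failure: unsupported input raises a parse error.

## FEP-SS and FCP-SS

For one (compound, endpoint) pair, retrieves are (similarity, verdict)
records, verdicts in {+1 toxic, 0 ambiguous, −1 non-toxic, NA}. After
dropping exact duplicate records (annotation mining returns verbatim
duplicates) and sorting by descending score:

* the **anchor** is the highest-scoring non-NA record; at a tied top
  score with conflicting verdicts the most cautionary verdict wins
  (+1 > 0 > −1) — an alerting system should not average away a toxic
  signal;
* **FEP-SS** is the maximum score, strictly below the anchor score, of a
  record whose verdict is *elusive* relative to the anchor: ambiguous when
  the anchor is definite, definite (either sign) when the anchor is
  ambiguous;
* **FCP-SS** is the maximum score, strictly below the anchor score, of a
  record with the verdict *opposite* to a definite anchor; it is undefined
  for an ambiguous anchor.

"First as the score decreases" is implemented as the maximum qualifying
score — identical to the first hit of a descending scan, but
order-stable. The two scans are **independent**: a contrast record does
not terminate the elusive scan or vice versa. This is forced by the data
this design was validated against, where a compound can show
FEP-SS < FCP-SS; a nested "stop at the first difference of any kind"
reading cannot produce that ordering. Both statistics are, by
construction, members of the input score list and strictly below the
anchor score; NA-verdict records are skipped everywhere.

When the anchor is ambiguous, a later +1 and a later −1 are both treated
as elusive — the definitions speak of disagreement with the anchor, and
with an ambiguous anchor any definite verdict is a change of epistemic
state, not a contradiction.

## Threshold calibration

Per-pair FEP-SS/FCP-SS values ≤ 0.3 are excluded from the *summary only*
(they typically reflect sparse annotation, not a real contrast; the
per-pair table always reports them). The cutoff comparison is `≤`, i.e. a
value exactly 0.3 is excluded. The calibrated threshold is the **mean of
surviving FCP-SS values**: ambiguity in borrowed evidence is tolerable for
hypothesis generation, outright contradiction is not, so the contrast
statistic — the stricter of the two — anchors the threshold. The third
quartile is computed with linear interpolation between order statistics
(`quantile` type 7), pinned so that the summary is reproducible across
implementations. The package ships 0.6171 as the default threshold — the
mean FCP-SS of a 20-herb calibration study whose full per-pair data is
not packaged; it is a documented constant, not a recomputed value, and
`calibrate_threshold()` recalibrates from any user-supplied retrieve
table.

## Prediction aggregation

Indicators are hits with similarity **strictly above** the threshold
("above" is read as strict; a compound exactly at the threshold provides
no evidence) joined to non-NA endpoint verdicts. The verdict is:

* **TOXIC** if toxic indicators form a strict majority of *all* non-NA
  indicators (`n(+1) > n(0) + n(−1)`) — the weakest reading of "major
  indicators" under which a toxic call is strictly stronger than an
  ambiguous one; ambiguous indicators count in the denominator because
  they are evidence of non-consensus;
* **NONTOXIC** only under unanimity of −1;
* **AMBIGUOUS** for any other non-empty indicator multiset;
* **NA** with no indicators.

Aggregation is a multiset operation — indicator order never matters — and
prediction yield is non-increasing in the threshold, the property that
makes threshold sweeps interpretable.

## Interaction texts and the network

The expert reading of free-text interaction records is replaced by a
transparent keyword lexicon (`inst/extdata/interaction_lexicon.csv`,
user-editable): case-insensitive regular expressions mapped to seven
cancer-management categories, first matching rule wins, and rows matching
no rule are surfaced as unclassified — never dropped — for manual review.
Reproducibility is preferred over cleverness here; no hidden NLP. The
direction vocabulary is synergistic/antagonistic; *enhanced genotoxicity*
maps to synergistic but carries a safety-alert flag, because increased DNA
damage in combination is a risk, not a benefit. The compound–partner graph
is bipartite with duplicate edges collapsed (multiplicity recorded) and
deterministic node ordering; exports are Cytoscape-loadable SIF and
GraphML.

## Synergy layer

**4PL fits.** `response = bottom + (top − bottom) / (1 + 10^((logIC50 −
log10 d)·hill))`, least squares via `nls` (port) with a deterministic
initialization — asymptotes from the data extremes, logIC50 from the dose
bracketing the half-range, hill ±1 by orientation — and a Nelder-Mead
fallback. Flat data and non-convergence are explicit errors; an IC50
outside the tested dose range is flagged. Viability input uses a negative
Hill slope; the matrix pipeline works on inhibition = 1 − viability,
converted once at ingest.

**Combination Index.** `CI = D1/Dx1 + D2/Dx2`; < 1 synergistic, = 1
additive, > 1 antagonistic. Unit labels are checked within each drug, and
the index is invariant to rescaling either drug's dose axis.

**ZIP deltas.** Each monotherapy margin is fitted with a three-parameter
logistic (bottom fixed at 0 — zero dose inhibits nothing — top in (0, 1],
positive slope); margins shorter than four doses use direct least squares
because `nls` is unreliable below that. The zero-interaction expectation on
each combination cell is `y_zip = y1 + y2 − y1·y2`, and the reported delta
is `observed − y_zip` in percentage points, with the observed cells used
as measured (no smoothing — the testable default; web platforms
post-process in undocumented ways, which is why externally printed ZIP
summary scores are declared out of reproduction scope). The most
synergistic area is the maximum mean delta over contiguous 3×3 windows of
the combination block (the conventional window size, pinned so MSA is
well-defined); smaller blocks fall back to the largest window with a
warning.

## Synthetic data: what it emulates and what it does not

Generators are pure functions of parameters and seed.

* `gen_compound_set()` draws valid structures from a template pool (cores
  × substituents — guaranteed chemical validity without a generative
  model), assigns 1–2 of three herbs per compound, and draws OB/DL so
  roughly 70% pass the screen — enough survivors to exercise every
  downstream stage while keeping the screen non-trivial. The library
  contains every query structure, so exact-match (score 1) paths are
  always covered.
* `gen_annotation_sequence()` plants elusive/contrast records at known
  depths under strictly decreasing scores and returns the planted scores
  as ground truth; recovery tests ask the calibration statistics to return
  exactly those values.
* `gen_zip_matrix()` builds margins from Hill curves and combination cells
  from the ZIP null plus a planted delta field plus Gaussian noise,
  clipped to [0, 1]. Defaults: 5 doses per drug log-spaced two decades
  around the IC50 (a 6×6 plate with margins), σ = 0.03 for
  calibration runs — typical replicate noise for plate-based viability
  assays.

Green tests therefore establish *internal* correctness — the statistics
recover what was planted, the null is scored near zero, thresholds behave
monotonically — not agreement with any external platform's numbers. Real
annotation text is messier than the keyword fixtures; real dose-response
matrices have correlated (plate-position) noise that the independent
Gaussian model does not emulate. A physical constraint worth noting for
plant-and-recover designs: inhibition saturates at 100%, so a planted
positive delta near the high-dose corner is clipped away; recovery tests
plant where the null leaves headroom (low-dose corner), which is also
where real synergies are pharmacologically most interesting.

## Numerical choices and edge cases

* Tanimoto of two empty bit sets: error, not 1.
* Ranking ties in hit lists broken by ascending library id — regression
  tests need byte-stable output.
* Quartiles: type 7 (linear interpolation), fixed.
* Exclusion cutoff: `≤ 0.3`, summary-only.
* Threshold comparison for indicators: strictly `>`.
* Verdict coercion accepts the Unicode minus sign and `"N.A."` spellings
  found in curated tables.
* 4PL parameter box: bottom ∈ [−0.5, 1], top ∈ [0, 1.5], hill magnitude
  ≤ 50; wide enough for fractional response data, tight enough to stop
  the port algorithm wandering.

## Known limitations

* The similarity scheme is an open approximation; absolute score values
  are not comparable to proprietary platforms, only the workflow contract
  is preserved.
* The SMILES reader is scoped to the package's needs (no stereochemistry
  in fingerprints, no five-membered-ring Kekulé aromatization).
* The shipped 0.6171 threshold is inherited, not recomputed; treat it as
  a default, and recalibrate when your reference library changes.
* Keyword classification is transparent but shallow; unclassified rows
  are expected and must be reviewed by a human.
* All predictions are screening hypotheses. Nothing here replaces
  experimental confirmation.
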