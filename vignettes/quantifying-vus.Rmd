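---
title: "Quantifying variant classifications and AlphaMissense evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying variant classifications and AlphaMissense evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vusquant)
```

## The problem

Clinical laboratories classify germline variants into five tiers — benign,
likely benign, variant of uncertain significance (VUS), likely pathogenic,
pathogenic — by combining named ACMG/AMP evidence criteria. Each criterion has
a polarity (benign or pathogenic), a strength (stand-alone, strong, moderate,
supporting, very strong), and a type (population, functional/allelic,
clinical, computational, molecular impact). The VUS tier dominates curated
cohorts of missense variants, and the question this package addresses is
operational: if a modern in-silico predictor (AlphaMissense) is admitted as
the supporting-strength computational criterion (PP3 for damaging
predictions, BP4 for benign ones), how much do VUS quantifications and
classifications move?

`vusquant` implements the full analysis as reusable, tested functions:
evidence parsing, points-based quantification, AlphaMissense categorization,
the two evidence-integration experiments, and concordance statistics, plus
deterministic fixtures and a seeded cohort simulator so that every stage runs
from code alone.

## The point system

Evidence items are scored with an integer point adaptation of the Bayesian
classification framework. Each item contributes the point value of its
*applied* strength class:

| class | meaning | points |
|-------|------------------------------|--------|
| PVS   | pathogenic very strong       | +8 |
| PS    | pathogenic strong            | +4 |
| PM    | pathogenic moderate          | +2 |
| PP    | pathogenic supporting        | +1 |
| BP    | benign supporting            | −1 |
| BS    | benign strong                | −4 |
| BA    | benign stand-alone           | −4 |

Absent or indeterminate evidence contributes 0. A variant's quantification is
the sum over its items, and the total maps to a tier:

* ≤ −4 — benign
* −3 … −1 — likely benign
* 0 … 5 — VUS, subdivided into Low (0–1), Mid (2–3) and High (4–5) bands
* 6 … 9 — likely pathogenic
* ≥ 10 — pathogenic

Two design points deserve a note. First, published descriptions of these
bins are not perfectly consistent about the −4 boundary (one figure legend
describes likely benign as reaching down to −4); the table rule — −4 is
benign, likely benign starts at −3 — is implemented, and
`classify_points(-4)` returns `"benign"`. Second, BA scores −4 here, the
rule used by the source analysis, although other published calibrations give
stand-alone benign evidence −8; the point map is an explicit argument
(`acmg_points()`) so an alternative calibration can be passed through every
quantification function, while the default stays at −4.

Bins are open-ended: totals below −8 or above 10 are classified by the ≤/≥
rules without clamping.

## The evidence catalog and parsing

The catalog (`acmg_catalog()`, shipped as a plain-text TSV that laboratories
can extend) maps each code root to polarity, base strength and evidence type,
mirroring the groupings used in the curated cohort: population codes BA1,
BS1, BS2, PS4, PM2; functional/allelic BS3, BP2, PS3, PM3; clinical BS4,
BP5, PP1, PP4, PS2, PM6 and the non-standard `PPC` family; computational BP4
and PP3; molecular-impact BP7, BP3, BP1, PVS1, PS1, PM4, PM1, PM5, PP2. The
`PPC`, `PPC HET`, `PPC HOM`, `PPC COMHET` tokens are treated as pathogenic
clinical evidence at supporting strength, following the published grouping
of these codes with the PP clinical criteria. These assignments mirror the
source cohort's table rather than re-deriving type categories from the
original ACMG guideline text — the two differ in places (e.g. segregation
and de-novo codes), and the cohort's own grouping is the one its numbers
were produced under.

Strength modifiers are suffixes on the root: `_VS`, `_S`, `_M`, `_P` set the
applied strength, so `PS4_M` counts as PM (+2) while keeping its population
type. Only `_M` occurs in the curated cohort, but the full suffix set is
supported for generality. Duplicate codes each count — multiplicity is real
data, not an error — and `strength_profile()` tallies items under their
applied strength. Parsing is case-insensitive and round-trips through
`format_evidence()`.

## AlphaMissense categorization and evidence conversion

AlphaMissense scores in [0, 1] categorize by fixed thresholds: below 0.34
benign, 0.34–0.564 ambiguous, above 0.564 pathogenic. The published range
notation leaves gaps (0.33–0.34, 0.564–0.565); the implemented rule uses
`< 0.34` and `≤ 0.564` cut points, matching the predictor's release
convention, so gap scores resolve to benign and ambiguous respectively.
`am_evidence_code()` converts categories to evidence: pathogenic → PP3 (+1),
benign → BP4 (−1), ambiguous → nothing (0 points). When a record carries
both a score and a precomputed category that disagree, the score-derived
category wins and a warning is raised.

## The two integration experiments

**Augmentation** (`run_augmentation()`): only variants that are curated VUS
*and* carry no computational-type evidence are touched; each receives the
single AlphaMissense-derived item (nothing if ambiguous). Since at most one
supporting item is added, per-variant point deltas are confined to
{−1, 0, +1}.

**Replacement** (`run_replacement()`): for in-scope variants (curated VUS,
or the whole cohort with `scope = "all"`), all computational-type items of
both polarities and multiplicities are removed and the single
AlphaMissense-derived item appended. Variants without computational evidence
simply gain the item, so the operation covers both replacement and addition.
Because the added PP3/BP4 is itself computational, the operation is
idempotent — a property the test suite checks on simulated cohorts.

Both experiments re-quantify the entire cohort and return per-variant
before/after points, tiers and VUS bands, counts of points- and tier-changes,
and a 5×5 transition matrix over quantified tiers. "Quantification changed"
counts any points delta, including sub-band moves within VUS; tier changes
are reported separately. The curated tier and the quantified tier are kept
side by side and never merged: a curated VUS quantifying to −1 remains
curated VUS, and the package does not attempt to reconcile the two labels.

## Concordance statistics

`contingency_3x3()` tallies AlphaMissense categories (rows: pathogenic,
ambiguous, benign) against collapsed curated tiers (columns: P/LP, VUS,
B/LB). Two binary collapse schemes are computed:

* `metrics_excluding_uncertain()` — pathogenic vs benign with the ambiguous
  row and VUS column excluded entirely: TP = (path, path), FP = (path,
  benign), FN = (benign, path), TN = (benign, benign).
* `metrics_path_vs_rest()` — curated P/LP vs everything else, against AM
  pathogenic vs non-pathogenic: FN collects curated-pathogenic variants
  called ambiguous *or* benign, FP collects AM-pathogenic calls on curated
  VUS *or* B/LB, TN is the remaining 2×2 block. The published verbal
  definition of this scheme mentions only the ambiguous row for FN/FP, but
  that reading does not reproduce the published percentages; the cell
  assignment implemented here does, and is documented as the operative
  definition.

Metrics are kept as fractions and rendered as whole percents with
round-half-away-from-zero. Zero-denominator metrics are reported as `NA`,
never 0 or 100. Chi-square (Pearson, no continuity correction), Spearman
rank correlation (average ranks for ties) and t-based mean confidence
intervals are delegated to base R's `chisq.test`, `cor` and `t.test` behind
small validating wrappers.

## Fixtures: expanding the published tables

The per-variant cohort behind the source analysis is not publicly released;
what is printed are summary tables. The fixtures module expands those tables
deterministically into cohorts that reproduce every printed count:

* `fixture_from_contingency()` / `fixture_table2a()` — emits exactly the
  3×3 cell counts as records; P/LP and B/LB cells alternate deterministically
  between their two constituent tiers, and scores are drawn (seeded)
  uniformly inside the row category's interval so the category round-trips.
* `fixture_vus_table5()` — the 20 pre-augmentation VUS combination groups
  (4085 variants). Within each group, exactly the printed numbers of members
  receive benign (score 0.20) or pathogenic (0.90) predictions. Which
  concrete codes realize a strength count is underdetermined; canonical
  non-computational codes are used (PS4, PM2, PP1, BP1, BS1), and the
  non-added remainder of a group is realized with one PP3/BP4 item when the
  profile contains a supporting item — marking existing computational
  evidence, hence ineligibility — or, for profiles with no supporting item,
  kept eligible but AlphaMissense-ambiguous (score 0.45, inert). The
  published narrative's eligible-variant total cannot be reconciled exactly
  with the printed per-group addition counts (the printed benign additions
  sum to 239, the narrative says 308); the fixture follows the printed rows.
* `fixture_vus_table6()` — the 26 post-replacement profile groups
  (4085 variants), used to verify quantification of replacement outcomes.

Fixtures reproduce counts, not variant identities.

## The cohort simulator

`simulate_cohort()` draws seeded cohorts from a `cohort_spec()`. The default
specification encodes the study conditions: 5845 variants; collapsed-tier
proportions 1576 P/LP : 184 B/LB : 4085 VUS, split evenly within each
collapsed pair (the published data do not give the five-way split);
AlphaMissense scores from Beta mixtures with means 0.30 (benign) and 0.85
(pathogenic) and a bimodal VUS mixture of components at 0.20 and 0.80
weighted 4/15 and 11/15 so the VUS mean is exactly 0.64. Component
concentrations (kappa 8–12) are configuration chosen to give realistic
spreads, not empirical claims. VUS evidence combinations reuse the 20
published templates at their published frequencies, with a per-template
probability of carrying computational evidence taken from the fixture
realization; non-VUS tiers use invented point-consistent templates (each
quantifies into its tier's bin) because per-variant evidence for those tiers
is not published. A REVEL-like companion score is drawn with its mean
tracking the AlphaMissense score, giving a strong positive rank correlation
for exercising `spearman_rho()`.

What the simulator does *not* emulate: genomic coordinates and transcripts,
gnomAD frequencies, per-gene evidence structure, and any dependence between
evidence combinations and AlphaMissense scores within a tier. Passing tests
on simulated cohorts therefore demonstrate correctness of the pipeline's
accounting, not predictive performance on real data.

## Numerical and degenerate-input choices

* Tier bins and VUS bands operate on integer totals; inputs are validated
  rather than rounded.
* Empty evidence fields are legal and quantify to 0 (VUS, Low band).
* Contingency tables from empty cohorts are all-zero; the chi-square test
  refuses zero marginals rather than returning NaN.
* Constant vectors give `NA` rank correlation (with a warning) and a
  degenerate confidence interval at the mean.
* Typographic minus signs (U+2212), as printed in the source tables, are
  normalized to ASCII on cohort read.
* Problem sizes in the test suite are the natural fixture sizes (4085 and
  5845 records) plus simulated cohorts of 300–1000 records for
  property-style checks; the full suite runs in seconds.

## Known limitations

* The catalog ships the codes attested in the curated cohort; other ACMG
  codes (e.g. BP6, PP5) must be added via a custom catalog file.
* Replacement inserts at most one AlphaMissense item per variant; schemes
  that weight predictor evidence above supporting strength are expressible
  only by editing the points map, not per-item.
* Per-gene stratification is supported through the `gene` field but has no
  reference values to test against, since the per-variant cohort is
  unreleased.
* The package quantifies evidence already assigned; it does not decide which
  criteria apply to a variant, nor does it implement the full ACMG
  combining rules or the continuous Bayesian posterior.

## A worked example

```{r example}
cohort <- fixture_vus_table5()
aug <- run_augmentation(cohort)
aug

# concordance on the full-cohort fixture
concordance_summary(fixture_table2a())
```
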