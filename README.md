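# vusquant

Points-based quantification of ACMG/AMP germline variant classifications,
with AlphaMissense predictions injected as computational evidence.

## What it is for

Clinical variant curation assigns named ACMG/AMP evidence criteria (PM2,
PP3, BS1, ...) and combines them into a five-tier call; the variant of
uncertain significance (VUS) tier dominates curated missense cohorts.
`vusquant` is for analysts who want to measure, reproducibly, what a
pathogenicity predictor does to such a cohort when it is admitted as the
supporting-strength computational criterion. It provides:

* an extensible **evidence catalog and parser** (polarity, strength,
  `_M`-style strength modifiers, evidence type, `PPC HET`-style qualifiers);
* the **integer point adaptation** of the Bayesian classification framework:
  BA/BS −4, BP −1, PP +1, PM +2, PS +4, PVS +8, with tier bins
  ≤−4 benign, −3…−1 likely benign, 0…5 VUS (Low 0–1 / Mid 2–3 / High 4–5),
  6…9 likely pathogenic, ≥10 pathogenic;
* **AlphaMissense categorization** at the release thresholds
  (<0.34 benign, ≤0.564 ambiguous, else pathogenic) and conversion to
  PP3/BP4 evidence (ambiguous contributes nothing);
* the two **integration experiments** — augmentation of
  computational-evidence-free VUS, and replacement of existing computational
  evidence by the AlphaMissense item — with per-variant before/after points,
  tiers, VUS bands, and tier-transition matrices;
* **concordance statistics**: the 3×3 category-vs-tier contingency table,
  two binary collapse schemes (sensitivity/specificity/PPV/NPV), comparison
  groups, chi-square, Spearman rank correlation, t-based mean CIs;
* **fixtures** that deterministically expand the published summary tables
  into per-variant cohorts, and a **seeded simulator** emulating the
  cohort's statistical structure (class proportions, bimodal VUS score
  mixture, evidence-combination frequencies).

See `vignette("quantifying-vus")` for the methods account and design
decisions.

## Worked example

```r
library(vusquant)

# 4085 curated VUS expanded from the published evidence-combination table,
# with the published per-group AlphaMissense additions
cohort <- fixture_vus_table5()
run_augmentation(cohort)
#> Evidence-integration experiment over 4085 variants
#>   modified:        934
#>   points changed:  934
#>   tier changed:    68
#> Tier transitions (quantified before -> after):
#>                    after
#> before              benign likely_benign  vus likely_pathogenic pathogenic
#>   benign                 0             0    0                 0          0
#>   likely_benign          0            24    0                 0          0
#>   vus                    0            12 3993                56          0
#>   likely_pathogenic      0             0    0                 0          0
#>   pathogenic             0             0    0                 0          0
```

Adding the AlphaMissense item to eligible VUS changes 934 quantifications;
56 variants reach the likely-pathogenic bin (points 6) and 12 drop to −1.
The 24 variants already at −1 before augmentation are curated VUS whose
existing evidence quantifies as likely benign; they are untouched.

```r
concordance_summary(fixture_table2a())
#> AlphaMissense vs curated-tier concordance, 5845 variants
#>
#>             acmg
#> am           pathogenic  vus benign
#>   pathogenic       1352 2458     38
#>   ambiguous         108  403     14
#>   benign            116 1224    132
#>
#> Concordant (diagonal): 1887
#> Pathogenic vs benign (uncertain excluded): sens 92%, spec 78%, PPV 97%, NPV 53%
#> Pathogenic vs rest:                        sens 86%, spec 42%, PPV 35%, NPV 89%
#> Chi-square: 578.4 (df 4), p <2e-16
```

The first metric line compares pathogenic against benign calls with all
uncertain calls excluded; the second treats curated P/LP against everything
else. The high PPV (97%) says AlphaMissense-pathogenic calls on decisively
curated variants are nearly always curated pathogenic; the low NPV (53%)
says its benign calls are much less reliable.

A thin command-line wrapper is included for shell pipelines:

```sh
Rscript inst/scripts/vusquant.R fixtures table5 --out t5.tsv
Rscript inst/scripts/vusquant.R augment --input t5.tsv --out report/
```

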