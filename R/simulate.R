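# Seeded stochastic cohort generator emulating the statistical structure of a
# curated neuromuscular-panel cohort: class proportions, per-class
# AlphaMissense score mixtures (bimodal for VUS), and evidence-combination
# frequencies.

#' Gene symbols of the curated neuromuscular/neurological panel
#'
#' The 59 genes of the curated panel associated with neurological,
#' musculoskeletal and/or neuromuscular Mendelian disorders, carried as
#' metadata on simulated variants.
#'
#' @return Character vector of 59 gene symbols.
#' @export
panel_genes <- function() {
  c("AGRN", "BPNT2", "MUSK", "MYO9A", "SCN4A", "SNAP25", "ABHD16A", "ACSL4",
    "ANKLE2", "AP3B2", "ASAH1", "BEAN1", "BRWD3", "CABP4", "CC2D1A",
    "CDC42BPB", "CEP135", "CRADD", "DDHD1", "FAM126A", "FOXP1", "GRIN2A",
    "KDM5C", "NBEA", "NF1", "PLA2G6", "PRRT2", "SACS", "SCN8A", "SLC52A3",
    "SNIP1", "STAG2", "TAF2", "WDR45", "COQ8A", "GLRB", "SLC6A5", "ALG14",
    "ASCC1", "CAPN3", "CHAT", "CHRNB1", "CHRND", "CHRNE", "COL13A1",
    "COL6A3", "COLQ", "DOK7", "DPM3", "DYSF", "FKRP", "GCH1", "GFPT1",
    "LRP4", "PREPL", "RYR1", "SLC18A3", "SLC5A7", "VAMP1")
}

#' Default AlphaMissense score mixtures per collapsed tier
#'
#' Beta-mixture components on `[0, 1]` parameterized by mean and concentration
#' (`kappa`): benign variants center on 0.3, pathogenic on 0.85, and VUS follow
#' a bimodal (saddle) mixture of components at 0.2 and 0.8 weighted 4/15 and
#' 11/15 so the overall VUS mean is 0.64. Component spreads are configuration,
#' not empirical claims.
#'
#' @return A named list (`benign`, `vus`, `pathogenic`) of component
#'   parameter lists (`mean`, `kappa`, `weight`).
#' @export
default_am_mixture <- function() {
  list(
    benign = list(mean = 0.30, kappa = 8, weight = 1),
    vus = list(mean = c(0.20, 0.80), kappa = c(8, 8),
               weight = c(4 / 15, 11 / 15)),
    pathogenic = list(mean = 0.85, kappa = 12, weight = 1))
}

#' Default evidence-combination templates per curated tier
#'
#' Weighted strength-profile templates drawn per simulated variant. The VUS
#' templates are the 20 published combination groups weighted by their group
#' sizes, with a per-template probability of carrying computational evidence
#' (`p_computational`) equal to the fraction of the group not receiving an
#' AlphaMissense addition in the published augmentation accounting (0 for
#' profiles with no supporting item to realize). Templates for the four
#' non-VUS tiers are point-consistent inventions — each template quantifies
#' into its tier's point bin — since per-variant evidence for those tiers is
#' not published.
#'
#' @return A named list per tier, each a tibble of `PS, PM, PP, BP, BS, BA`
#'   counts with `weight` and `p_computational` columns.
#' @export
default_evidence_profiles <- function() {
  t5 <- table5_rows()
  has_supporting <- t5$PP > 0 | t5$BP > 0
  p_comp <- ifelse(has_supporting,
                   (t5$n - t5$n_benign - t5$n_pathogenic) / t5$n, 0)
  vus <- tibble::tibble(PS = t5$PS, PM = t5$PM, PP = t5$PP, BP = t5$BP,
                        BS = t5$BS, BA = 0L, weight = t5$n / sum(t5$n),
                        p_computational = p_comp)
  tpl <- function(...) {
    df <- tibble::tibble(...)
    for (col in c("PS", "PM", "PP", "BP", "BS", "BA")) {
      if (!col %in% names(df)) df[[col]] <- 0L
    }
    df$weight <- df$weight / sum(df$weight)
    if (!"p_computational" %in% names(df)) df$p_computational <- 0
    df[, c("PS", "PM", "PP", "BP", "BS", "BA", "weight", "p_computational")]
  }
  list(
    benign = tpl(BS = c(2L, 1L), BA = c(0L, 1L), weight = c(0.6, 0.4)),
    likely_benign = tpl(BP = c(1L, 2L, 3L), weight = c(0.5, 0.3, 0.2)),
    vus = vus,
    likely_pathogenic = tpl(PS = c(1L, 0L, 1L), PM = c(1L, 3L, 1L),
                            PP = c(1L, 1L, 0L), weight = c(0.5, 0.3, 0.2)),
    pathogenic = tpl(PS = c(2L, 1L, 2L), PM = c(1L, 3L, 2L),
                     PP = c(2L, 1L, 0L), weight = c(0.4, 0.3, 0.3)))
}

#' Specification for a simulated cohort
#'
#' Bundles the generator's parameters: cohort size, five-tier proportions,
#' per-collapsed-tier AlphaMissense score mixtures, per-tier
#' evidence-combination templates, and the default seed. The defaults emulate
#' the published cohort: 5845 variants in proportions 1576 P/LP : 184 B/LB :
#' 4085 VUS (split evenly within each collapsed pair), score mixtures with
#' means 0.3 / 0.85 and a bimodal VUS mixture with mean 0.64, and VUS evidence
#' combinations at their published frequencies.
#'
#' @param n_variants Cohort size.
#' @param tier_proportions Named 5-vector over [acmg_tiers()], summing to 1.
#' @param am_mixture See [default_am_mixture()].
#' @param evidence_profiles See [default_evidence_profiles()].
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_variants = 100)
#' @export
cohort_spec <- function(n_variants = 5845L,
                        tier_proportions = c(benign = 92, likely_benign = 92,
                                             vus = 4085,
                                             likely_pathogenic = 788,
                                             pathogenic = 788) / 5845,
                        am_mixture = default_am_mixture(),
                        evidence_profiles = default_evidence_profiles(),
                        seed = 1234L) {
  stopifnot(length(n_variants) == 1, n_variants >= 0)
  if (!setequal(names(tier_proportions), TIER_LEVELS)) {
    stop("`tier_proportions` must be named over the five tiers")
  }
  if (abs(sum(tier_proportions) - 1) > 1e-9 || any(tier_proportions < 0)) {
    stop("`tier_proportions` must be non-negative and sum to 1")
  }
  for (g in c("benign", "vus", "pathogenic")) {
    mix <- am_mixture[[g]]
    if (is.null(mix)) stop("`am_mixture` must have a `", g, "` component")
    if (abs(sum(mix$weight) - 1) > 1e-9 || any(mix$weight < 0)) {
      stop("mixture weights for `", g, "` must be non-negative and sum to 1")
    }
    if (any(mix$mean <= 0) || any(mix$mean >= 1) || any(mix$kappa <= 0)) {
      stop("mixture components for `", g,
           "` must have means in (0, 1) and positive concentration")
    }
  }
  if (!all(TIER_LEVELS %in% names(evidence_profiles))) {
    stop("`evidence_profiles` must have templates for all five tiers")
  }
  structure(list(n_variants = as.integer(n_variants),
                 tier_proportions = tier_proportions[TIER_LEVELS],
                 am_mixture = am_mixture,
                 evidence_profiles = evidence_profiles,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.empty_cohort <- function() {
  tibble::tibble(variant_id = character(), gene = character(),
                 curated_tier = character(), evidence = character(),
                 am_score = numeric(), am_category = character(),
                 revel_score = numeric())
}

.draw_mixture <- function(n, mix) {
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(mix$weight), n, replace = TRUE, prob = mix$weight)
  stats::rbeta(n, mix$mean[comp] * mix$kappa[comp],
               (1 - mix$mean[comp]) * mix$kappa[comp])
}

#' Simulate a variant cohort
#'
#' Seeded draw of `spec$n_variants` records: curated tier from the tier
#' proportions, evidence from the tier's weighted combination templates
#' (realized as concrete codes, with computational-evidence marking at the
#' template's probability), AlphaMissense score from the collapsed tier's Beta
#' mixture, and a REVEL-like companion score rank-correlated with the
#' AlphaMissense score. The output is a pure function of `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the spec's.
#' @return A cohort tibble (see [read_cohort()] for the column contract).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_variants = 50))
#' table(cohort$curated_tier)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_variants
  if (n == 0) return(.empty_cohort())
  .with_seed(seed, {
    tier <- sample(TIER_LEVELS, n, replace = TRUE,
                   prob = spec$tier_proportions)
    collapsed <- collapse_tier(tier)
    am_score <- numeric(n)
    for (g in c("benign", "vus", "pathogenic")) {
      idx <- which(collapsed == g)
      am_score[idx] <- .draw_mixture(length(idx), spec$am_mixture[[g]])
    }
    evidence <- character(n)
    for (t in TIER_LEVELS) {
      idx <- which(tier == t)
      if (length(idx) == 0) next
      tmpl <- spec$evidence_profiles[[t]]
      pick <- sample.int(nrow(tmpl), length(idx), replace = TRUE,
                         prob = tmpl$weight)
      comp <- stats::runif(length(idx)) < tmpl$p_computational[pick]
      evidence[idx] <- mapply(function(k, cm) {
        row <- tmpl[k, ]
        base <- .realize_profile(row$PS, row$PM, row$PP, row$BP, row$BS,
                                 computational = cm)
        if (row$BA > 0) {
          base <- paste(c(base[nzchar(base)], rep("BA1", row$BA)),
                        collapse = ";")
        }
        base
      }, pick, comp, USE.NAMES = FALSE)
    }
    # REVEL companion: Beta draw whose mean tracks the AM score, giving a
    # strong positive rank correlation without duplicating the score.
    revel_mean <- 0.15 + 0.7 * am_score
    revel <- stats::rbeta(n, revel_mean * 10, (1 - revel_mean) * 10)
    tibble::tibble(
      variant_id = sprintf("SIM-%05d", seq_len(n)),
      gene = sample(panel_genes(), n, replace = TRUE),
      curated_tier = tier,
      evidence = evidence,
      am_score = am_score,
      am_category = am_category(am_score),
      revel_score = revel)
  })
}
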