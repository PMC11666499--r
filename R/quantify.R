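# Points-based quantification: strength class -> points, points -> tier/band.

#' Point values for the seven evidence-strength classes
#'
#' The integer point adaptation of the Bayesian classification framework used
#' throughout the package: stand-alone and strong benign evidence score -4,
#' supporting benign -1, and pathogenic supporting/moderate/strong/very-strong
#' score +1/+2/+4/+8. Indeterminate or absent evidence contributes 0. The map
#' is exposed so alternative calibrations can be passed to the quantification
#' functions; defaults should be left alone for the standard system.
#'
#' @return A named integer vector over `PVS, PS, PM, PP, BP, BS, BA`.
#' @examples
#' acmg_points()
#' @export
acmg_points <- function() {
  c(PVS = 8L, PS = 4L, PM = 2L, PP = 1L, BP = -1L, BS = -4L, BA = -4L)
}

#' Points for a single strength class
#'
#' @param strength_class Character vector of scored strength classes
#'   (`PVS`, `PS`, `PM`, `PP`, `BP`, `BS`, `BA`).
#' @param points Point map, by default [acmg_points()].
#' @return Integer vector of point values.
#' @examples
#' points_for_strength(c("PM", "BS", "PVS"))
#' @export
points_for_strength <- function(strength_class, points = acmg_points()) {
  bad <- !strength_class %in% names(points)
  if (any(bad)) {
    stop("unknown strength class: ",
         paste(unique(strength_class[bad]), collapse = ", "))
  }
  unname(points[strength_class])
}

#' Quantify a strength profile
#'
#' Sums count-weighted points over the strength classes of a profile. Missing
#' classes count as zero, so partial profiles such as `c(PM = 2, PP = 1)` are
#' accepted.
#'
#' @param profile Named non-negative integer vector of per-class counts, as
#'   from [strength_profile()].
#' @param points Point map, by default [acmg_points()].
#' @return Integer points total (0 for an empty profile).
#' @examples
#' quantify_profile(c(PM = 1, PP = 1)) # 3
#' quantify_profile(c(PP = 1, BP = 1)) # 0
#' @export
quantify_profile <- function(profile, points = acmg_points()) {
  if (length(profile) == 0) return(0L)
  if (is.null(names(profile)) || any(!nzchar(names(profile)))) {
    stop("`profile` must be a named count vector over strength classes")
  }
  bad <- !names(profile) %in% names(points)
  if (any(bad)) {
    stop("unknown strength class: ",
         paste(names(profile)[bad], collapse = ", "))
  }
  counts <- as.numeric(profile)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("profile counts must be non-negative integers")
  }
  as.integer(sum(counts * points[names(profile)]))
}

#' Classify a points total into the five-tier system
#'
#' Tier bins over the points total: `<= -4` benign, `-3..-1` likely benign,
#' `0..5` VUS, `6..9` likely pathogenic, `>= 10` pathogenic. Bins are
#' open-ended at both extremes; no clamping is applied.
#'
#' @param points Integer points total (vectorized).
#' @return Character vector of tiers (see [acmg_tiers()]).
#' @examples
#' classify_points(c(-4, -1, 0, 5, 6, 10))
#' @export
classify_points <- function(points) {
  if (!is.numeric(points)) stop("`points` must be numeric")
  as.character(cut(points, breaks = c(-Inf, -3.5, -0.5, 5.5, 9.5, Inf),
                   labels = TIER_LEVELS))
}

#' VUS sub-band for a points total
#'
#' Points in the VUS bin are subdivided into Low (0-1), Mid (2-3), and High
#' (4-5). Points outside 0-5 have no band (`NA`).
#'
#' @param points Integer points total (vectorized).
#' @return Character vector in `low`, `mid`, `high`, or `NA`.
#' @examples
#' vus_band(c(0, 3, 5, 7))
#' @export
vus_band <- function(points) {
  if (!is.numeric(points)) stop("`points` must be numeric")
  ifelse(points >= 0 & points <= 1, "low",
  ifelse(points >= 2 & points <= 3, "mid",
  ifelse(points >= 4 & points <= 5, "high", NA_character_)))
}

#' Quantify every variant in a cohort
#'
#' Parses each variant's semicolon-delimited evidence field, sums item points,
#' and derives the tier and (for VUS-range totals) the sub-band. Also flags
#' whether any computational-type evidence (PP3/BP4) is assigned.
#'
#' @param cohort Cohort tibble with `variant_id` and `evidence` columns.
#' @param catalog Evidence catalog.
#' @param points Point map, by default [acmg_points()].
#' @return A tibble: `variant_id`, `points`, `tier`, `vus_band`,
#'   `has_computational`.
#' @examples
#' cohort <- tibble::tibble(variant_id = c("v1", "v2"),
#'                          evidence = c("PM2;PP1", "PP3;BP1"))
#' cohort_quantify(cohort)
#' @export
cohort_quantify <- function(cohort, catalog = acmg_catalog(),
                            points = acmg_points()) {
  .check_cohort(cohort, require = c("variant_id", "evidence"))
  n <- nrow(cohort)
  pts <- integer(n)
  comp <- logical(n)
  items <- .split_evidence(cohort$evidence)
  if (sum(lengths(items)) > 0) {
    idx <- rep(seq_len(n), lengths(items))
    parsed <- parse_evidence(unlist(items, use.names = FALSE), catalog)
    item_pts <- points_for_strength(parsed$strength_class, points)
    agg <- rowsum(as.numeric(item_pts), idx)
    pts[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    comp[unique(idx[parsed$evidence_type == "computational"])] <- TRUE
  }
  tier <- classify_points(pts)
  tibble::tibble(
    variant_id = cohort$variant_id,
    points = pts,
    tier = tier,
    vus_band = ifelse(tier == "vus", vus_band(pts), NA_character_),
    has_computational = comp)
}
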