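# Concordance between AlphaMissense categories and curated tiers: 3x3
# contingency table, two binary collapse schemes, comparison groups, and
# auxiliary statistics.

COMPARISON_GROUPS <- c("PATH-path", "PATH-amb", "PATH-ben",
                       "VUS-path", "VUS-amb", "VUS-ben",
                       "BEN-path", "BEN-amb", "BEN-ben")

# Whole-percent rendering, round-half-away-from-zero (values are >= 0 here).
.whole_percent <- function(x) {
  ifelse(is.na(x), NA_real_, floor(x * 100 + 0.5))
}

#' 3x3 AlphaMissense-vs-curated contingency table
#'
#' Tallies a cohort into a 3x3 table with AlphaMissense categories as rows
#' (pathogenic, ambiguous, benign) and collapsed curated tiers as columns
#' (pathogenic = P/LP, vus, benign = B/LB).
#'
#' @param cohort Cohort tibble; every variant must have a `curated_tier` and
#'   an AlphaMissense category (given or derivable from `am_score`).
#' @return An integer matrix with dimnames `am` x `acmg`.
#' @examples
#' contingency_3x3(fixture_table2a())
#' @export
contingency_3x3 <- function(cohort) {
  .check_cohort(cohort, require = c("variant_id", "curated_tier"))
  amc <- .resolve_am_category(cohort)
  if (anyNA(amc) || anyNA(cohort$curated_tier)) {
    bad <- is.na(amc) | is.na(cohort$curated_tier)
    stop("every variant needs a curated tier and an AlphaMissense category; ",
         "missing for: ",
         paste(utils::head(cohort$variant_id[bad], 10), collapse = ", "),
         if (sum(bad) > 10) " ..." else "")
  }
  acmg <- collapse_tier(cohort$curated_tier)
  tab <- table(factor(amc, levels = c("pathogenic", "ambiguous", "benign")),
               factor(acmg, levels = c("pathogenic", "vus", "benign")))
  matrix(as.integer(tab), nrow = 3,
         dimnames = list(am = c("pathogenic", "ambiguous", "benign"),
                         acmg = c("pathogenic", "vus", "benign")))
}

.check_contingency <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == c(3, 3))) {
    stop("`tab` must be a 3x3 matrix (AlphaMissense rows x curated columns)")
  }
  if (any(tab < 0)) stop("contingency counts must be non-negative")
  if (is.null(dimnames(tab))) {
    dimnames(tab) <- list(am = c("pathogenic", "ambiguous", "benign"),
                          acmg = c("pathogenic", "vus", "benign"))
  }
  tab
}

.binary_metrics <- function(tp, fp, fn, tn) {
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  ppv <- frac(tp, tp + fp)
  npv <- frac(tn, tn + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       percent = c(sensitivity = .whole_percent(sens),
                   specificity = .whole_percent(spec),
                   ppv = .whole_percent(ppv),
                   npv = .whole_percent(npv)))
}

#' Concordance metrics excluding uncertain calls
#'
#' The pathogenic-vs-benign collapse: TP = (AM pathogenic, curated P/LP),
#' FP = (AM pathogenic, curated B/LB), FN = (AM benign, curated P/LP),
#' TN = (AM benign, curated B/LB). The ambiguous row and the VUS column are
#' excluded entirely. Metrics with a zero denominator are reported as `NA`
#' rather than 0 or 100.
#'
#' @param tab 3x3 contingency matrix from [contingency_3x3()].
#' @return A list with `tp`, `fp`, `fn`, `tn`, the four metric fractions, and
#'   a `percent` vector with whole-percent renderings
#'   (round-half-away-from-zero).
#' @examples
#' metrics_excluding_uncertain(contingency_3x3(fixture_table2a()))$percent
#' @export
metrics_excluding_uncertain <- function(tab) {
  tab <- .check_contingency(tab)
  .binary_metrics(tp = tab["pathogenic", "pathogenic"],
                  fp = tab["pathogenic", "benign"],
                  fn = tab["benign", "pathogenic"],
                  tn = tab["benign", "benign"])
}

#' Concordance metrics, pathogenic versus everything else
#'
#' The pathogenic-vs-rest collapse: curated P/LP versus curated non-pathogenic
#' (VUS and B/LB), against AM pathogenic versus AM non-pathogenic (ambiguous
#' and benign). TP = (AM pathogenic, curated P/LP); FN = curated P/LP called
#' ambiguous or benign; FP = AM pathogenic calls on curated VUS or B/LB;
#' TN = everything else.
#'
#' @inheritParams metrics_excluding_uncertain
#' @return As [metrics_excluding_uncertain()].
#' @examples
#' metrics_path_vs_rest(contingency_3x3(fixture_table2a()))$percent
#' @export
metrics_path_vs_rest <- function(tab) {
  tab <- .check_contingency(tab)
  .binary_metrics(
    tp = tab["pathogenic", "pathogenic"],
    fn = tab["ambiguous", "pathogenic"] + tab["benign", "pathogenic"],
    fp = tab["pathogenic", "vus"] + tab["pathogenic", "benign"],
    tn = tab["ambiguous", "vus"] + tab["ambiguous", "benign"] +
         tab["benign", "vus"] + tab["benign", "benign"])
}

#' Comparison-group label for a variant
#'
#' Combines the collapsed curated tier (PATH/VUS/BEN) with the AlphaMissense
#' category (path/amb/ben) into the nine comparison-group labels used to sort
#' evidence heatmaps, e.g. `PATH-path` for concordant pathogenic calls or
#' `VUS-amb` for curated VUS predicted ambiguous.
#'
#' @param curated_tier Character vector of curated tiers.
#' @param am_category Character vector of AlphaMissense categories.
#' @return A factor over the nine labels.
#' @examples
#' comparison_group(c("vus", "pathogenic"), c("ambiguous", "benign"))
#' @export
comparison_group <- function(curated_tier, am_category) {
  if (length(curated_tier) != length(am_category)) {
    stop("`curated_tier` and `am_category` must have the same length")
  }
  ct <- collapse_tier(curated_tier)
  bad <- !is.na(am_category) & !am_category %in% AM_LEVELS
  if (any(bad)) {
    stop("invalid AlphaMissense category: ",
         paste(unique(am_category[bad]), collapse = ", "))
  }
  tier_part <- c(pathogenic = "PATH", vus = "VUS", benign = "BEN")[ct]
  am_part <- c(pathogenic = "path", ambiguous = "amb",
               benign = "ben")[am_category]
  factor(ifelse(is.na(tier_part) | is.na(am_part), NA,
                paste(tier_part, am_part, sep = "-")),
         levels = COMPARISON_GROUPS)
}

#' Pearson chi-square test of independence
#'
#' Runs the Pearson chi-square test (no continuity correction) on a
#' contingency table, typically the full 3x3 AM-vs-curated table (df = 4).
#' Tables with a zero row or column marginal are rejected.
#'
#' @param tab Count matrix.
#' @return A list: `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(contingency_3x3(fixture_table2a()))
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test requires all row and column marginals > 0")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic),
       df = unname(res$parameter),
       p_value = res$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, e.g. for comparing
#' AlphaMissense scores against REVEL scores. Constant input yields `NA` with
#' a warning.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return The correlation coefficient, or `NA` if either vector is constant.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("rank correlation undefined for constant input", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Mean with t-based confidence interval
#'
#' Sample mean with a two-sided Student-t confidence interval, as used for
#' per-group AlphaMissense score summaries. A constant sample returns a
#' degenerate interval at the mean.
#'
#' @param values Numeric vector, length >= 2.
#' @param level Confidence level (default 0.95).
#' @return A named numeric vector: `mean`, `lower`, `upper`.
#' @examples
#' mean_ci(c(1, 2, 3, 4, 5))
#' @export
mean_ci <- function(values, level = 0.95) {
  if (anyNA(values)) stop("missing values are not allowed")
  if (length(values) < 2) stop("need at least 2 observations")
  m <- mean(values)
  if (stats::sd(values) == 0) {
    return(c(mean = m, lower = m, upper = m))
  }
  ci <- stats::t.test(values, conf.level = level)$conf.int
  c(mean = m, lower = ci[1], upper = ci[2])
}

#' Full concordance summary for a cohort
#'
#' Convenience wrapper assembling the 3x3 contingency table, its diagonal
#' concordance count, marginals, both binary metric schemes, comparison-group
#' counts, and the chi-square test (omitted with a message when a marginal is
#' zero).
#'
#' @param cohort Cohort tibble with curated tiers and AlphaMissense
#'   categories/scores.
#' @return An object of class `am_concordance`.
#' @examples
#' concordance_summary(fixture_table2a())
#' @export
concordance_summary <- function(cohort) {
  tab <- contingency_3x3(cohort)
  amc <- .resolve_am_category(cohort)
  chi <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("chi-square test skipped: zero marginal in the contingency table")
    NULL
  } else {
    chi_square_independence(tab)
  }
  structure(list(
    n = sum(tab),
    contingency = tab,
    concordant = sum(diag(tab)),
    am_marginals = rowSums(tab),
    acmg_marginals = colSums(tab),
    metrics_excluding_uncertain = metrics_excluding_uncertain(tab),
    metrics_path_vs_rest = metrics_path_vs_rest(tab),
    comparison_groups = table(comparison_group(cohort$curated_tier, amc)),
    chi_square = chi), class = "am_concordance")
}

#' @export
print.am_concordance <- function(x, ...) {
  cat("AlphaMissense vs curated-tier concordance,", x$n, "variants\n\n")
  print(x$contingency)
  cat("\nConcordant (diagonal):", x$concordant, "\n")
  fmt <- function(m) {
    p <- m$percent
    paste0("sens ", p["sensitivity"], "%, spec ", p["specificity"],
           "%, PPV ", p["ppv"], "%, NPV ", p["npv"], "%")
  }
  cat("Pathogenic vs benign (uncertain excluded): ",
      fmt(x$metrics_excluding_uncertain), "\n", sep = "")
  cat("Pathogenic vs rest:                        ",
      fmt(x$metrics_path_vs_rest), "\n", sep = "")
  if (!is.null(x$chi_square)) {
    cat(sprintf("Chi-square: %.1f (df %d), p %s\n", x$chi_square$statistic,
                x$chi_square$df,
                format.pval(x$chi_square$p_value, digits = 3)))
  }
  invisible(x)
}
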