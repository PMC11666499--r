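# Evidence-integration experiments: augmentation of computational-evidence-free
# VUS, and replacement of existing computational evidence by the AlphaMissense
# item; tier-transition accounting.

#' Does a variant carry computational-type evidence?
#'
#' True when at least one assigned evidence item is of computational type
#' (PP3 or BP4 in the default catalog, any multiplicity or modifier).
#'
#' @param evidence Character vector of semicolon-delimited evidence fields.
#' @param catalog Evidence catalog.
#' @return Logical vector.
#' @examples
#' has_computational_evidence(c("PM2;PP3", "PM2;PP1", ""))
#' @export
has_computational_evidence <- function(evidence, catalog = acmg_catalog()) {
  items <- .split_evidence(evidence)
  out <- logical(length(evidence))
  if (sum(lengths(items)) > 0) {
    idx <- rep(seq_along(items), lengths(items))
    parsed <- parse_evidence(unlist(items, use.names = FALSE), catalog)
    out[unique(idx[parsed$evidence_type == "computational"])] <- TRUE
  }
  out
}

# Append a code token to a semicolon-delimited evidence field.
.append_code <- function(evidence, code) {
  evidence <- ifelse(is.na(evidence), "", evidence)
  ifelse(nzchar(evidence), paste(evidence, code, sep = ";"), code)
}

# Remove all computational-type items from evidence fields (both polarities,
# all multiplicities), preserving the order of the remaining tokens.
.strip_computational <- function(evidence, catalog = acmg_catalog()) {
  items <- .split_evidence(evidence)
  out <- character(length(evidence))
  if (sum(lengths(items)) > 0) {
    idx <- rep(seq_along(items), lengths(items))
    parsed <- parse_evidence(unlist(items, use.names = FALSE), catalog)
    keep <- parsed$evidence_type != "computational"
    kept <- vapply(split(parsed$raw_code[keep], factor(idx[keep],
                   levels = seq_along(items))),
                   paste, character(1), collapse = ";")
    out[] <- unname(kept)
  }
  out
}

# Assemble the shared experiment outcome object.
.experiment_outcome <- function(cohort, points_before, points_after,
                                modified, evidence_after) {
  tier_before <- classify_points(points_before)
  tier_after <- classify_points(points_after)
  per_variant <- tibble::tibble(
    variant_id = cohort$variant_id,
    curated_tier = cohort$curated_tier,
    points_before = points_before,
    points_after = points_after,
    tier_before = tier_before,
    tier_after = tier_after,
    band_before = ifelse(tier_before == "vus", vus_band(points_before),
                         NA_character_),
    band_after = ifelse(tier_after == "vus", vus_band(points_after),
                        NA_character_),
    modified = modified)
  trans <- transition_matrix(tier_before, tier_after)
  cohort_after <- cohort
  cohort_after$evidence <- evidence_after
  structure(list(
    per_variant = per_variant,
    n_modified = sum(modified),
    n_points_changed = sum(points_after != points_before),
    n_tier_changed = trans$n_changed,
    transition_counts = trans$counts,
    cohort_after = cohort_after), class = "evidence_experiment")
}

#' Augment computational-evidence-free VUS with AlphaMissense evidence
#'
#' Appends the AlphaMissense-derived computational item (PP3 for pathogenic
#' predictions, BP4 for benign; nothing for ambiguous) to exactly those
#' variants that are curated VUS *and* carry no computational-type evidence.
#' All other variants are untouched. The whole cohort is re-quantified and
#' before/after points, tiers and VUS sub-bands are recorded.
#'
#' @param cohort Cohort tibble with `variant_id`, `curated_tier`, `evidence`,
#'   and `am_score` and/or `am_category`. Eligible variants must have an
#'   AlphaMissense category.
#' @param catalog Evidence catalog.
#' @param points Point map.
#' @return An object of class `evidence_experiment`: a list with `per_variant`
#'   (one row per cohort variant), `n_modified`, `n_points_changed`,
#'   `n_tier_changed`, the 5x5 `transition_counts` matrix over quantified
#'   tiers, and `cohort_after` (the cohort with updated evidence fields).
#' @examples
#' cohort <- fixture_vus_table5()
#' out <- run_augmentation(cohort)
#' out$n_points_changed
#' @export
run_augmentation <- function(cohort, catalog = acmg_catalog(),
                             points = acmg_points()) {
  .check_cohort(cohort)
  q0 <- cohort_quantify(cohort, catalog, points)
  amc <- .resolve_am_category(cohort)
  eligible <- !is.na(cohort$curated_tier) & cohort$curated_tier == "vus" &
    !q0$has_computational
  missing_am <- eligible & is.na(amc)
  if (any(missing_am)) {
    stop("augmentation requires an AlphaMissense category for every eligible ",
         "VUS; missing for: ",
         paste(utils::head(cohort$variant_id[missing_am], 10),
               collapse = ", "),
         if (sum(missing_am) > 10) " ..." else "")
  }
  add <- rep(NA_character_, nrow(cohort))
  add[eligible] <- am_evidence_code(amc[eligible])
  modified <- !is.na(add)
  delta <- ifelse(modified, ifelse(add == "PP3", 1L, -1L), 0L)
  evidence_after <- ifelse(modified,
                           .append_code(cohort$evidence, add),
                           ifelse(is.na(cohort$evidence), "",
                                  cohort$evidence))
  .experiment_outcome(cohort, q0$points, q0$points + delta, modified,
                      evidence_after)
}

#' Replace existing computational evidence with the AlphaMissense item
#'
#' For every in-scope variant (curated VUS when `scope = "vus"`, everyone when
#' `scope = "all"`), removes all computational-type evidence items (both
#' polarities, all multiplicities) and appends the single AlphaMissense-derived
#' item (PP3/BP4; nothing for ambiguous). In-scope variants lacking
#' computational evidence thereby also receive the item, so the operation
#' covers both replacement and addition. The operation is idempotent: the
#' AM-derived item is itself computational and is swapped for itself on a
#' second run.
#'
#' @inheritParams run_augmentation
#' @param scope `"vus"` (curated VUS only) or `"all"` (entire cohort).
#' @return An `evidence_experiment` object; see [run_augmentation()].
#' @examples
#' cohort <- fixture_vus_table5()
#' out <- run_replacement(cohort, scope = "vus")
#' out$n_tier_changed
#' @export
run_replacement <- function(cohort, scope = c("vus", "all"),
                            catalog = acmg_catalog(),
                            points = acmg_points()) {
  scope <- match.arg(scope)
  .check_cohort(cohort)
  q0 <- cohort_quantify(cohort, catalog, points)
  in_scope <- if (scope == "vus") {
    !is.na(cohort$curated_tier) & cohort$curated_tier == "vus"
  } else {
    rep(TRUE, nrow(cohort))
  }
  amc <- .resolve_am_category(cohort)
  missing_am <- in_scope & is.na(amc)
  if (any(missing_am)) {
    stop("replacement requires an AlphaMissense category for every in-scope ",
         "variant; missing for: ",
         paste(utils::head(cohort$variant_id[missing_am], 10),
               collapse = ", "),
         if (sum(missing_am) > 10) " ..." else "")
  }
  stripped <- .strip_computational(cohort$evidence, catalog)
  add <- rep(NA_character_, nrow(cohort))
  add[in_scope] <- am_evidence_code(amc[in_scope])
  new_evidence <- ifelse(in_scope,
                         ifelse(is.na(add), stripped,
                                .append_code(stripped, add)),
                         ifelse(is.na(cohort$evidence), "", cohort$evidence))
  cohort_new <- cohort
  cohort_new$evidence <- new_evidence
  q1 <- cohort_quantify(cohort_new, catalog, points)
  modified <- in_scope & (q0$has_computational | !is.na(add))
  .experiment_outcome(cohort, q0$points, q1$points, modified, new_evidence)
}

#' Tier transition matrix
#'
#' Cross-tabulates aligned before/after tier vectors into a 5x5 count matrix
#' (rows = before, columns = after, both ordered benign to pathogenic), and
#' reports the number and fraction of variants changing tier.
#'
#' @param before,after Equal-length character vectors of tiers.
#' @return A list: `counts` (5x5 integer matrix), `n_changed` (off-diagonal
#'   sum), `fraction_changed`.
#' @examples
#' transition_matrix(c("vus", "vus"), c("vus", "likely_pathogenic"))$n_changed
#' @export
transition_matrix <- function(before, after) {
  if (length(before) != length(after)) {
    stop("`before` and `after` must have the same length")
  }
  b <- factor(before, levels = TIER_LEVELS)
  a <- factor(after, levels = TIER_LEVELS)
  if (anyNA(b) != anyNA(before) || anyNA(a) != anyNA(after)) {
    stop("invalid tier label in `before`/`after`")
  }
  counts <- table(before = b, after = a)
  counts <- matrix(as.integer(counts), nrow = 5,
                   dimnames = list(before = TIER_LEVELS, after = TIER_LEVELS))
  n_changed <- sum(counts) - sum(diag(counts))
  list(counts = counts, n_changed = n_changed,
       fraction_changed = if (length(before) == 0) NA_real_
                          else n_changed / length(before))
}

#' @export
print.evidence_experiment <- function(x, ...) {
  n <- nrow(x$per_variant)
  cat("Evidence-integration experiment over", n, "variants\n")
  cat("  modified:       ", x$n_modified, "\n")
  cat("  points changed: ", x$n_points_changed, "\n")
  cat("  tier changed:   ", x$n_tier_changed, "\n")
  cat("Tier transitions (quantified before -> after):\n")
  print(x$transition_counts)
  invisible(x)
}
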