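# Deterministic fixtures expanding published per-combination summary tables
# into per-variant cohorts, so every pipeline stage is testable without any
# download or supplementary data.

# Restore the caller's RNG state after a seeded draw.
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Published 3x3 concordance counts (full cohort)
#'
#' The full-cohort cross-tabulation of AlphaMissense categories (rows:
#' pathogenic, ambiguous, benign) against collapsed curated tiers (columns:
#' P/LP, VUS, B/LB) for the 5845-variant neuromuscular-panel cohort.
#'
#' @return A 3x3 integer matrix.
#' @examples
#' table2a_counts()
#' @export
table2a_counts <- function() {
  matrix(c(1352L, 2458L, 38L,
           108L,  403L,  14L,
           116L, 1224L, 132L),
         nrow = 3, byrow = TRUE,
         dimnames = list(am = c("pathogenic", "ambiguous", "benign"),
                         acmg = c("pathogenic", "vus", "benign")))
}

#' Expand a 3x3 contingency table into a per-variant cohort
#'
#' Emits exactly `counts[i, j]` variant records per cell. Curated tiers are
#' set from the column, with P/LP (and B/LB) cells split deterministically by
#' alternation between the two constituent tiers. AlphaMissense scores are
#' drawn uniformly (seeded) inside the row category's score interval, so the
#' derived category round-trips exactly: [contingency_3x3()] of the result
#' reproduces `counts`.
#'
#' @param counts Non-negative 3x3 integer matrix (AlphaMissense rows x
#'   collapsed curated columns, both in the [table2a_counts()] order).
#' @param seed Integer seed for the score draws.
#' @return A cohort tibble (`variant_id`, `gene`, `curated_tier`, `evidence`,
#'   `am_score`, `am_category`, `revel_score`).
#' @examples
#' cohort <- fixture_from_contingency(table2a_counts())
#' nrow(cohort)
#' @export
fixture_from_contingency <- function(counts, seed = 1L) {
  if (!is.matrix(counts) || !all(dim(counts) == c(3, 3)) || any(counts < 0)) {
    stop("`counts` must be a non-negative 3x3 matrix")
  }
  am_rows <- c("pathogenic", "ambiguous", "benign")
  intervals <- list(pathogenic = c(0.565, 1),
                    ambiguous = c(0.34, 0.564),
                    benign = c(0, 0.33))
  tier_cols <- list(pathogenic = c("pathogenic", "likely_pathogenic"),
                    vus = "vus",
                    benign = c("benign", "likely_benign"))
  .with_seed(seed, {
    pieces <- list()
    k <- 0L
    for (i in 1:3) {
      for (j in 1:3) {
        n <- counts[i, j]
        if (n == 0) next
        k <- k + 1L
        rng <- intervals[[am_rows[i]]]
        tiers <- tier_cols[[j]]
        pieces[[k]] <- tibble::tibble(
          curated_tier = rep_len(tiers, n),
          am_score = stats::runif(n, rng[1], rng[2]))
      }
    }
    out <- if (length(pieces) == 0) {
      tibble::tibble(curated_tier = character(), am_score = numeric())
    } else {
      dplyr::bind_rows(pieces)
    }
    n_total <- nrow(out)
    tibble::tibble(
      variant_id = sprintf("CT-%05d", seq_len(n_total)),
      gene = NA_character_,
      curated_tier = out$curated_tier,
      evidence = "",
      am_score = out$am_score,
      am_category = am_category(out$am_score),
      revel_score = NA_real_)
  })
}

#' @rdname fixture_from_contingency
#' @export
fixture_table2a <- function(seed = 1L) {
  fixture_from_contingency(table2a_counts(), seed = seed)
}

#' Published VUS evidence-combination tables
#'
#' `table5_rows()` returns the 20 evidence-combination groups of the curated
#' 4085-VUS cohort before computational augmentation: group size, strength
#' profile (PS/PM/PP/BP/BS counts), the quantified points total, and the
#' number of group members that received an AlphaMissense benign (`n_benign`)
#' or pathogenic (`n_pathogenic`) addition in the augmentation experiment.
#' `table6_rows()` returns the 26 post-replacement profile groups with their
#' quantified totals.
#'
#' @return A tibble, one row per printed combination group.
#' @examples
#' sum(table5_rows()$n)   # 4085
#' sum(table6_rows()$n)   # 4085
#' @export
table5_rows <- function() {
  tibble::tibble(
    n    = c(24L, 16L, 19L, 35L, 4L, 406L, 23L, 546L, 203L, 1111L,
             4L, 29L, 71L, 775L, 2L, 164L, 40L, 1L, 450L, 162L),
    PS   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
             0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
    PM   = c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L,
             0L, 1L, 2L, 1L, 1L, 2L, 2L, 0L, 2L, 1L),
    PP   = c(0L, 0L, 1L, 1L, 2L, 0L, 2L, 0L, 1L, 1L,
             3L, 2L, 0L, 2L, 3L, 0L, 1L, 1L, 1L, 3L),
    BP   = c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L,
             0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L),
    BS   = 0L,
    quantification = c(-1L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L,
                       3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L, 5L, 5L),
    n_benign     = c(0L, 12L, 0L, 9L, 0L, 4L, 1L, 150L, 0L, 0L,
                     0L, 0L, 1L, 6L, 0L, 40L, 0L, 0L, 16L, 0L),
    n_pathogenic = c(0L, 1L, 0L, 0L, 0L, 2L, 0L, 318L, 0L, 191L,
                     0L, 0L, 2L, 11L, 0L, 114L, 0L, 0L, 54L, 2L))
}

#' @rdname table5_rows
#' @export
table6_rows <- function() {
  tibble::tibble(
    n  = c(49L, 1L, 12L, 38L, 9L, 9L, 6L, 617L, 1L, 8L, 303L, 186L, 5L,
           2L, 1083L, 36L, 133L, 842L, 2L, 44L, 42L, 1L, 153L, 440L,
           2L, 61L),
    PS = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
           0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    PM = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 2L,
           0L, 1L, 1L, 2L, 1L, 1L, 2L, 2L, 0L, 1L, 2L, 1L, 2L),
    PP = c(0L, 1L, 0L, 1L, 0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L, 0L,
           3L, 1L, 2L, 0L, 2L, 3L, 0L, 1L, 1L, 3L, 1L, 4L, 2L),
    BP = c(1L, 2L, 0L, 1L, 2L, 0L, 1L, 1L, 2L, 0L, 1L, 0L, 2L,
           0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L),
    BS = 0L,
    quantification = c(-1L, -1L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L,
                       3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L, 5L, 5L, 6L, 6L))
}

# Realize a strength profile as concrete evidence codes. One canonical
# non-computational code per (polarity, strength): PS -> PS4, PM -> PM2,
# PP -> PP1, BP -> BP1, BS -> BS1. When `computational = TRUE`, one PP item is
# realized as PP3 (or, failing that, one BP as BP4) so that the variant counts
# as computational-evidence-bearing; eligibility for augmentation depends only
# on computational-type presence, not on which code realizes it.
.realize_profile <- function(ps = 0, pm = 0, pp = 0, bp = 0, bs = 0,
                             computational = FALSE) {
  codes <- c(rep("PS4", ps), rep("PM2", pm), rep("PP1", pp),
             rep("BP1", bp), rep("BS1", bs))
  if (computational) {
    if (pp > 0) {
      codes[match("PP1", codes)] <- "PP3"
    } else if (bp > 0) {
      codes[match("BP1", codes)] <- "BP4"
    } else {
      stop("profile has no supporting item to realize as computational")
    }
  }
  paste(codes, collapse = ";")
}

#' Deterministic VUS cohort fixture for the augmentation experiment
#'
#' Expands the 20 printed evidence-combination groups ([table5_rows()]) into a
#' per-variant cohort of 4085 curated VUS. Within each group, exactly the
#' printed numbers of members receive AlphaMissense benign (score 0.20) or
#' pathogenic (score 0.90) predictions. The remainder of each group is either
#' ineligible for augmentation — realized with one PP3/BP4 item when the
#' profile contains a supporting item, marking existing computational
#' evidence — or, for profiles with no supporting item to realize, eligible
#' but AlphaMissense-ambiguous (score 0.45, inert). Which specific variants
#' constitute each group is unknowable from the published summary; the fixture
#' reproduces counts, not identities.
#'
#' @return A cohort tibble of 4085 records with a `fixture_row` column linking
#'   each record to its source combination group.
#' @examples
#' cohort <- fixture_vus_table5()
#' nrow(cohort)
#' @export
fixture_vus_table5 <- function() {
  rows <- table5_rows()
  pieces <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    n_add <- r$n_benign + r$n_pathogenic
    n_rest <- r$n - n_add
    has_supporting <- r$PP > 0 || r$BP > 0
    plain <- .realize_profile(r$PS, r$PM, r$PP, r$BP, r$BS,
                              computational = FALSE)
    rest_evidence <- if (has_supporting) {
      .realize_profile(r$PS, r$PM, r$PP, r$BP, r$BS, computational = TRUE)
    } else {
      plain
    }
    evidence <- c(rep(plain, n_add), rep(rest_evidence, n_rest))
    score <- c(rep(0.20, r$n_benign), rep(0.90, r$n_pathogenic),
               rep(0.45, n_rest))
    pieces[[i]] <- tibble::tibble(
      fixture_row = i,
      evidence = evidence,
      am_score = score)
  }
  out <- dplyr::bind_rows(pieces)
  tibble::tibble(
    variant_id = sprintf("T5-%04d", seq_len(nrow(out))),
    gene = NA_character_,
    curated_tier = "vus",
    evidence = out$evidence,
    am_score = out$am_score,
    am_category = am_category(out$am_score),
    revel_score = NA_real_,
    fixture_row = out$fixture_row)
}

#' Deterministic post-replacement VUS cohort fixture
#'
#' Expands the 26 printed post-replacement profile groups ([table6_rows()])
#' into a per-variant cohort of 4085 curated VUS, used to verify
#' quantification and classification of replacement outcomes.
#'
#' @return A cohort tibble of 4085 records with a `fixture_row` column.
#' @examples
#' cohort <- fixture_vus_table6()
#' nrow(cohort)
#' @export
fixture_vus_table6 <- function() {
  rows <- table6_rows()
  evidence <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    evidence[i] <- .realize_profile(r$PS, r$PM, r$PP, r$BP, r$BS)
  }
  idx <- rep(seq_len(nrow(rows)), rows$n)
  tibble::tibble(
    variant_id = sprintf("T6-%04d", seq_along(idx)),
    gene = NA_character_,
    curated_tier = "vus",
    evidence = evidence[idx],
    am_score = NA_real_,
    am_category = NA_character_,
    revel_score = NA_real_,
    fixture_row = idx)
}
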