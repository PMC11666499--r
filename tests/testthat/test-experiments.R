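# Augmentation and replacement experiments, transition accounting.

test_that("computational-evidence detection keys on the evidence type", {
  expect_identical(
    has_computational_evidence(c("PM2;PP3", "PM2;PP1", "", "BP4", "PM2;BP4")),
    c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("augmentation modifies only computational-evidence-free VUS", {
  cohort <- make_cohort(
    variant_id = paste0("v", 1:5),
    curated_tier = c("vus", "vus", "vus", "pathogenic", "vus"),
    evidence = c("", "PM2;PM2;PP1", "PM2;PP3", "PVS1;PS3", ""),
    am_score = c(0.20, 0.90, 0.90, 0.90, 0.45))
  out <- run_augmentation(cohort)
  pv <- out$per_variant
  # empty-evidence VUS with benign AM: 0 -> -1, vus -> likely_benign
  expect_identical(pv$points_before[1], 0L)
  expect_identical(pv$points_after[1], -1L)
  expect_identical(pv$tier_after[1], "likely_benign")
  # PM=2 PP=1 profile with pathogenic AM: 5 -> 6, vus -> likely_pathogenic
  expect_identical(pv$points_before[2], 5L)
  expect_identical(pv$points_after[2], 6L)
  expect_identical(pv$tier_after[2], "likely_pathogenic")
  # VUS with PP3 already assigned: untouched regardless of AM
  expect_false(pv$modified[3])
  expect_identical(pv$points_after[3], pv$points_before[3])
  # non-VUS: untouched
  expect_false(pv$modified[4])
  # ambiguous AM: eligible but inert
  expect_false(pv$modified[5])
  expect_identical(pv$points_after[5], 0L)
  expect_identical(out$n_modified, 2L)
  expect_identical(out$n_points_changed, 2L)
  # augmentation appends the AM code to the evidence field
  expect_identical(out$cohort_after$evidence[1], "BP4")
  expect_identical(out$cohort_after$evidence[2], "PM2;PM2;PP1;PP3")
})

test_that("augmentation point deltas are confined to one supporting item", {
  cohort <- simulate_cohort(cohort_spec(n_variants = 800), seed = 11)
  out <- run_augmentation(cohort)
  delta <- out$per_variant$points_after - out$per_variant$points_before
  expect_true(all(delta %in% c(-1L, 0L, 1L)))
  # untouched rows show zero delta
  expect_true(all(delta[!out$per_variant$modified] == 0L))
  expect_identical(out$n_points_changed, sum(delta != 0L))
})

test_that("augmentation rejects eligible variants without an AM category", {
  cohort <- make_cohort(c("ok", "bad"), evidence = c("", ""),
                        am_score = c(0.9, NA))
  expect_error(run_augmentation(cohort), "bad")
})

test_that("replacement swaps computational evidence for the AM item", {
  cohort <- make_cohort(
    variant_id = paste0("v", 1:4),
    curated_tier = "vus",
    evidence = c("PM2;PM2;PP1;PP3", "BP4", "PM2;PP1", ""),
    am_score = c(0.90, 0.20, 0.90, 0.45))
  out <- run_replacement(cohort, scope = "vus")
  pv <- out$per_variant
  # PM=2 PP=2 (one PP3), AM pathogenic: profile preserved, 6 points, LP
  expect_identical(pv$points_before[1], 6L)
  expect_identical(pv$points_after[1], 6L)
  expect_identical(out$cohort_after$evidence[1], "PM2;PM2;PP1;PP3")
  # single BP4, AM benign: -1 stays -1
  expect_identical(pv$points_after[2], -1L)
  expect_identical(out$cohort_after$evidence[2], "BP4")
  # no computational evidence: AM item is added
  expect_identical(pv$points_before[3], 3L)
  expect_identical(pv$points_after[3], 4L)
  expect_identical(out$cohort_after$evidence[3], "PM2;PP1;PP3")
  # ambiguous AM, nothing removed, nothing added
  expect_identical(pv$points_after[4], 0L)
  expect_identical(out$cohort_after$evidence[4], "")
})

test_that("replacement removes all computational items of both polarities", {
  cohort <- make_cohort("v1", evidence = "PP3;PP3;BP4;PM2", am_score = 0.20)
  out <- run_replacement(cohort)
  expect_identical(out$cohort_after$evidence, "PM2;BP4")
  expect_identical(out$per_variant$points_before, 3L)  # 1+1-1+2
  expect_identical(out$per_variant$points_after, 1L)   # 2-1
})

test_that("replacement is idempotent", {
  cohort <- simulate_cohort(cohort_spec(n_variants = 600), seed = 5)
  once <- run_replacement(cohort, scope = "vus")
  twice <- run_replacement(once$cohort_after, scope = "vus")
  expect_identical(twice$per_variant$points_before,
                   once$per_variant$points_after)
  expect_identical(twice$per_variant$points_after,
                   once$per_variant$points_after)
  expect_identical(twice$cohort_after$evidence, once$cohort_after$evidence)
})

test_that("replacement scope extends to the full cohort", {
  cohort <- make_cohort(
    variant_id = c("p", "v"),
    curated_tier = c("pathogenic", "vus"),
    evidence = c("PVS1;PP3", "PM2;PP3"),
    am_score = c(0.20, 0.20))
  vus_only <- run_replacement(cohort, scope = "vus")
  expect_identical(vus_only$per_variant$points_after, c(9L, 1L))
  all_scope <- run_replacement(cohort, scope = "all")
  expect_identical(all_scope$per_variant$points_after, c(7L, 1L))
})

test_that("transition matrices conserve cohort counts", {
  before <- c("vus", "vus", "benign", "pathogenic")
  after <- c("likely_pathogenic", "vus", "benign", "pathogenic")
  tr <- transition_matrix(before, after)
  expect_identical(sum(tr$counts), 4L)
  expect_identical(tr$n_changed, 1L)
  expect_identical(unname(tr$counts["vus", "likely_pathogenic"]), 1L)
  expect_equal(rowSums(tr$counts)[["vus"]], 2)
  # identical vectors: purely diagonal
  tr0 <- transition_matrix(before, before)
  expect_identical(tr0$n_changed, 0L)
  expect_identical(sum(diag(tr0$counts)), 4L)
  expect_error(transition_matrix(before, after[-1]), "same length")
  expect_error(transition_matrix("vus", "nonsense"), "invalid tier")
})

test_that("experiment outcomes satisfy the conservation laws", {
  cohort <- simulate_cohort(cohort_spec(n_variants = 500), seed = 3)
  for (out in list(run_augmentation(cohort),
                   run_replacement(cohort, scope = "all"))) {
    n <- nrow(out$per_variant)
    expect_identical(sum(out$transition_counts), n)
    expect_identical(sum(diag(out$transition_counts)) + out$n_tier_changed, n)
    expect_identical(out$n_points_changed,
                     sum(out$per_variant$points_after !=
                         out$per_variant$points_before))
    # bands present iff the quantified tier is VUS
    expect_identical(is.na(out$per_variant$band_after),
                     out$per_variant$tier_after != "vus")
  }
})
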