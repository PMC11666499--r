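# Fixtures expanding the published tables, and the stochastic generator.

test_that("contingency fixtures round-trip arbitrary tables", {
  set.seed(42)
  for (i in 1:5) {
    counts <- matrix(sample(0:40, 9, replace = TRUE), 3, 3,
                     dimnames = dimnames(table2a_counts()))
    cohort <- fixture_from_contingency(counts, seed = i)
    expect_identical(contingency_3x3(cohort), counts)
  }
  # single-cell table
  one <- matrix(0L, 3, 3, dimnames = dimnames(table2a_counts()))
  one["pathogenic", "pathogenic"] <- 1L
  cohort <- fixture_from_contingency(one)
  expect_identical(nrow(cohort), 1L)
  expect_identical(cohort$am_category, "pathogenic")
})

test_that("contingency fixtures are deterministic given the seed", {
  a <- fixture_from_contingency(table2a_counts(), seed = 9)
  b <- fixture_from_contingency(table2a_counts(), seed = 9)
  expect_identical(a, b)
  c <- fixture_from_contingency(table2a_counts(), seed = 10)
  expect_false(identical(a$am_score, c$am_score))
})

test_that("the full-cohort fixture reproduces the published margins", {
  cohort <- fixture_table2a()
  expect_identical(nrow(cohort), 5845L)
  collapsed <- collapse_tier(cohort$curated_tier)
  expect_identical(as.vector(table(collapsed)[c("pathogenic", "benign",
                                                "vus")]),
                   c(1576L, 184L, 4085L))
})

test_that("the pre-augmentation VUS fixture matches its printed accounting", {
  cohort <- fixture_vus_table5()
  expect_identical(nrow(cohort), 4085L)
  expect_true(all(cohort$curated_tier == "vus"))
  # per-row profile quantification matches the printed totals
  q <- cohort_quantify(cohort)
  rows <- table5_rows()
  for (i in seq_len(nrow(rows))) {
    expect_identical(unique(q$points[cohort$fixture_row == i]),
                     rows$quantification[i])
  }
  # AM category counts among augmentation-eligible variants match the
  # printed addition numbers
  eligible <- !q$has_computational
  expect_identical(sum(cohort$am_category == "pathogenic" & eligible), 695L)
  expect_identical(sum(cohort$am_category == "benign" & eligible),
                   sum(rows$n_benign))
})

test_that("the post-replacement fixture matches its printed quantifications", {
  cohort <- fixture_vus_table6()
  expect_identical(nrow(cohort), 4085L)
  q <- cohort_quantify(cohort)
  rows <- table6_rows()
  for (i in seq_len(nrow(rows))) {
    expect_identical(unique(q$points[cohort$fixture_row == i]),
                     rows$quantification[i])
  }
})

test_that("simulated cohorts are pure functions of spec and seed", {
  spec <- cohort_spec(n_variants = 300)
  a <- simulate_cohort(spec, seed = 77)
  b <- simulate_cohort(spec, seed = 77)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(spec, seed = 78)))
  expect_identical(nrow(simulate_cohort(cohort_spec(n_variants = 0))), 0L)
})

test_that("simulated tier counts track the published proportions", {
  cohort <- simulate_cohort(cohort_spec(), seed = 101)
  n <- nrow(cohort)
  counts <- table(collapse_tier(cohort$curated_tier))
  expected <- c(pathogenic = 1576, benign = 184, vus = 4085)
  for (g in names(expected)) {
    p <- expected[[g]] / 5845
    sigma <- sqrt(n * p * (1 - p))
    expect_lt(abs(counts[[g]] - n * p), 3 * sigma)
  }
})

test_that("simulated AM scores recover the configured mixture means", {
  spec <- cohort_spec()
  cohort <- simulate_cohort(spec, seed = 202)
  collapsed <- collapse_tier(cohort$curated_tier)
  mixture_mean <- function(mix) sum(mix$weight * mix$mean)
  for (g in c("benign", "vus", "pathogenic")) {
    s <- cohort$am_score[collapsed == g]
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - mixture_mean(spec$am_mixture[[g]])), 3 * se)
  }
  # VUS scores are bimodal: both flanks heavier than the middle
  vus <- cohort$am_score[collapsed == "vus"]
  expect_gt(mean(vus < 0.34), mean(vus >= 0.4 & vus < 0.6))
  expect_gt(mean(vus > 0.6), mean(vus >= 0.4 & vus < 0.6))
})

test_that("simulated evidence quantifies consistently with curated tiers", {
  cohort <- simulate_cohort(cohort_spec(n_variants = 1000), seed = 303)
  q <- cohort_quantify(cohort)
  # non-VUS tiers use point-consistent templates
  non_vus <- cohort$curated_tier != "vus"
  expect_identical(q$tier[non_vus], cohort$curated_tier[non_vus])
  # AM scores and REVEL companions are rank-correlated
  expect_gt(spearman_rho(cohort$am_score, cohort$revel_score), 0.6)
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(tier_proportions = c(vus = 1)), "five tiers")
  bad <- c(benign = 0.5, likely_benign = 0.5, vus = 0.5,
           likely_pathogenic = 0, pathogenic = 0)
  expect_error(cohort_spec(tier_proportions = bad), "sum to 1")
  mix <- default_am_mixture()
  mix$vus$weight <- c(0.5, 0.2)
  expect_error(cohort_spec(am_mixture = mix), "sum to 1")
})
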