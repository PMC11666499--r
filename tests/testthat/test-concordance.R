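# Contingency tables, binary collapse schemes, comparison groups, and
# auxiliary statistics.

test_that("the contingency table tallies collapsed tiers against categories", {
  cohort <- make_cohort(
    variant_id = paste0("v", 1:5),
    curated_tier = c("pathogenic", "likely_pathogenic", "vus", "benign",
                     "likely_benign"),
    am_score = c(0.9, 0.1, 0.45, 0.9, 0.1))
  tab <- contingency_3x3(cohort)
  expect_identical(sum(tab), 5L)
  expect_identical(unname(tab["pathogenic", "pathogenic"]), 1L)
  expect_identical(unname(tab["benign", "pathogenic"]), 1L)  # P/LP collapsed
  expect_identical(unname(tab["ambiguous", "vus"]), 1L)
  expect_identical(unname(tab["pathogenic", "benign"]), 1L)
  expect_identical(unname(tab["benign", "benign"]), 1L)
  # empty cohort: all-zero table
  expect_identical(sum(contingency_3x3(make_cohort(character(0)))), 0L)
  # missing categories are rejected with the offending id
  expect_error(contingency_3x3(make_cohort("naked")), "naked")
})

test_that("diagonal-only tables give perfect metrics in both schemes", {
  tab <- diag(c(10L, 5L, 8L))
  dimnames(tab) <- dimnames(table2a_counts())
  mA <- metrics_excluding_uncertain(tab)
  expect_equal(mA$sensitivity, 1)
  expect_equal(mA$specificity, 1)
  expect_equal(unname(mA$percent), c(100, 100, 100, 100))
  mB <- metrics_path_vs_rest(tab)
  expect_equal(mB$sensitivity, 1)
  expect_equal(mB$ppv, 1)
})

test_that("zero denominators yield absent metrics, not 0 or 100", {
  tab <- matrix(0L, 3, 3, dimnames = dimnames(table2a_counts()))
  tab["ambiguous", "vus"] <- 5L
  mA <- metrics_excluding_uncertain(tab)
  expect_true(is.na(mA$sensitivity))
  expect_true(is.na(mA$percent[["npv"]]))
  # empty pathogenic row in scheme B: sensitivity defined by column,
  # ppv absent
  tabB <- matrix(0L, 3, 3, dimnames = dimnames(table2a_counts()))
  tabB["benign", "benign"] <- 3L
  mB <- metrics_path_vs_rest(tabB)
  expect_true(is.na(mB$sensitivity))
  expect_true(is.na(mB$ppv))
})

test_that("metric fractions are invariant to uniform scaling of the table", {
  tab <- table2a_counts()
  m1 <- metrics_excluding_uncertain(tab)
  m2 <- metrics_excluding_uncertain(tab * 7L)
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
  expect_equal(m1$ppv, m2$ppv)
  expect_equal(m1$npv, m2$npv)
})

test_that("comparison groups cover the 3x3 label grid", {
  expect_identical(as.character(comparison_group("vus", "ambiguous")),
                   "VUS-amb")
  expect_identical(as.character(comparison_group("pathogenic", "benign")),
                   "PATH-ben")
  expect_identical(as.character(comparison_group("likely_benign", "benign")),
                   "BEN-ben")
  expect_identical(as.character(comparison_group("likely_pathogenic",
                                                 "ambiguous")),
                   "PATH-amb")
  # group counts match the contingency table cell-by-cell
  cohort <- fixture_table2a()
  tab <- contingency_3x3(cohort)
  groups <- table(comparison_group(cohort$curated_tier, cohort$am_category))
  expect_identical(unname(groups[["PATH-path"]]),
                   unname(tab["pathogenic", "pathogenic"]))
  expect_identical(unname(groups[["VUS-ben"]]),
                   unname(tab["benign", "vus"]))
  expect_identical(unname(groups[["BEN-amb"]]),
                   unname(tab["ambiguous", "benign"]))
  expect_identical(sum(groups), sum(tab))
})

test_that("chi-square matches the closed-form Pearson statistic", {
  # independence: outer-product table gives statistic 0, p 1
  ind <- outer(c(10, 20, 30), c(5, 10, 15)) / 60
  res <- chi_square_independence(ind)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # hand-computed 2x2: expecteds all 5, statistic 4 * 25/5 = 20
  res2 <- chi_square_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res2$statistic, 20)
  expect_identical(res2$df, 1L)
  expect_error(chi_square_independence(matrix(c(1, 1, 0, 0), 2)),
               "marginals")
})

test_that("rank correlation handles ties, reversal, and constants", {
  expect_equal(spearman_rho(1:5, 2:6), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # brute-force rank computation: d = (0,1,-1,0), rho = 1 - 6*2/60 = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(1:4, 1:3), "same length")
  expect_error(spearman_rho(c(1, 2), c(3, 4)), "at least 3")
  expect_warning(rho <- spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(rho))
})

test_that("mean confidence intervals follow the t distribution", {
  expect_equal(mean_ci(rep(0.5, 4)), c(mean = 0.5, lower = 0.5, upper = 0.5))
  ci <- mean_ci(c(0, 1))
  expect_equal(unname(ci["mean"]), 0.5)
  expect_equal(unname(ci["upper"] - ci["mean"]),
               unname(ci["mean"] - ci["lower"]))
  # closed-form t interval: mean 3, SE sqrt(2.5/5), t(0.975, 4)
  ci5 <- mean_ci(c(1, 2, 3, 4, 5))
  se <- sqrt(2.5 / 5)
  expect_equal(unname(ci5["mean"]), 3)
  expect_equal(unname(ci5["lower"]), 3 - qt(0.975, 4) * se)
  expect_equal(unname(ci5["upper"]), 3 + qt(0.975, 4) * se)
  expect_error(mean_ci(1), "at least 2")
})

test_that("the cohort-level summary assembles all components", {
  rep <- concordance_summary(fixture_table2a())
  expect_s3_class(rep, "am_concordance")
  expect_identical(rep$n, 5845L)
  expect_identical(rep$concordant, 1887L)
  expect_equal(unname(rep$am_marginals), c(3848, 525, 1472))
  expect_equal(unname(rep$acmg_marginals), c(1576, 4085, 184))
  expect_lt(rep$chi_square$p_value, 0.01)
  expect_identical(rep$chi_square$df, 4L)
})
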