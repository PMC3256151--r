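printed_tables <- list(
  # above / not-above counts for cases (a, b) and controls (c, d)
  whole_maxr = c(57, 369, 33, 440),
  whole_maxl = c(58, 368, 32, 441),
  men_maxr = c(15, 157, 7, 194),
  women_maxl = c(43, 211, 25, 247),
  fem_no_oc_maxl = c(6, 34, 1, 89),
  fem_no_oc_maxr = c(6, 34, 0, 90),
  age_le45_maxr = c(31, 178, 17, 206),
  bmi_le26_maxl = c(18, 181, 10, 254)
)

test_that("Woolf odds ratios reproduce the published contingency tables", {
  or1 <- function(x) round(do.call(odds_ratio_ci, as.list(x))$or, 1)
  expect_equal(or1(printed_tables$whole_maxr), 2.1)
  expect_equal(or1(printed_tables$whole_maxl), 2.2)
  expect_equal(or1(printed_tables$men_maxr), 2.6)
  expect_equal(or1(printed_tables$women_maxl), 2.0)
  expect_equal(or1(printed_tables$fem_no_oc_maxl), 15.7)
  expect_equal(or1(printed_tables$age_le45_maxr), 2.1)
  expect_equal(or1(printed_tables$bmi_le26_maxl), 2.5)

  ci <- do.call(odds_ratio_ci, as.list(printed_tables$whole_maxr))
  expect_equal(round(ci$ci_low, 1), 1.3)
  expect_equal(round(ci$ci_high, 1), 3.2)
  ci <- do.call(odds_ratio_ci, as.list(printed_tables$fem_no_oc_maxl))
  expect_equal(round(ci$ci_low, 1), 1.8)
  expect_equal(round(ci$ci_high), 135)
})

test_that("a zero cell yields an undefined odds ratio, not an error", {
  res <- do.call(odds_ratio_ci, as.list(printed_tables$fem_no_oc_maxr))
  expect_true(is.na(res$or))
  expect_equal(odds_ratio_ci(5, 5, 5, 5)$or, 1)
})

test_that("odds ratio is invariant under joint swap and inverts on row swap", {
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(1:50, 4)
    or <- odds_ratio_ci(x[1], x[2], x[3], x[4])$or
    expect_equal(odds_ratio_ci(x[3], x[4], x[1], x[2])$or, 1 / or)
    expect_equal(odds_ratio_ci(x[2], x[1], x[4], x[3])$or, 1 / or)
    expect_equal(odds_ratio_ci(x[4], x[3], x[2], x[1])$or, or)
  }
})

test_that("Fisher's exact p matches the published tables and enumeration", {
  expect_equal(do.call(fisher_exact, as.list(printed_tables$whole_maxr)),
               0.0017, tolerance = 0.03)
  expect_equal(do.call(fisher_exact, as.list(printed_tables$whole_maxl)),
               0.0008, tolerance = 0.05)
  expect_equal(fisher_exact(10, 90, 10, 90), 1)
  # independent oracle: full hypergeometric enumeration for a tiny table
  # margins 3/3, total 6, 3 above: tables with a = 0..3
  probs <- dhyper(0:3, 3, 3, 3)
  p_manual <- sum(probs[probs <= dhyper(3, 3, 3, 3) * (1 + 1e-7)])
  expect_equal(fisher_exact(3, 0, 0, 3), p_manual)
  expect_equal(fisher_exact(3, 0, 0, 3), 0.1)
})

test_that("Fisher p is symmetric under table transposition", {
  set.seed(32)
  for (rep in 1:10) {
    x <- sample(0:30, 4)
    expect_equal(fisher_exact(x[1], x[2], x[3], x[4]),
                 fisher_exact(x[1], x[3], x[2], x[4]))
  }
})

test_that("nearest-rank percentile with strict 'above'", {
  expect_equal(percentile_cutoff(1:100, 90), 90)
  expect_equal(sum(1:100 > percentile_cutoff(1:100, 90)), 10)
  expect_equal(sum(rep(7, 50) > percentile_cutoff(rep(7, 50), 90)), 0)
  set.seed(33)
  v <- rnorm(899)
  expect_equal(sum(v > percentile_cutoff(v, 90)), 89)
  expect_error(percentile_cutoff(1:5, 90), "too_few_values")
})

test_that("prevalence counts partition across disjoint subgroups", {
  set.seed(34)
  n <- 200
  metrics <- data.frame(
    subject_id = as.character(1:n),
    group = rep(c("case", "control"), each = n / 2),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = runif(n, 20, 70), bmi = runif(n, 18, 35),
    oc_use = FALSE,
    MaxR = c(rnorm(n / 2, 9, 3), rnorm(n / 2, 8, 3)))
  cut <- percentile_cutoff(metrics$MaxR, 90)
  whole <- prevalence_table(metrics, "MaxR", cut)
  men <- prevalence_table(metrics, "MaxR", cut, metrics$sex == "M", "men")
  women <- prevalence_table(metrics, "MaxR", cut, metrics$sex == "F", "women")
  expect_equal(men$a + women$a, whole$a)
  expect_equal(men$c + women$c, whole$c)
  expect_equal(whole$a + whole$b, sum(metrics$group == "case"))
  expect_equal(whole$a + whole$c, sum(metrics$MaxR > cut))
})

test_that("degenerate subgroups are rejected", {
  metrics <- data.frame(subject_id = "1", group = "case", sex = "M",
                        age = 30, bmi = 22, oc_use = FALSE, MaxR = 5)
  expect_error(prevalence_table(metrics, "MaxR", 1), "empty_subgroup")
  expect_error(prevalence_table(metrics, "MaxR", 1,
                                subset = metrics$sex == "F", "none"),
               "empty_subgroup")
})

test_that("cutoff above the subgroup maximum empties the 'above' cells", {
  metrics <- data.frame(
    subject_id = as.character(1:20),
    group = rep(c("case", "control"), 10),
    sex = "M", age = 30, bmi = 22, oc_use = FALSE,
    MaxR = runif(20, 1, 2))
  ct <- prevalence_table(metrics, "MaxR", 99)
  expect_equal(ct$a, 0)
  expect_equal(ct$c, 0)
  expect_true(is.na(ct$or))
})

test_that("group comparison picks the t-test for normal samples", {
  set.seed(35)
  a <- rnorm(200, 0, 1)
  b <- rnorm(200, 1, 1)
  res <- group_compare(a, b)
  expect_equal(res$test, "t")
  expect_lt(res$p, 0.001)
  expect_true(res$diff_ci[1] <= -1 + 0.35 && res$diff_ci[2] >= -1 - 0.35)
  expect_true(res$diff_ci[1] < -1 && res$diff_ci[2] > -1)
})

test_that("group comparison falls back to rank-sum for skewed samples", {
  set.seed(36)
  a <- rexp(200)^2
  b <- rexp(200)^2 + 0.1
  res <- group_compare(a, b)
  expect_equal(res$test, "wilcoxon")
  expect_null(res$diff_ci)
})

test_that("identical samples give a difference CI centered at zero", {
  set.seed(37)
  a <- rnorm(50, 5, 1)
  res <- group_compare(a, a)
  expect_equal(mean(res$diff_ci), 0, tolerance = 1e-12)
  expect_error(group_compare(1:2, 1:10), "too_few_values")
})

test_that("linear trend recovers exact and noisy slopes", {
  x <- seq(1, 50)
  exact <- suppressWarnings(linear_trend(0.2 * x, x))  # perfect fit
  expect_equal(exact$slope, 0.2)
  expect_equal(diff(exact$ci), 0, tolerance = 1e-10)

  const <- suppressWarnings(linear_trend(rep(3, 20), 1:20))
  expect_equal(const$slope, 0)

  set.seed(38)
  bmi <- runif(450, 18, 35)
  y <- 0.138 * bmi + rnorm(450, 0, 0.5)
  fit <- linear_trend(y, bmi)
  expect_true(fit$ci[1] <= 0.138 && 0.138 <= fit$ci[2])
  expect_error(linear_trend(rnorm(20), rep(1, 20)), "zero_variance")
})

test_that("run_cohort handles tiny, empty and duplicated cohorts", {
  fx <- fixture_compositions()
  cohort <- data.frame(
    subject_id = c("individual_1", "individual_2"),
    group = "control", sex = "F", age = 40, bmi = 24, oc_use = FALSE,
    t(sapply(fx[c("individual_1", "individual_2")],
             function(c) c$levels)))
  met <- run_cohort(cohort)
  expect_equal(nrow(met), 2)
  # the two printed individuals are distinguished by their fXa output
  expect_gt(abs(diff(met$MaxL)), 0)

  empty <- run_cohort(cohort[0, ])
  expect_equal(nrow(empty), 0)

  dup <- suppressWarnings(run_cohort(rbind(cohort[1, ], cohort[1, ])))
  expect_equal(dup$MaxR[1], dup$MaxR[2])
  expect_equal(dup$AUC[1], dup$AUC[2])
})

test_that("strict mode names invalid subjects, lenient mode drops them", {
  cohort <- data.frame(
    subject_id = c("ok", "bad"), group = "control",
    sex = "F", age = 40, bmi = 24, oc_use = FALSE,
    fII = c(100, -10), fV = 100, fVII = 100, fVIII = 100,
    fIX = 100, fX = 100, AT = 100, TFPI = 100)
  expect_error(run_cohort(cohort), "invalid_subjects")
  met <- suppressWarnings(run_cohort(cohort, mode = "lenient"))
  expect_equal(nrow(met), 1)
  expect_equal(attr(met, "n_failed"), 1L)
})
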