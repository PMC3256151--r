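test_that("sampled factor levels respect the published moments and ranges", {
  spec <- cohort_spec()
  ctrl <- sample_cohort(spec, "control", seed = 7L)
  expect_equal(nrow(ctrl), 473)
  # sample mean of fII within 3 standard errors of the printed 104 (15)
  expect_lt(abs(mean(ctrl$fII) - 104), 3 * 15 / sqrt(473))
  for (f in names(spec$factors$control)) {
    p <- spec$factors$control[[f]]
    expect_true(all(ctrl[[f]] >= p$min & ctrl[[f]] <= p$max))
  }
})

test_that("sampling is deterministic under a seed", {
  a <- sample_case_control_study(seed = 42L)
  b <- sample_case_control_study(seed = 42L)
  expect_identical(a, b)
  c <- sample_case_control_study(seed = 43L)
  expect_false(identical(a$fII, c$fII))
})

test_that("default study has 473 controls and 426 cases", {
  coh <- sample_case_control_study(seed = 1L)
  expect_equal(nrow(coh), 899)
  expect_equal(sum(coh$group == "case"), 426)
  expect_equal(sum(coh$group == "control"), 473)
  expect_true(all(coh$sex %in% c("M", "F")))
  expect_true(all(coh$age >= 15 & coh$age <= 72))
  # OC use restricted to premenopausal women
  expect_true(all(coh$sex[coh$oc_use] == "F"))
  expect_true(all(coh$age[coh$oc_use] <= 49))
})

test_that("sample moments converge to the spec moments at large n", {
  spec <- cohort_spec()
  big <- sample_factor_levels(10000, spec$factors$control)
  for (f in c("fII", "fVIII", "TFPI")) {
    p <- spec$factors$control[[f]]
    # truncation pulls moments slightly toward the window; 3 SE of the
    # untruncated SD is the agreed bound at the printed (mild) truncations
    expect_lt(abs(mean(big[[f]]) - p$mean), 3 * p$sd / sqrt(10000) + 0.5)
  }
})

test_that("subgroup mean overrides shift only the targeted factors", {
  spec <- cohort_spec()
  set.seed(9)
  oc <- sample_factor_levels(5000, spec$factors$control,
                             mean_overrides = c(TFPI = 68, fIX = 115))
  # analytic truncated-normal mean as the oracle (truncation at the group
  # range biases the mean when the window is asymmetric about it)
  tn_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  p <- spec$factors$control$TFPI
  expect_lt(abs(mean(oc$TFPI) - tn_mean(68, p$sd, p$min, p$max)), 1.5)
  p <- spec$factors$control$fIX
  expect_lt(abs(mean(oc$fIX) - tn_mean(115, p$sd, p$min, p$max)), 1.5)
  p <- spec$factors$control$fII
  expect_lt(abs(mean(oc$fII) - tn_mean(104, p$sd, p$min, p$max)), 1.5)
})

test_that("correlated sampling honors the copula correlation", {
  skip_if_not_installed("MASS")
  spec <- cohort_spec()
  R <- diag(8)
  R[1, 2] <- R[2, 1] <- 0.8   # fII-fV strongly correlated
  set.seed(10)
  draws <- sample_factor_levels(4000, spec$factors$control, correlation = R)
  expect_gt(cor(draws$fII, draws$fV), 0.6)
  expect_lt(abs(cor(draws$fII, draws$fX)), 0.1)
})

test_that("infeasible truncation bounds are rejected", {
  expect_error(xagen:::rtruncnorm_reject(5, 100, 10, 200, 150),
               "infeasible_truncation")
  expect_error(xagen:::rtruncnorm_reject(5, 0, 1, 50, 60),
               "infeasible_truncation")
})

test_that("a null study draws cases from the control distributions", {
  coh <- sample_case_control_study(seed = 5L, n_control = 300, n_case = 300,
                                   null_effect = TRUE)
  cases <- coh[coh$group == "case", ]
  # case fVIII must follow the control distribution (122 sd 33), far from
  # the case distribution mean of 141
  expect_lt(abs(mean(cases$fVIII) - 122), 3 * 33 / sqrt(300) + 0.5)
})
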