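test_that("total active fXa sums free and prothrombinase-resident fXa", {
  net <- fixture_network()
  y <- setNames(numeric(34), net$species)
  y["Xa"] <- 1e-9
  y["Xa_Va"] <- 2e-9
  y["Xa_Va_II"] <- 0.5e-9
  y["Xa_AT"] <- 10e-9       # inhibited fXa is excluded
  y["TF_VIIa_Xa"] <- 3e-9   # product complex is excluded
  expect_equal(total_active_fxa(y), 3.5e-9)
  expect_equal(total_active_fxa(y, include_xa_va_ii = FALSE), 3e-9)
  expect_equal(total_active_fxa(setNames(numeric(34), net$species)), 0)
})

test_that("total thrombin weights meizothrombin", {
  net <- fixture_network()
  y <- setNames(numeric(34), net$species)
  y["IIa"] <- 100e-9
  y["mIIa"] <- 10e-9
  expect_equal(total_thrombin(y, 1.2), 112e-9)
  expect_equal(total_thrombin(y, 0), 100e-9)
  expect_equal(total_thrombin(setNames(numeric(34), net$species)), 0)
})

test_that("linear ramp yields the analytic generation parameters", {
  # series 2t pM on t = 0..10 s (in mol/L)
  s <- 2 * (0:10) * 1e-12
  m <- extract_metrics(s, step = 1, analyte = "fXa")
  expect_equal(m$MaxL, 20e-3)   # 20 pM = 0.020 nM
  expect_equal(m$TMaxL, 10)
  expect_equal(m$MaxR, 2)       # 2 pM/s
  expect_equal(m$TMaxR, 1)      # forward difference sits on the later point
  expect_equal(m$AUC, 110e-6)   # 110 pM*s in uM*s
})

test_that("constant series has zero rate and earliest-attainment times", {
  s <- rep(3e-9, 11)
  m <- extract_metrics(s, step = 1, analyte = "fXa")
  expect_equal(m$MaxR, 0)
  expect_equal(m$TMaxL, 0)
  expect_equal(m$AUC, 3e-9 * 11 * 1e6)
})

test_that("flat maxima resolve to the earliest time", {
  s <- c(0, 5, 5, 5, 2) * 1e-9
  m1 <- extract_metrics(s, analyte = "fXa")
  expect_equal(m1$TMaxL, 1)
  # sub-resolution perturbation at a later tied index must not move TMaxL
  s2 <- s
  s2[4] <- s2[4] + 1e-26
  expect_equal(extract_metrics(s2, analyte = "fXa")$TMaxL, 1)
  expect_equal(extract_metrics(rev(s), analyte = "fXa")$TMaxL, 1)
})

test_that("AUC is additive over a grid split", {
  set.seed(11)
  s <- abs(rnorm(101, 5e-9, 1e-9))
  full <- extract_metrics(s, analyte = "fXa")$AUC
  left <- sum(s[1:50]) * 1
  right <- sum(s[51:101]) * 1
  expect_equal(full, (left + right) * 1e6)
})

test_that("metrics scale linearly in the series and times are invariant", {
  set.seed(12)
  s <- cumsum(abs(rnorm(200, 1e-11)))
  m1 <- extract_metrics(s, analyte = "fXa")
  m2 <- extract_metrics(3 * s, analyte = "fXa")
  expect_equal(m2$MaxL, 3 * m1$MaxL)
  expect_equal(m2$MaxR, 3 * m1$MaxR)
  expect_equal(m2$AUC, 3 * m1$AUC)
  expect_equal(m2$TMaxL, m1$TMaxL)
  expect_equal(m2$TMaxR, m1$TMaxR)
})

test_that("non-uniform grids are rejected", {
  expect_error(extract_metrics(c(1, 2, 3) * 1e-9, times = c(0, 1, 3)),
               "nonuniform_grid")
})

test_that("trajectory metrics equal an independent file-level recomputation", {
  traj <- nominal_trajectory()
  tmp <- tempfile(fileext = ".tsv")
  write_trajectory(traj, tmp)
  oracle <- file_level_fxa_metrics(tmp)
  m <- trajectory_metrics(traj, "fXa")
  expect_equal(m$MaxL, oracle$MaxL, tolerance = 1e-6)
  expect_equal(m$TMaxL, oracle$TMaxL)
  expect_equal(m$MaxR, oracle$MaxR, tolerance = 1e-6)
  expect_equal(m$TMaxR, oracle$TMaxR)
  expect_equal(m$AUC, oracle$AUC, tolerance = 1e-6)
})

test_that("MaxL dominates the analyte level at every grid point", {
  traj <- fixture_trajectory("oc_users")
  m <- trajectory_metrics(traj, "fXa")
  expect_gte(m$MaxL, max(total_active_fxa(traj)) * 1e9 - 1e-12)
  expect_true(m$TMaxR >= 0 && m$TMaxR <= 3600)
  expect_true(m$TMaxL >= 0 && m$TMaxL <= 3600)
})
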