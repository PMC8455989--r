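test_that("oxidation_degree computes heavy/(light+heavy) percent", {
  expect_equal(oxidation_degree(75, 25), 25)
  expect_equal(oxidation_degree(0, 10), 100)
  expect_equal(oxidation_degree(10, 0), 0)
  expect_error(oxidation_degree(0, 0), "> 0")
  expect_error(oxidation_degree(-1, 5))
  # vectorized, always in [0, 100]
  set.seed(4)
  l <- runif(50, 0, 100); h <- runif(50, 0, 100)
  d <- oxidation_degree(l, h)
  expect_true(all(d >= 0 & d <= 100))
})

test_that("delta_oxidation matches the hand t-statistic", {
  recs <- tibble::tibble(
    protein = "p", cys_pos = 1L,
    treatment = rep(c("L", "N"), each = 3), replicate = rep(1:3, 2),
    light = c(20, 18, 22, 40, 41, 39), heavy = c(80, 82, 78, 60, 59, 61))
  res <- delta_oxidation(recs, "L", "N")
  expect_equal(res$delta_ox, 20)
  # pooled t = 20 / sqrt(2.5 * 2/3) = 15.49..., df 4
  t_hand <- 20 / sqrt(((2 * 4 + 2 * 1) / 4) * (2 / 3))
  p_hand <- 2 * stats::pt(-t_hand, df = 4)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
})

test_that("delta_oxidation handles degenerate and unbalanced groups", {
  same <- tibble::tibble(
    protein = "p", cys_pos = 1L,
    treatment = rep(c("L", "N"), each = 3), replicate = rep(1:3, 2),
    light = rep(50, 6), heavy = rep(50, 6))
  res <- delta_oxidation(same, "L", "N")
  expect_equal(res$delta_ox, 0)
  expect_equal(res$p_value, 1)

  # single replicate in one group: delta reported, p unavailable
  single <- tibble::tibble(
    protein = "p", cys_pos = 1L,
    treatment = c("L", "L", "N"), replicate = c(1, 2, 1),
    light = c(20, 22, 40), heavy = c(80, 78, 60))
  res2 <- delta_oxidation(single, "L", "N")
  expect_equal(res2$delta_ox, 19)
  expect_true(is.na(res2$p_value))

  # zero-intensity records are dropped with a warning
  withzero <- dplyr::bind_rows(
    same, tibble::tibble(protein = "p", cys_pos = 1L, treatment = "L",
                         replicate = 4, light = 0, heavy = 0))
  expect_warning(res3 <- delta_oxidation(withzero, "L", "N"), "dropped 1")
  expect_equal(res3$n_lethal, 3L)
})

test_that("delta_oxidation is antisymmetric under group swap", {
  ox <- synth_ox_table(ox_spec(noise_sd = 2, seed = 12))
  a <- delta_oxidation(ox$records, ox$truth$lethal[1], ox$truth$nonlethal[1])
  b <- delta_oxidation(ox$records, ox$truth$nonlethal[1], ox$truth$lethal[1])
  expect_equal(a$delta_ox, -b$delta_ox)
  expect_equal(a$p_value, b$p_value)
})

test_that("fit_calibration recovers exact lines and flags bad designs", {
  conc <- c(12, 6, 3, 1.5, 0.75, 0)
  cal <- fit_calibration(tibble::tibble(conc_um = conc, rfu = 1000 * conc))
  expect_equal(cal$slope, 1000)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
  # nonzero intercept recovered exactly
  cal2 <- fit_calibration(tibble::tibble(conc_um = conc, rfu = 50 + 800 * conc))
  expect_equal(cal2$intercept, 50)
  expect_error(fit_calibration(tibble::tibble(conc_um = c(1, 1, 1),
                                              rfu = c(5, 5, 5))), "distinct")
  # constant RFU across concentrations: slope 0, downstream activity errors
  flat <- fit_calibration(tibble::tibble(conc_um = conc, rfu = rep(7, 6)))
  expect_equal(flat$slope, 0)
  kin <- synth_kinetics()
  expect_error(compute_activity(kin$trace, flat, 2e-4, 6e-5), "> 0")
})

test_that("tidy and glance expose the calibration fit", {
  conc <- c(12, 6, 3, 1.5, 0.75, 0)
  cal <- fit_calibration(tibble::tibble(conc_um = conc, rfu = 20 + 950 * conc))
  td <- tidy(cal)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(20, 950))
  gl <- glance(cal)
  expect_equal(gl$slope, 950)
  expect_equal(gl$nobs, 6L)
})

test_that("compute_activity converts the hand example", {
  # slope 500 RFU/min, cal 1000 RFU/uM, 200 uL well, 60 ng protein
  kin <- synth_kinetics(rate_um_min = 0.5, cal_slope = 1000, noise_sd = 0)
  cal <- fit_calibration(kin$standards)
  act <- compute_activity(kin$trace, cal, volume_l = 2e-4, protein_mg = 6e-5)
  expect_equal(act$slope_rfu_min, 500, tolerance = 1e-9)
  expect_equal(act$rate_um_min, 0.5, tolerance = 1e-9)
  expect_equal(act$activity_umol_min_mg, 5 / 3, tolerance = 1e-9)
  # flat trace: zero activity
  flat <- tibble::tibble(time_min = 0:10, rfu = rep(100, 11))
  expect_equal(compute_activity(flat, cal, 2e-4, 6e-5)$activity_umol_min_mg, 0)
  # doubling the calibration slope halves the activity
  kin2 <- synth_kinetics(rate_um_min = 0.5, cal_slope = 2000, noise_sd = 0)
  cal2 <- fit_calibration(kin2$standards)
  act2 <- compute_activity(kin$trace, cal2, 2e-4, 6e-5)
  expect_equal(act2$activity_umol_min_mg, act$activity_umol_min_mg / 2,
               tolerance = 1e-9)
})

test_that("compute_activity is invariant to constant fluorescence offsets", {
  kin <- synth_kinetics(rate_um_min = 0.3, noise_sd = 5, seed = 9)
  cal <- fit_calibration(kin$standards)
  a1 <- compute_activity(kin$trace, cal, 2e-4, 6e-5)
  shifted <- dplyr::mutate(kin$trace, rfu = rfu + 5000)
  a2 <- compute_activity(shifted, cal, 2e-4, 6e-5)
  expect_equal(a1$activity_umol_min_mg, a2$activity_umol_min_mg)
  expect_error(compute_activity(kin$trace[1:3, ], cal, 2e-4, 6e-5))
})

test_that("inhibition_percent handles complete, partial and no inhibition", {
  expect_equal(inhibition_percent(0, 0.35), 100)
  expect_equal(inhibition_percent(0.28, 0.35), 20)
  expect_equal(inhibition_percent(0.35, 0.35), 0)
  expect_equal(inhibition_percent(0.5, 0.35), 0)  # floored at 0
  expect_error(inhibition_percent(0.1, 0), "> 0")
})

test_that("relative_expression implements 2^-ddCt", {
  expect_equal(relative_expression(20, 15, 22, 15), 4)
  expect_equal(relative_expression(20, 15, 20, 15), 1)
  expect_equal(relative_expression(25, 15, 22, 15), 0.125)
  expect_error(relative_expression(NA, 15, 22, 15))
})

test_that("null t-test rejection rate is calibrated at alpha = 0.05", {
  # both groups from the same normal, n = 3 each, pooled t
  set.seed(2024)
  n_sim <- 10000
  a <- matrix(rnorm(3 * n_sim, 50, 5), nrow = 3)
  b <- matrix(rnorm(3 * n_sim, 50, 5), nrow = 3)
  # closed-form pooled t for speed; same statistic delta_oxidation uses
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  tstat <- (ma - mb) / sqrt(((2 * va + 2 * vb) / 4) * (2 / 3))
  p <- 2 * stats::pt(-abs(tstat), df = 4)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.040)
  expect_lte(rate, 0.060)
  # spot-check the closed form against delta_oxidation on 50 draws
  for (k in 1:50) {
    recs <- tibble::tibble(
      protein = "p", cys_pos = 1L,
      treatment = rep(c("L", "N"), each = 3), replicate = rep(1:3, 2),
      light = 100 - c(a[, k], b[, k]), heavy = c(a[, k], b[, k]))
    expect_equal(delta_oxidation(recs, "L", "N")$p_value, p[k],
                 tolerance = 1e-9)
  }
})
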