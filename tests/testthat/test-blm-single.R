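test_that("parameter constructor enforces the model's domain", {
  expect_error(blm_parameters("Cu", 5.9, 2.9, f50 = 1.2), "f50")
  expect_error(blm_parameters("Cu", Inf, 2.9, f50 = 0.3), "finite")
  expect_error(blm_parameters("Cu", 5.9, 2.9,
                              logK_IMBL = c(5.7), f50 = 0.3), "named")
  expect_error(blm_parameters("Cu", 5.9, 2.9,
                              logK_IMBL = c(FeOH = 5), f50 = 0.3),
               "not tracked")
  p <- published_blm_parameters("Cu")
  expect_s3_class(p, "blm_parameters")
  expect_equal(p$logK_MBL, 5.87)
  expect_equal(published_blm_parameters("Co")$logK_IMBL[["CoHCO3"]], 5.81)
})

test_that("site occupancy follows the competitive-binding algebra", {
  # symmetric numerator and competitor, unity off -> exactly 1/2
  p <- blm_parameters("Cu", logK_MBL = log10(2e6), logK_MgBL = log10(2e4),
                      f50 = 0.5)
  sp <- fake_spec(c(Cu = 1e-6, Mg = 1e-4))
  expect_equal(fraction_occupied(sp, p, include_unity_term = FALSE), 0.5)
  # empty numerator -> 0
  sp0 <- fake_spec(c(Cu = 0, Mg = 1e-4))
  expect_equal(fraction_occupied(sp0, p), 0)
  # published Cu constants at {Cu2+} 0.54 uM, {Mg2+} 3.95e-5 M, complexes
  # negligible at pH 6, unity on: hand evaluation gives ~0.28
  pcu <- published_blm_parameters("Cu")
  sph <- fake_spec(c(Cu = 0.54e-6, Mg = 3.95e-5,
                     CuHCO3 = 0, CuCO3 = 0, CuOH = 0))
  expect_equal(fraction_occupied(sph, pcu), 0.28, tolerance = 0.01)
  expect_error(fraction_occupied(fake_spec(c(Mg = 1e-4)), pcu), "missing")
})

test_that("occupancy is monotone in each driver and bounded in [0, 1]", {
  pcu <- published_blm_parameters("Cu")
  pco <- published_blm_parameters("Co")
  grid <- 10^seq(-9, -4, length.out = 12)
  f_cu <- sapply(grid, function(a)
    fraction_occupied(fake_spec(c(Cu = a, Mg = 1e-4, CuHCO3 = 0,
                                  CuCO3 = 0, CuOH = 0)), pcu))
  expect_true(all(diff(f_cu) > 0))
  expect_true(all(f_cu >= 0 & f_cu <= 1))
  f_im <- sapply(grid, function(a)
    fraction_occupied(fake_spec(c(Cu = 1e-7, Mg = 1e-4, CuHCO3 = a,
                                  CuCO3 = 0, CuOH = 0)), pcu))
  expect_true(all(diff(f_im) > 0))
  f_mg <- sapply(grid, function(a)
    fraction_occupied(fake_spec(c(Co = 1e-5, Mg = a, CoHCO3 = 0)), pco))
  expect_true(all(diff(f_mg) < 0))
  # co-exposure competition lowers the occupancy
  mixed <- fraction_occupied(
    fake_spec(c(Cu = 1e-6, Co = 1e-4, Mg = 1e-4, CuHCO3 = 0, CuCO3 = 0,
                CuOH = 0, CoHCO3 = 0)), pcu, competitors = list(pco))
  alone <- fraction_occupied(
    fake_spec(c(Cu = 1e-6, Mg = 1e-4, CuHCO3 = 0, CuCO3 = 0, CuOH = 0)),
    pcu)
  expect_lt(mixed, alone)
})

test_that("EC50 inversion reduces to theta/K without competition", {
  p <- blm_parameters("Cu", logK_MBL = 5, logK_MgBL = 3, f50 = 0.25)
  sp <- fake_spec(c(Mg = 0), lambda = list(Cu = c()))
  expect_equal(predict_ec50_free_ion(p, sp), (0.25 / 0.75) / 1e5)
  # complexes switched off via -Inf reproduce the classical free-ion BLM
  pfull <- blm_parameters("Cu", logK_MBL = 5, logK_MgBL = 3,
                          logK_IMBL = c(CuOH = -Inf, CuCO3 = -Inf,
                                        CuHCO3 = -Inf), f50 = 0.25)
  sp2 <- fake_spec(c(Mg = 2e-4),
                   lambda = list(Cu = c(CuOH = 0.5, CuCO3 = 0.2,
                                        CuHCO3 = 0.01)))
  expect_equal(predict_ec50_free_ion(pfull, sp2),
               (0.25 / 0.75) * (1 + 1e3 * 2e-4) / 1e5)
})

test_that("predicted EC50 is exactly linear in Mg activity at fixed pH", {
  set.seed(17)
  for (i in 1:100) {
    p <- blm_parameters("Cu", logK_MBL = runif(1, 3, 8),
                        logK_MgBL = runif(1, 1, 5),
                        logK_IMBL = c(CuOH = runif(1, 3, 8)),
                        f50 = runif(1, 0.05, 0.95))
    lam <- list(Cu = c(CuOH = 10^runif(1, -3, 0)))
    mg <- 10^runif(3, -5, -2)
    ec <- sapply(mg, function(a)
      predict_ec50_free_ion(p, fake_spec(c(Mg = a), lambda = lam)))
    co <- stats::coef(stats::lm(ec ~ mg))
    # collinearity: third point on the two-point line
    pred3 <- co[1] + co[2] * mg[3]
    expect_equal(unname(ec[3]), unname(pred3), tolerance = 1e-9)
    # slope/intercept ratio identifies the competition constant
    expect_equal(unname(co[2] / co[1]), 10^p$logK_MgBL, tolerance = 1e-6)
  }
})

test_that("EC50-level fits recover the generating constants over the 12-media design", {
  # Cu: {OH} and {HCO3} are exactly proportional across media at fixed pCO2,
  # so only the lumped OH+HCO3 contribution is identifiable; assert the
  # identified parameters and the lump
  ec50_cu <- sapply(fx_specs, function(s) predict_ec50_free_ion(fx_cu, s))
  fit_cu <- fit_single_metal_blm(fx_design$media, "Cu", ec50 = ec50_cu,
                                 f50 = fx_cu$f50)
  p <- fit_cu$parameters
  expect_equal(p$logK_MBL, 5.87, tolerance = 1e-3)
  expect_equal(p$logK_MgBL, 2.93, tolerance = 1e-3)
  expect_equal(p$logK_IMBL[["CuCO3"]], 5.44, tolerance = 1e-3)
  lam <- fx_specs[[1]]$lambda$Cu
  lump_true <- 10^5.67 * lam[["CuHCO3"]] + 10^5.07 * lam[["CuOH"]]
  lump_fit <- 10^p$logK_IMBL[["CuHCO3"]] * lam[["CuHCO3"]] +
    10^p$logK_IMBL[["CuOH"]] * lam[["CuOH"]]
  expect_equal(lump_fit, lump_true, tolerance = 1e-3)
  expect_lt(fit_cu$deviance, 1e-12)

  # Co: fully identified
  ec50_co <- sapply(fx_specs, function(s) predict_ec50_free_ion(fx_co, s))
  fit_co <- fit_single_metal_blm(fx_design$media, "Co", ec50 = ec50_co,
                                 f50 = fx_co$f50)
  expect_equal(fit_co$parameters$logK_MBL, 4.72, tolerance = 1e-3)
  expect_equal(fit_co$parameters$logK_MgBL, 3.84, tolerance = 1e-3)
  expect_equal(fit_co$parameters$logK_IMBL[["CoHCO3"]], 5.81,
               tolerance = 1e-3)
})

test_that("response-level fit identifies the occupancy scale from curve shape", {
  sim <- simulate_single_metal_assay(fx_design, fx_co, noise_sd = 0,
                                     seed = 1)
  resp <- data.frame(medium = match(sim$data$set, names(fx_design$media)),
                     dose = sim$data$dose_M, rne = sim$data$rne)
  resp <- resp[!duplicated(paste(resp$medium, resp$dose)), ]
  fit <- fit_single_metal_blm(fx_design$media, "Co", response = resp)
  p <- fit$parameters
  expect_equal(p$logK_MBL, 4.72, tolerance = 1e-2)
  expect_equal(p$logK_MgBL, 3.84, tolerance = 1e-2)
  expect_equal(p$f50, 0.66, tolerance = 1e-2)
  expect_equal(p$beta, 4.59, tolerance = 1e-2)
})

test_that("deficient designs and missing f50 are refused", {
  one_set <- fx_design$media[1]
  expect_error(fit_single_metal_blm(one_set, "Cu", ec50 = 1e-6,
                                    f50 = 0.28), "Mg")
  mg_only <- fx_design$media[1:4]
  expect_error(
    fit_single_metal_blm(mg_only, "Cu", ec50 = rep(1e-6, 4), f50 = 0.28),
    "pH axis deficient")
  ph_only <- fx_design$media[5:12]
  expect_error(
    fit_single_metal_blm(ph_only, "Cu", ec50 = rep(1e-6, 8), f50 = 0.28),
    "Mg")
  ec50 <- sapply(fx_specs, function(s) predict_ec50_free_ion(fx_cu, s))
  expect_error(fit_single_metal_blm(fx_design$media, "Cu", ec50 = ec50),
               "f50 must be fixed")
})

test_that("EC50 regression on Mg activity behaves like OLS", {
  r <- suppressWarnings(linear_mg_regression(c(1, 2, 3), c(0.1, 0.2, 0.3)))
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 10)
  expect_error(linear_mg_regression(c(1, 2), c(0.1, 0.2)), ">= 3")
  expect_warning(linear_mg_regression(c(1, 2, 3), c(0.1, 0.1, 0.1)),
                 "rank-deficient")
})

test_that("regressing printed Mg-set EC50s on speciated Mg activity gives R2 near 0.97", {
  mg_act <- sapply(fx_specs[1:4], function(s) s$activities[["Mg"]])
  reg <- linear_mg_regression(fx_ref$ec50_Cu_uM[1:4], mg_act)
  expect_equal(reg$r2, 0.97, tolerance = 0.02)
  expect_gt(reg$slope, 0)
})
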