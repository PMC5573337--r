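test_that("toxic units add per metal on both scales", {
  # FIAM: unit contribution per metal at its own EC50
  sp <- fake_spec(c(Cu = 0.41e-6, Co = 64.49e-6))
  expect_equal(toxic_units_fiam(sp, 0.41e-6, 64.49e-6), 2)
  expect_equal(toxic_units_fiam(fake_spec(c(Cu = 0, Co = 0)),
                                0.41e-6, 64.49e-6), 0)
  # half of each EC50 sums to one toxic unit
  expect_equal(toxic_units_fiam(fake_spec(c(Cu = 0.205e-6,
                                            Co = 32.245e-6)),
                                0.41e-6, 64.49e-6), 1)
  expect_error(toxic_units_fiam(sp, -1, 64e-6), "> 0")

  # BLM: occupancy normalised by f50
  expect_equal(toxic_units_blm(fx_cu$f50, 0, fx_cu, fx_co), 1)
  expect_equal(toxic_units_blm(0, 0, fx_cu, fx_co), 0)
  expect_equal(toxic_units_blm(0.14, 0.33, fx_cu, fx_co), 1)
  expect_error(toxic_units_blm(-0.1, 0.2, fx_cu, fx_co), "fractions")
  # homogeneity of degree 1 in per-metal contributions
  expect_equal(toxic_units_blm(0.1, 0.2, fx_cu, fx_co) +
                 toxic_units_blm(0.05, 0.1, fx_cu, fx_co),
               toxic_units_blm(0.15, 0.3, fx_cu, fx_co))
})

test_that("mixture occupancies match a hand evaluation of the binding algebra", {
  for (i in c(1, 4, 6, 9, 12)) {
    m <- with_metal_dose(fx_design$media[[i]], Cu_uM = 1.6, Co_uM = 160)
    sp <- speciate(m)
    fr <- mixture_fractions(sp, fx_cu, fx_co)
    a <- sp$activities
    n_cu <- 10^5.87 * a[["Cu"]] + 10^5.67 * a[["CuHCO3"]] +
      10^5.44 * a[["CuCO3"]] + 10^5.07 * a[["CuOH"]]
    n_co <- 10^4.72 * a[["Co"]] + 10^5.81 * a[["CoHCO3"]]
    d_cu <- n_cu + n_co + 10^2.93 * a[["Mg"]] + 1
    d_co <- n_cu + n_co + 10^3.84 * a[["Mg"]] + 1
    expect_equal(fr[["Cu"]], unname(n_cu / d_cu), tolerance = 1e-6)
    expect_equal(fr[["Co"]], unname(n_co / d_co), tolerance = 1e-6)
    tu <- toxic_units_blm(fr[["Cu"]], fr[["Co"]], fx_cu, fx_co)
    expect_equal(tu, unname(n_cu / d_cu / 0.28 + n_co / d_co / 0.66),
                 tolerance = 1e-6)
  }
})

test_that("single-metal exposure at its EC50 scores one toxic unit on both scales", {
  # exact algebraic identity on a hand-built chemistry
  sp0 <- fake_spec(c(Mg = 3.9e-5), lambda = list(Cu = c(CuOH = 0,
                                                        CuCO3 = 0,
                                                        CuHCO3 = 0)))
  ec50 <- predict_ec50_free_ion(fx_cu, sp0)
  spx <- fake_spec(c(Cu = ec50, Co = 0, Mg = 3.9e-5, CuOH = 0, CuCO3 = 0,
                     CuHCO3 = 0, CoHCO3 = 0))
  expect_equal(toxic_units_fiam(spx, ec50, 64.49e-6), 1)
  f <- mixture_fractions(spx, fx_cu, fx_co)
  expect_equal(unname(f[["Cu"]]), fx_cu$f50, tolerance = 1e-12)
  expect_equal(toxic_units_blm(f[["Cu"]], f[["Co"]], fx_cu, fx_co), 1,
               tolerance = 1e-12)
})

test_that("RMSE follows its definition", {
  expect_equal(rmse(c(20, 50, 80), c(30, 50, 70)), sqrt(200 / 3))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("additive noise-free mixtures refit to TU50 = 1", {
  mix <- simulate_mixture_assay(fx_design, fx_cu, fx_co, lambda = 1,
                                noise_sd = 0, seed = 1)
  fit <- fit_mixture_dose_response(mix$data$tu_f, mix$data$rne,
                                   model = "BLM-TU")
  expect_equal(fit$tu50, 1, tolerance = 1e-6)
  expect_equal(fit$beta, 4.04, tolerance = 1e-6)
  expect_equal(fit$rmse, 0, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("interaction calls follow the concentration-addition rule", {
  expect_equal(classify_interaction(1.03)$label, "additive")
  expect_equal(classify_interaction(0.5, ci = c(0.45, 0.55))$label,
               "synergistic")
  expect_equal(classify_interaction(2.0, ci = c(1.9, 2.1))$label,
               "antagonistic")
  # observed range of set-wise TU50s is all additive under the default band
  expect_true(all(sapply(fx_ref$tu50_mix, function(t)
    classify_interaction(t)$label) == "additive"))
  expect_error(classify_interaction(-1), "tu50")
  # invariant to metal relabelling: TU is symmetric in its contributions
  f1 <- toxic_units_blm(0.1, 0.3, fx_cu, fx_co)
  f2 <- toxic_units_blm(0.3, 0.1, fx_co, fx_cu)
  expect_equal(f1, f2)
  expect_equal(classify_interaction(f1)$label, classify_interaction(f2)$label)
})

test_that("occupancy toxic units outperform free-ion toxic units across chemistry gradients", {
  mix <- simulate_mixture_assay(fx_design, fx_cu, fx_co, lambda = 1,
                                noise_sd = 0, seed = 1)
  base <- fx_specs[[1]]
  ec50_cu <- predict_ec50_free_ion(fx_cu, base)
  ec50_co <- predict_ec50_free_ion(fx_co, base)
  set.seed(99)
  obs <- mix$data
  obs$rne <- obs$rne_true + rnorm(nrow(obs), 0, 5)
  cmp <- compare_models(obs, fx_cu, fx_co, ec50_cu, ec50_co)
  expect_lt(cmp$blm$rmse, cmp$fiam$rmse)
  expect_gt(cmp$blm$r2, cmp$fiam$r2)
  expect_equal(cmp$blm$tu50, 1, tolerance = 0.05)

  # with constant chemistry (one medium) the two scales nearly coincide:
  # their RMSE gap collapses relative to the chemistry-varying case
  one <- obs[obs$set == "Mg0.05", ]
  cmp1 <- compare_models(one, fx_cu, fx_co, ec50_cu, ec50_co)
  expect_lt(abs(cmp1$blm$rmse - cmp1$fiam$rmse),
            0.5 * (cmp$fiam$rmse - cmp$blm$rmse))
})

test_that("model comparison validates its inputs", {
  expect_error(compare_models(data.frame(rne = 1), fx_cu, fx_co, 1, 1),
               "tu_m/tu_f")
  df <- data.frame(rne = c(90, 50, 10, 5), act_Cu = 1:4, act_Co = 1:4,
                   f_Cu = 0.1, f_Co = 0.1)
  expect_error(compare_models(df, fx_cu, fx_co, -1, 1), "> 0")
})
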