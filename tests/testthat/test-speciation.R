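test_that("ionic strength sums 1/2 c z^2 over charged species", {
  expect_identical(ionic_strength(numeric(0)), 0)
  expect_equal(ionic_strength(c(Na = 2e-3, Cl = 2e-3)), 2e-3)
  # fully dissociated base medium, hand sum: 0.5*(0.08 + 2 + 4*0.2 + 4*0.05
  # + 2.48 + 4*0.05) mM = 2.88 mM
  expect_equal(ionic_strength(fx_base_bare), 2.88e-3, tolerance = 1e-10)
  expect_error(ionic_strength(c(Na = -1e-3)), "negative")
  expect_error(ionic_strength(c(Xx = 1e-3)), "unknown species")
})

test_that("Davies coefficients match direct evaluation and limits", {
  expect_identical(davies_gamma(0, 1), 1)
  expect_identical(davies_gamma(0, 2), 1)
  expect_identical(davies_gamma(0.1, 0), 1)
  expect_equal(davies_gamma(0.01, 1), 0.902, tolerance = 1e-3)
  expect_equal(davies_gamma(0.0105, 2), 0.656, tolerance = 1e-3)
  # gamma in (0, 1] over the validity range, decreasing in |z|
  for (I in c(1e-5, 1e-3, 0.05, 0.3)) {
    g <- davies_gamma(I, c(1, 2))
    expect_true(all(g > 0 & g <= 1))
    expect_lt(g[2], g[1])
  }
  expect_error(davies_gamma(-0.01, 1), "ionic strength")
})

test_that("speciation conserves mass and keeps fractions in bounds", {
  set.seed(11)
  for (i in 1:12) {
    comp <- solution_composition(
      K_mM = runif(1, 0, 1), Na_mM = runif(1, 0, 5),
      Ca_mM = runif(1, 0, 2), Mg_mM = runif(1, 0, 3),
      Cu_uM = runif(1, 0, 20), Co_uM = runif(1, 0, 2000),
      Cl_mM = runif(1, 0, 8), SO4_mM = runif(1, 0, 3),
      pH = runif(1, 4, 8))
    sp <- speciate(comp)
    expect_true(sp$converged)
    for (metal in c("Cu", "Co", "Mg", "Ca")) {
      tot <- comp$totals[[metal]]
      if (tot > 0) {
        members <- names(sp$fractions[[metal]])
        expect_equal(sum(sp$concentrations[members]), tot,
                     tolerance = 1e-8, ignore_attr = TRUE)
        expect_true(all(sp$fractions[[metal]] >= 0))
        expect_lte(sum(sp$fractions[[metal]]), 1 + 1e-12)
      }
    }
    expect_true(all(sp$activities >= 0))
    # activity = gamma * concentration for every tracked species
    z <- abs(species_charge(names(sp$concentrations)))
    expect_equal(sp$activities,
                 sp$concentrations * sp$gamma[as.character(z)],
                 ignore_attr = TRUE)
  }
})

test_that("metal-free media carry zero metal-species activities", {
  sp <- speciate(fx_base_bare)
  keys <- c("Cu", "Co", "CuOH", "CuHCO3", "CuCO3", "CoOH", "CoHCO3")
  expect_true(all(sp$activities[keys] == 0))
})

test_that("solver matches the closed-form single-equilibrium solution", {
  # Cu2+/CuOH+ only, dilute enough that gamma ~ 1
  kset <- default_constants(overrides = list(
    logK_CuHCO3 = -Inf, logK_CuCO3 = -Inf, logK_CoOH = -Inf,
    logK_CoHCO3 = -Inf, logK_MgSO4 = -Inf, logK_CaSO4 = -Inf))
  comp <- solution_composition(Cu_uM = 1, Cl_mM = 0.002, pH = 8)
  sp <- speciate(comp, constants = kset)
  aOH <- 10^kset$logKw / 10^(-8)
  K <- 10^kset$logK_CuOH
  # algebra: [Cu]tot = [Cu](1 + g2 K {OH}/g1)
  g1 <- sp$gamma[["1"]]; g2 <- sp$gamma[["2"]]
  cu_free <- comp$totals[["Cu"]] / (1 + g2 * K * aOH / g1)
  expect_equal(sp$concentrations[["Cu"]], cu_free, tolerance = 1e-6)
  expect_equal(sp$activities[["CuOH"]], K * sp$activities[["Cu"]] * aOH,
               tolerance = 1e-6)
})

test_that("ideal-solution limit is approached on dilution", {
  # H+, OH- and the open-CO2 carbonate pool set a pH-dependent floor on I,
  # so the limit is tested along a dilution series at mildly acidic pH
  sps <- lapply(c(1, 0.01, 1e-4), function(scale) {
    speciate(solution_composition(
      K_mM = 0.08 * scale, Na_mM = 2 * scale, Ca_mM = 0.2 * scale,
      Mg_mM = 0.05 * scale, Cl_mM = 2.48 * scale, SO4_mM = 0.05 * scale,
      Cu_uM = 1e-2, pH = 5))
  })
  g2 <- sapply(sps, function(s) s$gamma[["2"]])
  expect_true(all(diff(g2) > 0))
  expect_equal(g2[3], 1, tolerance = 2e-2)  # residual I from H+ at pH 5
  # at the dilute end the ideal-solution closed form is reproduced
  kset <- default_constants()
  aH <- 1e-5
  aOH <- 10^kset$logKw / aH
  aHCO3 <- 10^(kset$logKa1 + kset$logK_H_CO2) * 1e-3 / aH
  aCO3 <- 10^kset$logKa2 * aHCO3 / aH
  phi <- 10^kset$logK_CuOH * aOH + 10^kset$logK_CuHCO3 * aHCO3 +
    10^kset$logK_CuCO3 * aCO3
  expect_equal(sps[[3]]$fractions$Cu[["Cu"]], 1 / (1 + phi),
               tolerance = 1e-3)
})

test_that("hydrolysis and carbonate complexation strengthen with pH", {
  ratio <- sapply(c(5, 6, 7, 8), function(ph) {
    comp <- solution_composition(K_mM = 0.08, Na_mM = 2, Ca_mM = 0.2,
                                 Mg_mM = 0.05, Cl_mM = 2.48, SO4_mM = 0.05,
                                 Cu_uM = 1, pH = ph)
    sp <- speciate(comp)
    c(oh = sp$activities[["CuOH"]] / sp$activities[["Cu"]],
      co3 = sp$activities[["CuCO3"]] / sp$activities[["Cu"]])
  })
  expect_true(all(diff(ratio["oh", ]) > 0))
  expect_true(all(diff(ratio["co3", ]) > 0))
})

test_that("free-ion activity shares across the pH series match reported spans", {
  # reported free-ion activity as % of total: Cu 11.7-78.6, Co 61.5-78.6
  # over pH 4.5 -> 7.6 (different constants database: +/- 10 points)
  ph_media <- fx_design$media[5:12]
  cu_share <- sapply(ph_media, function(m)
    free_ion_activity_share(speciate(with_metal_dose(m, Cu_uM = 1)), "Cu"))
  co_share <- sapply(ph_media, function(m)
    free_ion_activity_share(speciate(with_metal_dose(m, Co_uM = 100)), "Co"))
  expect_true(all(diff(cu_share) < 0))   # monotone decline with pH
  expect_true(all(diff(co_share) < 0))
  expect_lt(abs(cu_share[1] * 100 - 78.6), 10)
  expect_lt(abs(cu_share[8] * 100 - 11.7), 10)
  expect_lt(abs(co_share[1] * 100 - 78.6), 10)
  expect_lt(abs(co_share[8] * 100 - 61.5), 10)
})

test_that("composition validation rejects unphysical inputs", {
  expect_error(solution_composition(Na_mM = -1), "concentrations")
  expect_error(solution_composition(pH = 13), "pH")
  expect_error(solution_composition(pCO2_atm = 0), "pCO2")
  expect_error(with_metal_dose(fx_base_bare, Cu_uM = -2), "doses")
})

test_that("sulfate ion pairs lower free Mg and can be disabled", {
  comp <- solution_composition(K_mM = 0.08, Na_mM = 2, Ca_mM = 0.2,
                               Mg_mM = 2, Cl_mM = 2.48, SO4_mM = 2, pH = 6)
  with_pairs <- speciate(comp)
  without <- speciate(comp, include_ion_pairs = FALSE)
  expect_lt(with_pairs$activities[["Mg"]], without$activities[["Mg"]])
  expect_identical(without$concentrations[["MgSO4"]], 0)
  expect_equal(without$fractions$Mg[["Mg"]], 1)
})
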