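# shared fixtures: built once per test run, all in code

fx_design <- default_design()
fx_ref <- wheat_cuco_reference()
fx_cu <- published_blm_parameters("Cu")
fx_co <- published_blm_parameters("Co")

# background-media speciation, reused across files
fx_specs <- lapply(fx_design$media, speciate)

# base Mg 0.05 mM / pH 6 medium without buffer (hand-checkable ionic strength)
fx_base_bare <- solution_composition(
  K_mM = 0.08, Na_mM = 2, Ca_mM = 0.2, Mg_mM = 0.05,
  Cl_mM = 2.48, SO4_mM = 0.05, pH = 6)

# minimal hand-built "speciation result" for algebraic identity tests
fake_spec <- function(activities, lambda = list()) {
  list(activities = activities, lambda = lambda)
}
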