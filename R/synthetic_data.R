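#' Default synthetic study design
#'
#' Reproduces the twelve-set wheat bioassay design: an Mg-set (Mg 0.05, 0.5,
#' 1.0, 2.0 mM at pH 6.0) and a pH-set (pH 4.5, 5, 5.5, 6, 6.5, 7, 7.3, 7.6
#' at Mg 0.05 mM), each on a 0.08 mM K / 2.0 mM Na / 0.2 mM Ca background
#' with chloride as the macro-cation counter-ion and sulfate carried by Mg.
#' Dose grids are seven-level 2x geometric series — Cu 0.2-12.8 uM, Co
#' 20-1280 uM, mixtures at fixed molar ratio Cu:Co = 1:100 — plus a zero
#' control, each in triplicate. pH buffering (1 mM MES below pH 7, 3.6 mM
#' MOPS at and above) enters only through ionic strength.
#'
#' @param replicates Replicates per treatment.
#' @param noise_sd Default Gaussian noise on RNE (percentage points).
#' @param pCO2_atm CO2 partial pressure passed to every medium.
#' @return Object of class `study_design`: list with `media` (12
#'   [solution_composition()]s, labelled), `cu_doses_M`, `co_doses_M`,
#'   `mix_cu_doses_M`, `mix_ratio`, `replicates`, `noise_sd`.
#' @examples
#' design <- default_design()
#' length(design$media)
#' @export
default_design <- function(replicates = 3, noise_sd = 5, pCO2_atm = 1e-3) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  ref <- wheat_cuco_reference()
  media <- lapply(seq_len(nrow(ref)), function(i) {
    mgmM <- ref$Mg_mM[i]
    ph <- ref$pH[i]
    buffer_mM <- if (ph < 7) 1 else 3.6
    buffer_pKa <- if (ph < 7) 6.15 else 7.18
    solution_composition(
      K_mM = 0.08, Na_mM = 2.0, Ca_mM = 0.2, Mg_mM = mgmM,
      Cl_mM = 0.08 + 2.0 + 2 * 0.2,  # KCl + NaCl + CaCl2
      SO4_mM = mgmM,                 # Mg added as MgSO4
      pH = ph, pCO2_atm = pCO2_atm,
      buffer_mM = buffer_mM, buffer_pKa = buffer_pKa,
      label = ref$set[i])
  })
  names(media) <- ref$set
  cu <- 0.2e-6 * 2^(0:6)
  co <- 20e-6 * 2^(0:6)
  structure(
    list(media = media, cu_doses_M = cu, co_doses_M = co,
         mix_cu_doses_M = cu, mix_ratio = 100,
         replicates = replicates, noise_sd = noise_sd),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat(sprintf("  %d media, %d Cu doses, %d Co doses, mixtures at Cu:Co = 1:%g\n",
              length(x$media), length(x$cu_doses_M), length(x$co_doses_M),
              x$mix_ratio))
  cat(sprintf("  %d replicates, RNE noise sd %.1f%%\n",
              x$replicates, x$noise_sd))
  invisible(x)
}

#' Simulate a single-metal bioassay from a BLM truth
#'
#' Forward model: each medium x dose is speciated, the occupied BL fraction f
#' computed, and the noise-free response set to RNE = 100/(1 + (f/f50)^beta);
#' Gaussian noise (sd in percentage points) is then added per replicate. The
#' truth block records the generating parameters and each medium's exact
#' EC50 as free-ion activity, so any estimator run on the data can be scored.
#' A given `seed` reproduces the dataset exactly.
#'
#' @param design A [default_design()] (or compatible `study_design`).
#' @param params [blm_parameters()] truth, including `f50` and `beta`.
#' @param noise_sd Gaussian RNE noise (percentage points); 0 gives the
#'   noise-free forward model. `NULL` uses the design default.
#' @param seed Integer seed; all randomness of the call flows from it.
#' @param include_unity_term,constants Passed to the occupancy/speciation
#'   steps.
#' @return Object of class `synthetic_dataset`: list with `data` (one row
#'   per replicate: `set`, `dose_M`, `free_activity_M`, `f`, `rne_true`,
#'   `replicate`, `rne`) and `truth` (params, per-medium `ec50_free_M`,
#'   `noise_sd`, `seed`).
#' @examples
#' \donttest{
#' d <- default_design()
#' sim <- simulate_single_metal_assay(d, published_blm_parameters("Co"),
#'                                    noise_sd = 0, seed = 1)
#' head(sim$data)
#' }
#' @export
simulate_single_metal_assay <- function(design, params, noise_sd = NULL,
                                        seed = 1,
                                        include_unity_term = TRUE,
                                        constants = default_constants()) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "blm_parameters"))
  if (is.null(noise_sd)) noise_sd <- design$noise_sd
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a finite value >= 0", call. = FALSE)
  }
  if (!is.finite(params$beta) || params$beta <= 0) {
    stop("params$beta must be > 0 to simulate responses", call. = FALSE)
  }
  doses <- c(0, if (params$metal == "Cu") design$cu_doses_M else
               design$co_doses_M)

  grid <- expand.grid(set = names(design$media), dose_M = doses,
                      stringsAsFactors = FALSE)
  chem <- lapply(seq_len(nrow(grid)), function(i) {
    m <- design$media[[grid$set[i]]]
    dose_uM <- grid$dose_M[i] * 1e6
    dosed <- if (params$metal == "Cu") with_metal_dose(m, Cu_uM = dose_uM)
      else with_metal_dose(m, Co_uM = dose_uM)
    sp <- speciate(dosed, constants = constants)
    c(act = unname(sp$activities[params$metal]),
      f = fraction_occupied(sp, params,
                            include_unity_term = include_unity_term))
  })
  grid$free_activity_M <- vapply(chem, `[[`, numeric(1), "act")
  grid$f <- vapply(chem, `[[`, numeric(1), "f")
  grid$rne_true <- 100 / (1 + (grid$f / params$f50)^params$beta)

  data <- grid[rep(seq_len(nrow(grid)), each = design$replicates), ]
  data$replicate <- rep(seq_len(design$replicates), nrow(grid))
  set.seed(seed)
  data$rne <- data$rne_true +
    if (noise_sd > 0) stats::rnorm(nrow(data), 0, noise_sd) else 0
  rownames(data) <- NULL

  ec50 <- vapply(design$media, function(m)
    predict_ec50_free_ion(params, speciate(m, constants = constants),
                          include_unity_term = include_unity_term),
    numeric(1))
  structure(
    list(data = data,
         truth = list(params = params, ec50_free_M = ec50,
                      noise_sd = noise_sd, seed = seed)),
    class = "synthetic_dataset")
}

#' Simulate per-medium EC50 series with lognormal noise
#'
#' The EC50-level counterpart of [simulate_single_metal_assay()]: each
#' medium's exact BLM EC50 (free-ion activity) is perturbed by multiplicative
#' lognormal noise with the given coefficient of variation, emulating the
#' sampling error of an EC50 estimated from one bioassay.
#'
#' @param design A `study_design`.
#' @param params [blm_parameters()] truth.
#' @param cv Coefficient of variation of the lognormal noise (0 = exact).
#' @param seed Integer seed.
#' @param include_unity_term,constants As elsewhere.
#' @return List with `ec50` (named, mol/L), `ec50_true`, `cv`, `seed`.
#' @export
simulate_ec50_series <- function(design, params, cv = 0.1, seed = 1,
                                 include_unity_term = TRUE,
                                 constants = default_constants()) {
  stopifnot(inherits(design, "study_design"))
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  ec50_true <- vapply(design$media, function(m)
    predict_ec50_free_ion(params, speciate(m, constants = constants),
                          include_unity_term = include_unity_term),
    numeric(1))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  fac <- if (cv > 0) {
    exp(stats::rnorm(length(ec50_true), -sdlog^2 / 2, sdlog))
  } else rep(1, length(ec50_true))
  list(ec50 = ec50_true * fac, ec50_true = ec50_true, cv = cv, seed = seed)
}

#' Simulate a Cu-Co mixture bioassay from a BLM truth
#'
#' Forward model on the occupancy toxic-unit scale: every medium x mixture
#' dose is speciated with both metals present, the per-metal occupancies and
#' TU_f computed, and the noise-free response set to
#' RNE = 100/(1 + (TU_f / lambda)^beta). `lambda` = 1 generates exact
#' concentration addition; `lambda` < 1 injects synergism and > 1 antagonism
#' (the truth block records it). Gaussian RNE noise is added per replicate.
#'
#' @param design A `study_design`.
#' @param params_Cu,params_Co [blm_parameters()] truths for the two metals.
#' @param lambda True TU50 of the generated mixture (1 = additive).
#' @param beta_mix Slope of the mixture dose-response on the TU scale.
#' @param noise_sd Gaussian RNE noise (percentage points); `NULL` uses the
#'   design default.
#' @param seed Integer seed.
#' @param include_unity_term,constants As elsewhere.
#' @return Object of class `synthetic_dataset` whose `data` has one row per
#'   replicate: `set`, `cu_dose_M`, `co_dose_M`, `act_Cu`, `act_Co`, `f_Cu`,
#'   `f_Co`, `tu_f`, `rne_true`, `replicate`, `rne`; `truth` records the
#'   parameter sets, `lambda`, `beta_mix`, `noise_sd`, `seed`.
#' @export
simulate_mixture_assay <- function(design, params_Cu, params_Co,
                                   lambda = 1, beta_mix = 4.04,
                                   noise_sd = NULL, seed = 1,
                                   include_unity_term = TRUE,
                                   constants = default_constants()) {
  stopifnot(inherits(design, "study_design"))
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (beta_mix <= 0) stop("beta_mix must be > 0", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- design$noise_sd
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a finite value >= 0", call. = FALSE)
  }

  doses <- c(0, design$mix_cu_doses_M)
  grid <- expand.grid(set = names(design$media), cu_dose_M = doses,
                      stringsAsFactors = FALSE)
  grid$co_dose_M <- grid$cu_dose_M * design$mix_ratio
  chem <- lapply(seq_len(nrow(grid)), function(i) {
    m <- design$media[[grid$set[i]]]
    dosed <- with_metal_dose(m, Cu_uM = grid$cu_dose_M[i] * 1e6,
                             Co_uM = grid$co_dose_M[i] * 1e6)
    sp <- speciate(dosed, constants = constants)
    fr <- mixture_fractions(sp, params_Cu, params_Co,
                            include_unity_term = include_unity_term)
    c(act_Cu = unname(sp$activities["Cu"]),
      act_Co = unname(sp$activities["Co"]), fr)
  })
  grid$act_Cu <- vapply(chem, `[[`, numeric(1), "act_Cu")
  grid$act_Co <- vapply(chem, `[[`, numeric(1), "act_Co")
  grid$f_Cu <- vapply(chem, `[[`, numeric(1), "Cu")
  grid$f_Co <- vapply(chem, `[[`, numeric(1), "Co")
  grid$tu_f <- toxic_units_blm(grid$f_Cu, grid$f_Co, params_Cu, params_Co)
  grid$rne_true <- 100 / (1 + (grid$tu_f / lambda)^beta_mix)

  data <- grid[rep(seq_len(nrow(grid)), each = design$replicates), ]
  data$replicate <- rep(seq_len(design$replicates), nrow(grid))
  set.seed(seed)
  data$rne <- data$rne_true +
    if (noise_sd > 0) stats::rnorm(nrow(data), 0, noise_sd) else 0
  rownames(data) <- NULL

  structure(
    list(data = data,
         truth = list(params_Cu = params_Cu, params_Co = params_Co,
                      lambda = lambda, beta_mix = beta_mix,
                      noise_sd = noise_sd, seed = seed)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat(sprintf("  %d observations, noise sd %.1f%%, seed %d\n",
              nrow(x$data), x$truth$noise_sd, x$truth$seed))
  invisible(x)
}
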