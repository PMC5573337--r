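#' Read a media composition CSV
#'
#' One row per treatment medium. Units are declared in the column headers
#' and are not silently converted: macro-components in mM
#' (`K_mM,Na_mM,Ca_mM,Mg_mM,Cl_mM,SO4_mM`), metals in uM (`Cu_uM,Co_uM`),
#' plus `pH`. Optional columns: `label`, `buffer_mM`, `buffer_pKa`,
#' `pCO2_atm`. A header carrying a recognised component with the wrong unit
#' suffix (e.g. `Cu_mM`) is an explicit error.
#'
#' @param path CSV file path (UTF-8, comma separator, dot decimal).
#' @return A list of [solution_composition()] objects.
#' @export
read_media_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  required <- c("K_mM", "Na_mM", "Ca_mM", "Mg_mM", "Cu_uM", "Co_uM",
                "Cl_mM", "SO4_mM", "pH")
  .check_schema(names(df), required,
                units = c(K = "mM", Na = "mM", Ca = "mM", Mg = "mM",
                          Cu = "uM", Co = "uM", Cl = "mM", SO4 = "mM"))
  lapply(seq_len(nrow(df)), function(i) {
    solution_composition(
      K_mM = df$K_mM[i], Na_mM = df$Na_mM[i], Ca_mM = df$Ca_mM[i],
      Mg_mM = df$Mg_mM[i], Cu_uM = df$Cu_uM[i], Co_uM = df$Co_uM[i],
      Cl_mM = df$Cl_mM[i], SO4_mM = df$SO4_mM[i], pH = df$pH[i],
      pCO2_atm = if ("pCO2_atm" %in% names(df)) df$pCO2_atm[i] else 1e-3,
      buffer_mM = if ("buffer_mM" %in% names(df)) df$buffer_mM[i] else 0,
      buffer_pKa = if ("buffer_pKa" %in% names(df)) df$buffer_pKa[i]
        else NA_real_,
      label = if ("label" %in% names(df)) df$label[i] else
        paste0("row", i))
  })
}

#' Write media compositions to CSV
#'
#' Inverse of [read_media_csv()]; `read_media_csv(write_media_csv(x))`
#' round-trips the compositions.
#'
#' @param media List of [solution_composition()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_media_csv <- function(media, path) {
  df <- do.call(rbind, lapply(media, function(m) {
    data.frame(
      label = if (is.null(m$label)) NA_character_ else m$label,
      K_mM = m$totals[["K"]] * 1e3, Na_mM = m$totals[["Na"]] * 1e3,
      Ca_mM = m$totals[["Ca"]] * 1e3, Mg_mM = m$totals[["Mg"]] * 1e3,
      Cu_uM = m$totals[["Cu"]] * 1e6, Co_uM = m$totals[["Co"]] * 1e6,
      Cl_mM = m$totals[["Cl"]] * 1e3, SO4_mM = m$totals[["SO4"]] * 1e3,
      pH = m$pH, pCO2_atm = m$pCO2_atm, buffer_mM = m$buffer_mM,
      buffer_pKa = m$buffer_pKa, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# schema check with unit-suffix diagnosis
.check_schema <- function(have, required, units = NULL) {
  missing <- setdiff(required, have)
  if (length(missing) == 0) return(invisible())
  if (!is.null(units)) {
    for (col in missing) {
      base <- sub("_[^_]+$", "", col)
      wrong <- grep(paste0("^", base, "_"), have, value = TRUE)
      if (length(wrong) > 0) {
        stop(sprintf(
          "unit mismatch in column '%s': expected '%s' (%s declared in %s)",
          wrong[1], col, base, units[[base]]), call. = FALSE)
      }
    }
  }
  stop("missing required column(s): ", paste(missing, collapse = ", "),
       call. = FALSE)
}

#' Read a bioassay CSV
#'
#' Accepts either summarised exposure-response rows
#' (`treatment,replicate,x,rne` with `x` the exposure metric and `rne` in
#' percent) or raw root lengths (`treatment,replicate,re_t_cm,re_0_cm,
#' re_c_cm`), in which case RNE is computed with
#' [relative_net_elongation()].
#'
#' @param path CSV file path.
#' @return Data frame with columns `treatment`, `replicate`, `x` (may be
#'   `NA` for raw-length input), `rne`.
#' @export
read_bioassay_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  base <- c("treatment", "replicate")
  .check_schema(names(df), base)
  if (all(c("x", "rne") %in% names(df))) {
    out <- df[c(base, "x", "rne")]
  } else if (all(c("re_t_cm", "re_0_cm", "re_c_cm") %in% names(df))) {
    out <- df[base]
    out$x <- if ("x" %in% names(df)) df$x else NA_real_
    out$rne <- relative_net_elongation(df$re_t_cm, df$re_0_cm, df$re_c_cm)
  } else {
    .check_schema(names(df), c(base, "x", "rne"),
                  units = c(re_t = "cm", re_0 = "cm", re_c = "cm"))
  }
  out
}

#' Write a speciation table for a set of media
#'
#' Runs [speciate()] on each medium and writes one row per medium mirroring
#' the input composition plus `I_mol_L`, `act_<species>` (mol/L) and
#' `frac_<species>` (fraction of parent metal) columns.
#'
#' @param media List of [solution_composition()].
#' @param path Output CSV path, or `NULL` to return the data frame only.
#' @param constants,include_ion_pairs Passed to [speciate()].
#' @return The speciation data frame, invisibly if written to `path`.
#' @export
write_speciation_csv <- function(media, path = NULL,
                                 constants = default_constants(),
                                 include_ion_pairs = TRUE) {
  rows <- lapply(media, function(m) {
    sp <- speciate(m, constants = constants,
                   include_ion_pairs = include_ion_pairs)
    act <- sp$activities[c("Cu", "Co", "Mg", "H", "CuOH", "CuHCO3",
                           "CuCO3", "CoHCO3")]
    fr <- c(sp$fractions$Cu, sp$fractions$Co["CoHCO3"])
    out <- data.frame(label = if (is.null(m$label)) NA_character_ else
      m$label, pH = m$pH, Mg_mM = m$totals[["Mg"]] * 1e3,
      Cu_uM = m$totals[["Cu"]] * 1e6, Co_uM = m$totals[["Co"]] * 1e6,
      I_mol_L = sp$ionic_strength, stringsAsFactors = FALSE)
    for (nm in names(act)) out[[paste0("act_", nm)]] <- unname(act[nm])
    for (nm in names(fr)) out[[paste0("frac_", nm)]] <- unname(fr[nm])
    out
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Pipeline configuration
#'
#' Bundles the options of [run_pipeline()] into one validated object that
#' round-trips to JSON.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed governing all simulated randomness.
#' @param noise_sd Gaussian RNE noise of the simulated bioassays.
#' @param f50_Cu,f50_Co Occupancy at 50% effect fixed in the EC50-level BLM
#'   fits (see [fit_single_metal_blm()] for why this is required).
#' @param pCO2_atm Open-system CO2 partial pressure.
#' @param include_unity_term,include_ion_pairs Model switches, see
#'   [fraction_occupied()] and [speciate()].
#' @param additivity_band Half-width of the additive band for
#'   [classify_interaction()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, noise_sd = 5,
                            f50_Cu = 0.28, f50_Co = 0.66,
                            pCO2_atm = 1e-3, include_unity_term = TRUE,
                            include_ion_pairs = TRUE,
                            additivity_band = 0.2) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              noise_sd = noise_sd, f50_Cu = f50_Cu, f50_Co = f50_Co,
              pCO2_atm = pCO2_atm, include_unity_term = include_unity_term,
              include_ion_pairs = include_ion_pairs,
              additivity_band = additivity_band)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates the stages end to end on data simulated under the published
#' parameter sets: speciate the twelve media; simulate single-metal Cu and
#' Co bioassays and fit per-medium log-logistic curves to obtain EC50s as
#' free-ion activity; fit the single-metal BLM constants from those EC50s;
#' simulate the 1:100 Cu-Co mixture bioassay, compute both toxic-unit
#' scales, fit and compare the FIAM-TU and BLM-TU models; classify the
#' interaction. Artifacts (speciation CSV, parameter JSON, TU-augmented
#' mixture CSV, comparison JSON, run log) are written under
#' `config$out_dir`; a fixed seed makes the run idempotent.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- default_design(noise_sd = config$noise_sd,
                           pCO2_atm = config$pCO2_atm)
  paths <- list()

  # 1. speciation of the background media
  spec_df <- write_speciation_csv(
    design$media, file.path(config$out_dir, "speciation.csv"),
    include_ion_pairs = config$include_ion_pairs)
  paths$speciation <- file.path(config$out_dir, "speciation.csv")

  # 2. single-metal assays -> per-medium EC50 -> BLM constants
  fits <- list()
  for (metal in c("Cu", "Co")) {
    truth <- published_blm_parameters(metal)
    sim <- simulate_single_metal_assay(
      design, truth, seed = config$seed + match(metal, c("Cu", "Co")),
      include_unity_term = config$include_unity_term)
    ec50 <- vapply(names(design$media), function(s) {
      rows <- sim$data$set == s
      fit_loglogistic(sim$data$free_activity_M[rows],
                      sim$data$rne[rows])$x50
    }, numeric(1))
    f50 <- if (metal == "Cu") config$f50_Cu else config$f50_Co
    fits[[metal]] <- fit_single_metal_blm(
      design$media, metal, ec50 = ec50, f50 = f50,
      include_unity_term = config$include_unity_term,
      include_ion_pairs = config$include_ion_pairs)
  }
  par_json <- file.path(config$out_dir, "single_metal_parameters.json")
  jsonlite::write_json(
    lapply(fits, function(f) {
      p <- f$parameters
      list(metal = p$metal, logK_MBL = round(p$logK_MBL, 6),
           logK_MgBL = round(p$logK_MgBL, 6),
           logK_IMBL = as.list(round(p$logK_IMBL, 6)),
           f50 = p$f50, r2 = round(f$r2, 6),
           deviance = signif(f$deviance, 6))
    }),
    par_json, auto_unbox = TRUE, pretty = TRUE)
  paths$parameters <- par_json

  # 3. mixtures: simulate, compute TUs, fit and compare the two scales
  params_Cu <- published_blm_parameters("Cu")
  params_Co <- published_blm_parameters("Co")
  mix <- simulate_mixture_assay(design, params_Cu, params_Co,
                                seed = config$seed + 10,
                                include_unity_term =
                                  config$include_unity_term)
  obs <- mix$data
  ec50_ref <- list(Cu = fits$Cu, Co = fits$Co)
  # FIAM reference EC50s: the base medium (first set) prediction per metal
  base_spec <- speciate(design$media[[1]],
                        include_ion_pairs = config$include_ion_pairs)
  ec50_Cu <- predict_ec50_free_ion(fits$Cu$parameters, base_spec,
                                   config$include_unity_term)
  ec50_Co <- predict_ec50_free_ion(fits$Co$parameters, base_spec,
                                   config$include_unity_term)
  obs$tu_m <- obs$act_Cu / ec50_Cu + obs$act_Co / ec50_Co
  cmp <- compare_models(obs, params_Cu, params_Co, ec50_Cu, ec50_Co)
  call <- classify_interaction(cmp$blm$tu50, band = config$additivity_band)

  mix_csv <- file.path(config$out_dir, "mixture_tu.csv")
  utils::write.csv(obs, mix_csv, row.names = FALSE)
  paths$mixture <- mix_csv
  cmp_json <- file.path(config$out_dir, "model_comparison.json")
  jsonlite::write_json(
    list(
      FIAM_TU = list(tu50 = round(cmp$fiam$tu50, 6),
                     beta = round(cmp$fiam$beta, 6),
                     rmse = round(cmp$fiam$rmse, 6),
                     r2 = round(cmp$fiam$r2, 6)),
      BLM_TU = list(tu50 = round(cmp$blm$tu50, 6),
                    beta = round(cmp$blm$beta, 6),
                    rmse = round(cmp$blm$rmse, 6),
                    r2 = round(cmp$blm$r2, 6)),
      interaction = list(tu50 = round(call$tu50, 6), label = call$label)),
    cmp_json, auto_unbox = TRUE, pretty = TRUE)
  paths$comparison <- cmp_json

  # 4. run log: everything needed to replay
  log_json <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(
    list(package = "blmtu",
         version = as.character(utils::packageVersion("blmtu")),
         config = unclass(config)),
    log_json, auto_unbox = TRUE, pretty = TRUE)
  paths$log <- log_json

  invisible(list(fits = fits, comparison = cmp, interaction = call,
                 speciation = spec_df, paths = paths))
}
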