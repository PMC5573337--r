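#' Published wheat Cu-Co bioassay summary (reference values)
#'
#' The printed summary of the twelve wheat root-elongation bioassay sets:
#' four Mg levels (0.05-2.0 mM) at pH 6.0 and eight pH levels (4.5-7.6) at
#' 0.05 mM Mg, all on a 0.08 mM K / 2.0 mM Na / 0.2 mM Ca background. For
#' each set the table carries the fitted single-metal EC50 (as free-ion
#' activity, uM) and slope for Cu-only and Co-only, and the fitted TU50 and
#' slope of the 1:100 Cu-Co mixture. These printed values are inputs for
#' arithmetic checks, regression against speciated \{Mg2+\}, and as anchors
#' for simulation; the raw per-seedling data behind them are not published.
#'
#' @return A data.frame with columns `set`, `series` ("Mg" or "pH"),
#'   `Mg_mM`, `pH`, `ec50_Cu_uM`, `beta_Cu`, `ec50_Co_uM`, `beta_Co`,
#'   `tu50_mix`, `beta_mix`.
#' @examples
#' ref <- wheat_cuco_reference()
#' subset(ref, series == "Mg")$ec50_Cu_uM
#' @export
wheat_cuco_reference <- function() {
  data.frame(
    set = c("Mg0.05", "Mg0.5", "Mg1.0", "Mg2.0",
            "pH4.5", "pH5", "pH5.5", "pH6", "pH6.5", "pH7", "pH7.3",
            "pH7.6"),
    series = c(rep("Mg", 4), rep("pH", 8)),
    Mg_mM = c(0.05, 0.5, 1.0, 2.0, rep(0.05, 8)),
    pH = c(rep(6.0, 4), 4.5, 5, 5.5, 6, 6.5, 7, 7.3, 7.6),
    ec50_Cu_uM = c(0.41, 0.66, 0.74, 1.01,
                   0.45, 0.50, 0.49, 0.42, 0.43, 0.28, 0.18, 0.11),
    beta_Cu = c(3.76, 4.52, 3.71, 2.63,
                8.73, 3.93, 6.71, 3.76, 3.20, 2.80, 2.68, 3.16),
    ec50_Co_uM = c(64.49, 51.52, 438.34, 620.75,
                   122.60, 129.42, 104.01, 64.61, 55.11, 40.81, 37.19,
                   29.94),
    beta_Co = c(3.31, 3.15, 3.73, 5.50,
                4.74, 4.63, 5.40, 3.35, 3.77, 4.37, 4.49, 4.26),
    tu50_mix = c(1.03, 0.93, 1.11, 0.97,
                 0.88, 1.10, 1.15, 1.02, 1.04, 1.13, 1.15, 1.02),
    beta_mix = c(4.89, 5.77, 3.25, 5.12,
                 5.21, 6.49, 8.26, 4.89, 6.57, 6.07, 5.05, 5.69),
    stringsAsFactors = FALSE
  )
}

#' Published pooled mixture-model fits (reference values)
#'
#' The pooled Cu-Co mixture dose-response fits reported for the two
#' toxic-unit scales: the free-ion (FIAM-TU) model with x50 0.87, slope 1.71,
#' RMSE 16.31 and R2 0.84, and the site-occupancy (BLM-TU) model with x50
#' 1.45, slope 4.04, RMSE 6.70 and R2 0.97. These depend on the unpublished
#' raw observations and are retained for documentation and orientation, not
#' as reproducible targets.
#'
#' @return A data.frame with columns `model`, `x50`, `beta`, `rmse`, `r2`.
#' @export
published_mixture_fits <- function() {
  data.frame(
    model = c("FIAM-TU", "BLM-TU"),
    x50 = c(0.87, 1.45),
    beta = c(1.71, 4.04),
    rmse = c(16.31, 6.70),
    r2 = c(0.84, 0.97),
    stringsAsFactors = FALSE
  )
}
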