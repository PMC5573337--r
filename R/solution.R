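#' Define the total composition of a test medium
#'
#' Represents one background nutrient solution by its total dissolved
#' component concentrations and its (externally buffered, hence fixed) pH.
#' Charge balance of the totals is not required: the solver treats pH as an
#' imposed boundary condition, mirroring pH-stat bioassay media.
#'
#' Concentrations are stored internally in mol/L. The convenience arguments
#' take the units conventional for these media: macro-ions in mM and the
#' trace metals in uM.
#'
#' pH buffers (MES/MOPS type) are assumed non-complexing, but their ionized
#' fraction, together with the Na+ counter-ion added on titration, contributes
#' to ionic strength; `buffer_mM`/`buffer_pKa` capture that contribution.
#'
#' @param K_mM,Na_mM,Ca_mM,Mg_mM Total macro-cation concentrations (mM).
#' @param Cu_uM,Co_uM Total trace-metal concentrations (uM).
#' @param Cl_mM,SO4_mM Total anion concentrations (mM).
#' @param pH Fixed pH (dimensionless, -log10 H+ activity), in \[2, 12\].
#' @param temperature_C Assay temperature; constants are 25 C values and no
#'   temperature correction is applied, so this is recorded for provenance.
#' @param pCO2_atm CO2 partial pressure of the open system (atm). The default
#'   10^-3 atm reflects the elevated CO2 of a closed, dark growth chamber with
#'   respiring seedlings rather than open-atmosphere 10^-3.5 atm.
#' @param buffer_mM Total pH-buffer concentration (mM); 0 disables the
#'   ionic-strength contribution.
#' @param buffer_pKa Acid dissociation pKa of the buffer.
#' @param label Optional treatment label.
#' @return An object of class `solution_composition`: list with `totals`
#'   (named mol/L vector over K, Na, Ca, Mg, Cu, Co, Cl, SO4), `pH`,
#'   `temperature_C`, `pCO2_atm`, `buffer_mM`, `buffer_pKa`, `label`.
#' @examples
#' base <- solution_composition(K_mM = 0.08, Na_mM = 2, Ca_mM = 0.2,
#'                              Mg_mM = 0.05, Cl_mM = 2.48, SO4_mM = 0.05,
#'                              pH = 6)
#' base$totals["Mg"]
#' @export
solution_composition <- function(K_mM = 0, Na_mM = 0, Ca_mM = 0, Mg_mM = 0,
                                 Cu_uM = 0, Co_uM = 0, Cl_mM = 0, SO4_mM = 0,
                                 pH = 6, temperature_C = 20, pCO2_atm = 1e-3,
                                 buffer_mM = 0, buffer_pKa = NA_real_,
                                 label = NULL) {
  totals <- c(K = K_mM, Na = Na_mM, Ca = Ca_mM, Mg = Mg_mM,
              Cl = Cl_mM, SO4 = SO4_mM) * 1e-3
  totals <- c(totals, Cu = Cu_uM * 1e-6, Co = Co_uM * 1e-6)
  totals <- totals[c("K", "Na", "Ca", "Mg", "Cu", "Co", "Cl", "SO4")]
  if (any(!is.finite(totals)) || any(totals < 0)) {
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(pH) || pH < 2 || pH > 12) {
    stop("pH must lie in [2, 12]", call. = FALSE)
  }
  if (!is.finite(pCO2_atm) || pCO2_atm <= 0) {
    stop("pCO2_atm must be > 0", call. = FALSE)
  }
  if (buffer_mM < 0) stop("buffer_mM must be >= 0", call. = FALSE)
  if (buffer_mM > 0 && !is.finite(buffer_pKa)) {
    stop("buffer_pKa must be given when buffer_mM > 0", call. = FALSE)
  }
  structure(
    list(totals = totals, pH = pH, temperature_C = temperature_C,
         pCO2_atm = pCO2_atm, buffer_mM = buffer_mM,
         buffer_pKa = buffer_pKa, label = label),
    class = "solution_composition"
  )
}

#' @export
print.solution_composition <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat("<solution_composition>", lab, "\n", sep = "")
  mM <- x$totals[c("K", "Na", "Ca", "Mg", "Cl", "SO4")] * 1e3
  uM <- x$totals[c("Cu", "Co")] * 1e6
  cat("  totals (mM): ", paste(sprintf("%s=%.3g", names(mM), mM),
                               collapse = ", "), "\n", sep = "")
  cat("  metals (uM): ", paste(sprintf("%s=%.3g", names(uM), uM),
                               collapse = ", "), "\n", sep = "")
  cat(sprintf("  pH %.2f, pCO2 %.2e atm, buffer %.2g mM\n",
              x$pH, x$pCO2_atm, x$buffer_mM))
  invisible(x)
}

#' Add a metal dose to a background medium
#'
#' Returns the medium with the metal totals raised by the stated dose. The
#' dose is assumed to be added as the chloride salt, so Cl- rises by twice
#' the added divalent metal (this matters only through ionic strength).
#'
#' @param comp A [solution_composition()].
#' @param Cu_uM,Co_uM Added metal (uM).
#' @return A new `solution_composition`.
#' @export
with_metal_dose <- function(comp, Cu_uM = 0, Co_uM = 0) {
  stopifnot(inherits(comp, "solution_composition"))
  if (Cu_uM < 0 || Co_uM < 0) stop("doses must be >= 0", call. = FALSE)
  comp$totals["Cu"] <- comp$totals["Cu"] + Cu_uM * 1e-6
  comp$totals["Co"] <- comp$totals["Co"] + Co_uM * 1e-6
  comp$totals["Cl"] <- comp$totals["Cl"] + 2 * (Cu_uM + Co_uM) * 1e-6
  comp
}
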