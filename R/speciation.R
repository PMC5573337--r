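#' Ionic strength of a set of dissolved species
#'
#' Computes I = 1/2 * sum(c_i * z_i^2) over all charged species. Accepts
#' either a named concentration vector (charges looked up with
#' [species_charge()] unless supplied) or a [solution_composition()], in which
#' case the stated totals are treated as fully dissociated — the conventional
#' first estimate before speciation.
#'
#' @param x Named numeric vector of species concentrations (mol/L), or a
#'   `solution_composition`.
#' @param charges Optional numeric vector of charges matching `x`.
#' @return Ionic strength in mol/L.
#' @examples
#' ionic_strength(c(Na = 2e-3, Cl = 2e-3))   # 0.002
#' @export
ionic_strength <- function(x, charges = NULL) {
  if (inherits(x, "solution_composition")) {
    concs <- x$totals
    charges <- species_charge(names(concs))
    ib <- .buffer_ionic_strength(x)
  } else {
    concs <- x
    if (is.null(charges)) charges <- species_charge(names(concs))
    ib <- 0
  }
  if (any(concs < 0)) stop("negative concentration", call. = FALSE)
  if (length(charges) != length(concs)) {
    stop("charges must match concentrations", call. = FALSE)
  }
  0.5 * sum(concs * charges^2) + ib
}

# ionized buffer + its Na+ counter-ion as a 1:1 electrolyte
.buffer_ionic_strength <- function(comp) {
  if (comp$buffer_mM <= 0) return(0)
  ionized <- comp$buffer_mM * 1e-3 / (1 + 10^(comp$buffer_pKa - comp$pH))
  ionized
}

#' Davies single-ion activity coefficient
#'
#' log10(gamma) = -A * z^2 * (sqrt(I)/(1 + sqrt(I)) - b * I), the empirical
#' Davies extension of Debye-Hueckel theory, with A = 0.51 and b = 0.3 at
#' 25 C. Adequate to roughly I = 0.5 mol/L; neutral species get gamma = 1.
#'
#' @param I Ionic strength (mol/L), >= 0.
#' @param z Integer charge (vectorized).
#' @param A,b Davies coefficients.
#' @return Activity coefficient(s), dimensionless.
#' @examples
#' davies_gamma(0.01, 1)    # ~0.902
#' davies_gamma(0.0105, 2)  # ~0.656
#' @export
davies_gamma <- function(I, z, A = 0.51, b = 0.3) {
  if (!is.finite(I) || I < 0) stop("ionic strength must be >= 0", call. = FALSE)
  sqI <- sqrt(I)
  10^(-A * z^2 * (sqI / (1 + sqI) - b * I))
}

#' Inorganic equilibrium speciation of a test medium
#'
#' Solves the fixed-pH, open-CO2 inorganic equilibrium of a defined nutrient
#' solution: free ions (Cu2+, Co2+, Mg2+, Ca2+, H+, OH-), the carbonate chain
#' fed by Henry's law at `pCO2_atm`, the metal complexes CuOH+, CuCO3(aq),
#' CuHCO3+, CoOH+, CoHCO3+, and (optionally) the MgSO4(aq)/CaSO4(aq) ion
#' pairs. Activity corrections use the Davies equation, iterated with ionic
#' strength to convergence. K+, Na+ and Cl- are treated as conservative.
#'
#' Because pH is imposed and the carbonate pool is an open reservoir, the
#' ligand activities {OH-}, {HCO3-}, {CO3 2-} are fixed by pH and pCO2 alone;
#' each metal's mass balance is then linear in its free-ion concentration and
#' solved exactly, with only the sulfate ion-pair block (which couples Mg, Ca
#' and SO4) requiring a scalar root solve.
#'
#' @param comp A [solution_composition()].
#' @param constants An `equilibrium_constants` set, see [default_constants()].
#' @param include_ion_pairs Include MgSO4(aq)/CaSO4(aq)? Disable for strict
#'   free-salt behaviour.
#' @param max_iter Maximum ionic-strength iterations.
#' @param tol Relative convergence tolerance on ionic strength.
#' @return An object of class `speciation_result`: list with
#'   `ionic_strength` (mol/L), `gamma` (named by |charge| "0","1","2"),
#'   `activities` and `concentrations` (named, mol/L), `fractions` (per-metal
#'   named vectors, concentration fractions of the parent total),
#'   `lambda` (per-metal activity ratios \{IM\}/\{M2+\} of each inorganic
#'   complex, fixed by pH/pCO2), `comp`, `iterations`, `converged`.
#' @examples
#' base <- solution_composition(K_mM = 0.08, Na_mM = 2, Ca_mM = 0.2,
#'                              Mg_mM = 0.05, Cl_mM = 2.48, SO4_mM = 0.05,
#'                              pH = 6, Cu_uM = 1)
#' sp <- speciate(base)
#' sp$activities["Cu"]
#' sp$fractions$Cu
#' @export
speciate <- function(comp, constants = default_constants(),
                     include_ion_pairs = TRUE, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(comp, "solution_composition"))
  if (!inherits(constants, "equilibrium_constants")) {
    stop("constants must come from default_constants()", call. = FALSE)
  }
  K <- lapply(constants, function(v) 10^v)  # linear-scale constants
  tot <- comp$totals

  # pH- and pCO2-fixed ligand activities (open system)
  aH <- 10^(-comp$pH)
  aOH <- K$logKw / aH
  aCO2 <- K$logK_H_CO2 * comp$pCO2_atm
  aHCO3 <- K$logKa1 * aCO2 / aH
  aCO3 <- K$logKa2 * aHCO3 / aH

  pair_on <- include_ion_pairs
  I <- ionic_strength(comp) + 0.5 * (aH + aOH + aHCO3 + 4 * aCO3)
  Ib <- .buffer_ionic_strength(comp)

  iter <- 0L
  converged <- FALSE
  g1 <- g2 <- 1
  out <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    g1 <- davies_gamma(I, 1)
    g2 <- davies_gamma(I, 2)

    # per-metal linear side-reaction coefficients: [M]tot = [M] * (1 + phi)
    phi_Cu <- g2 * (K$logK_CuOH * aOH / g1 +
                    K$logK_CuHCO3 * aHCO3 / g1 +
                    K$logK_CuCO3 * aCO3)
    phi_Co <- g2 * (K$logK_CoOH * aOH / g1 +
                    K$logK_CoHCO3 * aHCO3 / g1)
    cCu <- tot["Cu"] / (1 + phi_Cu)
    cCo <- tot["Co"] / (1 + phi_Co)

    # sulfate ion-pair block: scalar root in free [SO4]
    aMg_pair <- if (pair_on) K$logK_MgSO4 * g2^2 else 0
    aCa_pair <- if (pair_on) K$logK_CaSO4 * g2^2 else 0
    St <- tot["SO4"]
    if (St > 0 && pair_on && (tot["Mg"] + tot["Ca"]) > 0) {
      fr <- function(s) {
        s * (1 + aMg_pair * tot["Mg"] / (1 + aMg_pair * s) +
               aCa_pair * tot["Ca"] / (1 + aCa_pair * s)) - St
      }
      cSO4 <- stats::uniroot(fr, c(0, St), tol = max(St * 1e-13, 1e-28))$root
    } else {
      cSO4 <- St
    }
    cMg <- tot["Mg"] / (1 + aMg_pair * cSO4)
    cCa <- tot["Ca"] / (1 + aCa_pair * cSO4)

    conc <- c(
      K = unname(tot["K"]), Na = unname(tot["Na"]), Cl = unname(tot["Cl"]),
      Ca = unname(cCa), Mg = unname(cMg), Cu = unname(cCu), Co = unname(cCo),
      SO4 = unname(cSO4),
      H = aH / g1, OH = aOH / g1,
      CO2 = aCO2, HCO3 = aHCO3 / g1, CO3 = aCO3 / g2,
      CuOH = unname(K$logK_CuOH * g2 * cCu * aOH / g1),
      CuHCO3 = unname(K$logK_CuHCO3 * g2 * cCu * aHCO3 / g1),
      CuCO3 = unname(K$logK_CuCO3 * g2 * cCu * aCO3),
      CoOH = unname(K$logK_CoOH * g2 * cCo * aOH / g1),
      CoHCO3 = unname(K$logK_CoHCO3 * g2 * cCo * aHCO3 / g1),
      MgSO4 = unname(aMg_pair * cMg * cSO4),
      CaSO4 = unname(aCa_pair * cCa * cSO4)
    )
    Inew <- 0.5 * sum(conc * species_charge(names(conc))^2) + Ib
    out <- conc
    if (abs(Inew - I) <= tol * max(Inew, .Machine$double.eps)) {
      I <- Inew
      converged <- TRUE
      break
    }
    I <- Inew
  }
  if (!converged) {
    stop(sprintf(
      "speciation did not converge in %d iterations (last I = %.6g mol/L)",
      max_iter, I), call. = FALSE)
  }

  conc <- out
  gam <- c(`0` = 1, `1` = g1, `2` = g2)
  z <- abs(species_charge(names(conc)))
  act <- conc * gam[as.character(z)]
  names(act) <- names(conc)

  # mass-balance audit (construction makes these exact up to root tolerance)
  .check_balance <- function(total, parts, what) {
    if (total <= 0) return(invisible())
    rel <- abs(sum(parts) - total) / total
    if (rel > 1e-8) {
      stop(sprintf("mass balance violated for %s (rel. error %.3g)",
                   what, rel), call. = FALSE)
    }
  }
  .check_balance(tot["Cu"], conc[c("Cu", "CuOH", "CuHCO3", "CuCO3")], "Cu")
  .check_balance(tot["Co"], conc[c("Co", "CoOH", "CoHCO3")], "Co")
  .check_balance(tot["Mg"], conc[c("Mg", "MgSO4")], "Mg")
  .check_balance(tot["Ca"], conc[c("Ca", "CaSO4")], "Ca")
  .check_balance(tot["SO4"], conc[c("SO4", "MgSO4", "CaSO4")], "SO4")

  frac_of <- function(metal, members) {
    if (tot[metal] <= 0) {
      stats::setNames(rep(0, length(members)), members)
    } else {
      conc[members] / tot[metal]
    }
  }
  fractions <- list(
    Cu = frac_of("Cu", c("Cu", "CuOH", "CuHCO3", "CuCO3")),
    Co = frac_of("Co", c("Co", "CoOH", "CoHCO3")),
    Mg = frac_of("Mg", c("Mg", "MgSO4")),
    Ca = frac_of("Ca", c("Ca", "CaSO4"))
  )
  # activity ratios {IM}/{M2+}: defined by chemistry even at zero metal
  lambda <- list(
    Cu = c(CuOH = K$logK_CuOH * aOH,
           CuHCO3 = K$logK_CuHCO3 * aHCO3,
           CuCO3 = K$logK_CuCO3 * aCO3),
    Co = c(CoOH = K$logK_CoOH * aOH,
           CoHCO3 = K$logK_CoHCO3 * aHCO3)
  )

  structure(
    list(ionic_strength = unname(I), gamma = gam, activities = act,
         concentrations = conc, fractions = fractions, lambda = lambda,
         comp = comp, iterations = iter, converged = converged),
    class = "speciation_result"
  )
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("<speciation_result>\n")
  cat(sprintf("  I = %.4g mol/L (gamma1 %.3f, gamma2 %.3f), %d iterations\n",
              x$ionic_strength, x$gamma["1"], x$gamma["2"], x$iterations))
  keys <- c("Cu", "Co", "Mg", "CuOH", "CuHCO3", "CuCO3", "CoHCO3")
  on <- keys[x$activities[keys] > 0]
  if (length(on) > 0) {
    cat("  activities (mol/L):\n")
    for (k in on) cat(sprintf("    {%s} = %.4g\n", k, x$activities[k]))
  }
  invisible(x)
}

#' Free-ion activity as a share of the total metal
#'
#' The conventional reporting of speciation output for bioassay media: the
#' free divalent ion activity divided by the total dissolved metal
#' concentration (so both complexation and the activity coefficient reduce
#' it below 1).
#'
#' @param spec A `speciation_result`.
#' @param metal `"Cu"` or `"Co"` (any tracked metal).
#' @return Dimensionless share in \[0, 1\], or `NA` if the metal is absent.
#' @export
free_ion_activity_share <- function(spec, metal) {
  stopifnot(inherits(spec, "speciation_result"))
  total <- spec$comp$totals[metal]
  if (is.na(total) || total <= 0) return(NA_real_)
  unname(spec$activities[metal] / total)
}
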