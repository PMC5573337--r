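#' Biotic ligand model parameter set for one metal
#'
#' Collects the binding constants and effect parameters of a single-metal
#' biotic ligand model (BLM): the stability constant of the free divalent
#' metal at the biotic ligand (BL), the constants of its toxic inorganic
#' complexes, the Mg2+ competition constant, the occupied-site fraction at
#' 50% effect (f50), and the slope of the occupancy-scale dose-response.
#' H+, Ca2+, K+ and Na+ competition are deliberately not represented: across
#' these bioassays their influence is minor relative to Mg2+, and the pH
#' effect is carried by the complex terms instead.
#'
#' @param metal `"Cu"` or `"Co"`.
#' @param logK_MBL log10 stability constant of M2+ binding to the BL.
#' @param logK_MgBL log10 stability constant of Mg2+ competition at the BL.
#' @param logK_IMBL Named numeric vector of log10 constants for toxic
#'   inorganic complexes (names must be species the speciation module tracks,
#'   e.g. `c(CuHCO3 = 5.67, CuCO3 = 5.44, CuOH = 5.07)`). `-Inf` disables a
#'   term; an empty vector gives the classical free-ion-only BLM.
#' @param f50 Fraction of BL sites occupied at 50% effect, in (0, 1).
#' @param beta Slope of the occupancy-scale log-logistic dose-response.
#' @return An object of class `blm_parameters`.
#' @examples
#' blm_parameters("Cu", logK_MBL = 5.87, logK_MgBL = 2.93,
#'                logK_IMBL = c(CuHCO3 = 5.67, CuCO3 = 5.44, CuOH = 5.07),
#'                f50 = 0.28, beta = 2.73)
#' @export
blm_parameters <- function(metal, logK_MBL, logK_MgBL,
                           logK_IMBL = numeric(0), f50, beta = NA_real_) {
  metal <- match.arg(metal, c("Cu", "Co"))
  if (!is.finite(logK_MBL) || !is.finite(logK_MgBL)) {
    stop("logK_MBL and logK_MgBL must be finite", call. = FALSE)
  }
  if (length(logK_IMBL) > 0) {
    if (is.null(names(logK_IMBL)) || any(names(logK_IMBL) == "")) {
      stop("logK_IMBL must be a named vector", call. = FALSE)
    }
    known <- names(.species_charge)
    bad <- setdiff(names(logK_IMBL), known)
    if (length(bad) > 0) {
      stop("logK_IMBL names are not tracked species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(is.na(logK_IMBL)) || any(logK_IMBL == Inf)) {
      stop("logK_IMBL values must be finite or -Inf", call. = FALSE)
    }
  }
  if (!is.finite(f50) || f50 <= 0 || f50 >= 1) {
    stop("f50 must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(metal = metal, logK_MBL = logK_MBL, logK_MgBL = logK_MgBL,
         logK_IMBL = logK_IMBL, f50 = f50, beta = beta),
    class = "blm_parameters"
  )
}

#' @export
print.blm_parameters <- function(x, ...) {
  cat(sprintf("<blm_parameters> %s-BLM\n", x$metal))
  cat(sprintf("  logK_%sBL = %.2f, logK_MgBL = %.2f\n",
              x$metal, x$logK_MBL, x$logK_MgBL))
  if (length(x$logK_IMBL) > 0) {
    cat("  complexes: ",
        paste(sprintf("logK_%sBL = %.2f", names(x$logK_IMBL), x$logK_IMBL),
              collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  f50 = %.3f, beta = %.3f\n", x$f50, x$beta))
  invisible(x)
}

#' Published wheat-root BLM parameter sets for Cu and Co
#'
#' The single-metal constants estimated for acute Cu and Co inhibition of
#' wheat root elongation: for Cu, logK_CuBL 5.87 with toxic complexes
#' CuHCO3+ (5.67), CuCO3(aq) (5.44) and CuOH+ (5.07), Mg competition 2.93,
#' f50 0.28 and slope 2.73; for Co, logK_CoBL 4.72 with CoHCO3+ (5.81), Mg
#' competition 3.84, f50 0.66 and slope 4.59. These serve as reference truth
#' for simulation and as defaults for mixture toxic-unit calculations.
#'
#' @param metal `"Cu"` or `"Co"`.
#' @return A [blm_parameters()] object.
#' @export
published_blm_parameters <- function(metal = c("Cu", "Co")) {
  metal <- match.arg(metal)
  if (metal == "Cu") {
    blm_parameters("Cu", logK_MBL = 5.87, logK_MgBL = 2.93,
                   logK_IMBL = c(CuHCO3 = 5.67, CuCO3 = 5.44, CuOH = 5.07),
                   f50 = 0.28, beta = 2.73)
  } else {
    blm_parameters("Co", logK_MBL = 4.72, logK_MgBL = 3.84,
                   logK_IMBL = c(CoHCO3 = 5.81),
                   f50 = 0.66, beta = 4.59)
  }
}

# numerator of the site-occupancy expression: K_MBL{M2+} + sum K_IMBL{IM}
.bl_numerator <- function(activities, params) {
  act_m <- activities[params$metal]
  if (is.na(act_m)) {
    stop("missing activity for ", params$metal, call. = FALSE)
  }
  num <- 10^params$logK_MBL * act_m
  if (length(params$logK_IMBL) > 0) {
    act_im <- activities[names(params$logK_IMBL)]
    if (any(is.na(act_im))) {
      stop("missing activities for complex(es): ",
           paste(names(params$logK_IMBL)[is.na(act_im)], collapse = ", "),
           call. = FALSE)
    }
    on <- is.finite(params$logK_IMBL)
    num <- num + sum(10^params$logK_IMBL[on] * act_im[on])
  }
  unname(num)
}

#' Fraction of biotic ligand sites occupied by a metal's toxic species
#'
#' Site occupancy f = N / (N + sum over competitors + \[1\]), where the
#' numerator N = K_MBL\{M2+\} + sum(K_IMBL \{IM\}) collects the metal's toxic
#' species and the denominator adds Mg2+ competition, any co-exposed metal's
#' toxic species (via `competitors`), and — by default — the unity term
#' representing unoccupied sites. Without the unity term the expression
#' reproduces the literal ratio-of-bound-forms convention, under which the
#' predicted EC50 vanishes as \{Mg2+\} goes to 0; the conventional saturable
#' form (unity on) is the default.
#'
#' @param spec A `speciation_result` (or any list with an `activities`
#'   vector naming the needed species).
#' @param params [blm_parameters()] of the metal of interest.
#' @param competitors Optional list of [blm_parameters()] for co-exposed
#'   metals whose toxic species compete for the same sites (used for mixture
#'   occupancies).
#' @param include_unity_term Include the "+1" unoccupied-site term.
#' @return Occupied fraction in \[0, 1\].
#' @examples
#' sp <- speciate(solution_composition(K_mM = 0.08, Na_mM = 2, Ca_mM = 0.2,
#'                                     Mg_mM = 0.05, Cl_mM = 2.48,
#'                                     SO4_mM = 0.05, pH = 6, Cu_uM = 1))
#' fraction_occupied(sp, published_blm_parameters("Cu"))
#' @export
fraction_occupied <- function(spec, params, competitors = list(),
                              include_unity_term = TRUE) {
  stopifnot(inherits(params, "blm_parameters"))
  act <- spec$activities
  num <- .bl_numerator(act, params)
  den <- num
  for (cp in competitors) den <- den + .bl_numerator(act, cp)
  act_mg <- act["Mg"]
  if (is.na(act_mg)) stop("missing activity for Mg", call. = FALSE)
  den <- den + 10^params$logK_MgBL * unname(act_mg)
  if (include_unity_term) den <- den + 1
  if (den == 0) return(0)
  num / den
}

#' EC50 as free-ion activity predicted by the BLM for a given medium
#'
#' Inverts the occupancy model at f = f50: with theta = f50 / (1 - f50),
#' EC50\{M2+\} = theta * (1 + K_MgBL \{Mg2+\}) / (K_MBL + sum K_IMBL lambda_IM),
#' where lambda_IM = \{IM\}/\{M2+\} are the pH/pCO2-fixed complex-to-free-ion
#' activity ratios reported by [speciate()]. The prediction is exactly linear
#' in \{Mg2+\} at fixed pH, and decreasing in each lambda (toxic complexes
#' make the free ion look more potent). With `include_unity_term = FALSE`
#' the leading 1 in the numerator is dropped (literal bound-forms convention).
#'
#' @param params [blm_parameters()].
#' @param spec `speciation_result` of the background medium (typically
#'   speciated without the metal dose).
#' @param include_unity_term See [fraction_occupied()].
#' @return EC50 as free-ion activity (mol/L).
#' @examples
#' sp <- speciate(solution_composition(K_mM = 0.08, Na_mM = 2, Ca_mM = 0.2,
#'                                     Mg_mM = 0.05, Cl_mM = 2.48,
#'                                     SO4_mM = 0.05, pH = 6))
#' predict_ec50_free_ion(published_blm_parameters("Cu"), sp) * 1e6  # uM
#' @export
predict_ec50_free_ion <- function(params, spec, include_unity_term = TRUE) {
  stopifnot(inherits(params, "blm_parameters"))
  if (!is.finite(params$f50) || params$f50 <= 0 || params$f50 >= 1) {
    stop("f50 must lie strictly in (0, 1)", call. = FALSE)
  }
  theta <- params$f50 / (1 - params$f50)
  lam <- spec$lambda[[params$metal]]
  denom <- 10^params$logK_MBL
  if (length(params$logK_IMBL) > 0) {
    on <- is.finite(params$logK_IMBL)
    if (any(on)) {
      lam_im <- lam[names(params$logK_IMBL)[on]]
      if (any(is.na(lam_im))) {
        stop("speciation result lacks complex ratio(s): ",
             paste(names(params$logK_IMBL)[on][is.na(lam_im)],
                   collapse = ", "), call. = FALSE)
      }
      denom <- denom + sum(10^params$logK_IMBL[on] * lam_im)
    }
  }
  numer <- 10^params$logK_MgBL * unname(spec$activities["Mg"])
  if (include_unity_term) numer <- numer + 1
  theta * numer / denom
}

#' Ordinary least-squares regression of EC50 on free Mg2+ activity
#'
#' Under the free-ion BLM with no toxic complexes, EC50\{M2+\} is linear in
#' \{Mg2+\} with slope/intercept = K_MgBL; this regression is the classical
#' graphical estimate of the competition constant and a first check of BLM
#' behaviour in an Mg gradient.
#'
#' @param ec50 EC50 values as free-ion activity (mol/L or consistent units).
#' @param mg_activity Free Mg2+ activities (mol/L), same length.
#' @return List with `slope`, `intercept`, `r2`, `p` (slope t-test),
#'   `k_mg` (= slope/intercept, the implied competition constant) and the
#'   underlying `lm` fit.
#' @examples
#' linear_mg_regression(c(1, 2, 3), c(0.1, 0.2, 0.3))
#' @export
linear_mg_regression <- function(ec50, mg_activity) {
  if (length(ec50) != length(mg_activity)) {
    stop("ec50 and mg_activity must have equal length", call. = FALSE)
  }
  if (length(ec50) < 3) stop("need >= 3 points", call. = FALSE)
  if (length(unique(mg_activity)) < 2) {
    warning("rank-deficient design: Mg activities are not distinct")
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                p = NA_real_, k_mg = NA_real_, fit = NULL))
  }
  fit <- stats::lm(ec50 ~ mg_activity)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  list(slope = slope, intercept = intercept,
       r2 = sm$r.squared, p = sm$coefficients[2, 4],
       k_mg = slope / intercept, fit = fit)
}

# identifiability screen over the media design
.check_design <- function(media) {
  mg <- vapply(media, function(m) m$totals[["Mg"]], numeric(1))
  ph <- vapply(media, function(m) m$pH, numeric(1))
  n_mg <- max(vapply(split(mg, ph), function(v) length(unique(v)),
                     integer(1)))
  n_ph <- max(vapply(split(ph, mg), function(v) length(unique(v)),
                     integer(1)))
  if (n_mg < 3) {
    stop(paste("non-identifiable design: need >= 3 distinct Mg levels at",
               "a fixed pH (Mg axis deficient)"), call. = FALSE)
  }
  if (n_ph < 3) {
    stop(paste("non-identifiable design: need >= 3 distinct pH levels at",
               "a fixed Mg (pH axis deficient)"), call. = FALSE)
  }
  invisible()
}

#' Estimate single-metal BLM constants from bioassay series
#'
#' Joint nonlinear least squares of the BLM over bioassays spanning an Mg
#' gradient at fixed pH and a pH gradient at fixed Mg. Two data levels are
#' supported:
#'
#' * **EC50 level** (`ec50` given): the loss is on log10 EC50\{M2+\} across
#'   media, with predictions from [predict_ec50_free_ion()]. At this level
#'   the occupancy scale is structurally non-identifiable — scaling K_MBL and
#'   every K_IMBL by c while moving the f50 odds by the same factor leaves
#'   every EC50 unchanged — so `f50` must be supplied and is held fixed
#'   (conventionally it comes from the occupancy-scale dose-response of the
#'   same data, or an independent estimate).
#' * **Response level** (`response` given): the loss is on RNE (%), with
#'   RNE = 100/(1 + (f/f50)^beta) and f from [fraction_occupied()]. The
#'   unity (unoccupied-site) term makes the occupancy scale weakly
#'   identifiable here, so `f50` and `beta` are estimated unless fixed.
#'
#' Optimisation uses Levenberg-Marquardt with multi-start over a coarse
#' parameter grid; logK parameters are bounded in \[0, 10\] and f50 in
#' \[0.01, 0.99\]. Ties are broken by lowest residual, then lowest f50.
#'
#' @param media List of [solution_composition()] background media (one per
#'   bioassay set).
#' @param metal `"Cu"` or `"Co"`.
#' @param ec50 Numeric vector of observed EC50\{M2+\} (mol/L), one per
#'   medium, for the EC50-level fit.
#' @param response Data frame for the response-level fit with columns
#'   `medium` (index into `media`), `dose` (total metal, mol/L) and `rne`
#'   (percent).
#' @param complexes Character vector of toxic complex species to include
#'   (default: the metal's carbonate/hydroxide set for Cu, bicarbonate for
#'   Co). Empty vector fits the classical free-ion BLM.
#' @param f50 Fixed occupied fraction at 50% effect. Required for the
#'   EC50-level fit; optional (fixes the parameter) at response level.
#' @param beta Fixed slope for the response-level fit; `NULL` estimates it.
#' @param include_unity_term See [fraction_occupied()].
#' @param constants Equilibrium constants for the speciation step.
#' @param include_ion_pairs Passed to [speciate()].
#' @return Object of class `blm_fit`: list with `parameters`
#'   ([blm_parameters()]), `se` (named approximate standard errors),
#'   `residuals`, `deviance`, `r2`, `n`, `loss` (`"log10_ec50"` or `"rne"`),
#'   `converged`.
#' @examples
#' \donttest{
#' design <- default_design()
#' truth <- published_blm_parameters("Co")
#' specs <- lapply(design$media, speciate)
#' ec50 <- vapply(specs, function(s) predict_ec50_free_ion(truth, s),
#'                numeric(1))
#' fit <- fit_single_metal_blm(design$media, "Co", ec50 = ec50,
#'                             f50 = truth$f50)
#' fit$parameters
#' }
#' @export
fit_single_metal_blm <- function(media, metal = c("Cu", "Co"),
                                 ec50 = NULL, response = NULL,
                                 complexes = NULL, f50 = NULL, beta = NULL,
                                 include_unity_term = TRUE,
                                 constants = default_constants(),
                                 include_ion_pairs = TRUE) {
  metal <- match.arg(metal)
  if (is.null(ec50) && is.null(response)) {
    stop("supply either ec50 (per medium) or response (dose-response data)",
         call. = FALSE)
  }
  .check_design(media)
  if (is.null(complexes)) {
    complexes <- if (metal == "Cu") c("CuHCO3", "CuCO3", "CuOH") else "CoHCO3"
  }

  make_params <- function(logK_M, logK_Mg, logK_IM, f50v, betav) {
    blm_parameters(metal, logK_MBL = logK_M, logK_MgBL = logK_Mg,
                   logK_IMBL = stats::setNames(logK_IM, complexes),
                   f50 = f50v, beta = if (is.null(betav)) NA_real_ else betav)
  }
  nc <- length(complexes)

  if (!is.null(ec50)) {
    if (length(ec50) != length(media)) {
      stop("ec50 must have one value per medium", call. = FALSE)
    }
    if (any(ec50 <= 0)) stop("ec50 values must be > 0", call. = FALSE)
    if (is.null(f50)) {
      stop(paste("f50 must be fixed for the EC50-level fit: the occupancy",
                 "scale (K_MBL, K_IMBL, f50) is not identifiable from EC50",
                 "data alone"), call. = FALSE)
    }
    specs <- lapply(media, speciate, constants = constants,
                    include_ion_pairs = include_ion_pairs)
    obs <- log10(ec50)
    resid_fn <- function(p) {
      pars <- make_params(p[1], p[2], if (nc > 0) p[3:(2 + nc)] else
                            numeric(0), f50, NULL)
      pred <- vapply(specs, function(s)
        predict_ec50_free_ion(pars, s, include_unity_term), numeric(1))
      log10(pred) - obs
    }
    npar <- 2 + nc
    starts <- as.matrix(expand.grid(
      logK_M = c(3, 5, 7), logK_Mg = c(2, 3.5, 5)))
    if (nc > 0) {
      starts <- cbind(starts, matrix(rep(starts[, 1], nc), ncol = nc))
    }
    lower <- rep(0, npar); upper <- rep(10, npar)
    best <- .run_multistart(resid_fn, starts, lower, upper)
    p <- best$par
    pars <- make_params(p[1], p[2], if (nc > 0) p[3:(2 + nc)] else
                          numeric(0), f50, NULL)
    se <- .lm_se(best, length(obs), npar)
    names(se) <- c(paste0("logK_", metal, "BL"), "logK_MgBL",
                   if (nc > 0) paste0("logK_", complexes, "BL"))
    res <- best$fvec
    r2 <- 1 - sum(res^2) / sum((obs - mean(obs))^2)
    return(structure(
      list(parameters = pars, se = se, residuals = res,
           deviance = best$deviance, r2 = r2, n = length(obs),
           loss = "log10_ec50", converged = best$info %in% 1:4),
      class = "blm_fit"))
  }

  # response-level fit
  stopifnot(is.data.frame(response),
            all(c("medium", "dose", "rne") %in% names(response)))
  key <- paste(response$medium, response$dose)
  uniq <- !duplicated(key)
  spec_cache <- lapply(which(uniq), function(i) {
    m <- media[[response$medium[i]]]
    dose_uM <- response$dose[i] * 1e6
    dosed <- if (metal == "Cu") with_metal_dose(m, Cu_uM = dose_uM) else
      with_metal_dose(m, Co_uM = dose_uM)
    speciate(dosed, constants = constants,
             include_ion_pairs = include_ion_pairs)
  })
  names(spec_cache) <- key[uniq]
  specs <- spec_cache[key]
  obs <- response$rne

  fix_f50 <- !is.null(f50)
  fix_beta <- !is.null(beta)
  unpack <- function(p) {
    i <- 2 + nc
    f50v <- if (fix_f50) f50 else stats::plogis(p[i + 1])
    betav <- if (fix_beta) beta else
      exp(p[i + 1 + as.integer(!fix_f50)])
    list(pars = make_params(p[1], p[2], if (nc > 0) p[3:i] else numeric(0),
                            f50v, betav),
         f50 = f50v, beta = betav)
  }
  resid_fn <- function(p) {
    u <- unpack(p)
    fvals <- vapply(specs, fraction_occupied, numeric(1), params = u$pars,
                    include_unity_term = include_unity_term)
    100 / (1 + (fvals / u$f50)^u$beta) - obs
  }
  core <- as.matrix(expand.grid(logK_M = c(3, 5, 7), logK_Mg = c(2.5, 4.5)))
  if (nc > 0) {
    core <- cbind(core, matrix(rep(core[, 1], nc), ncol = nc))
  }
  extra <- NULL
  if (!fix_f50) extra <- cbind(extra, qf50 = stats::qlogis(c(0.2, 0.5, 0.8)))
  if (!fix_beta) {
    eb <- log(c(1.5, 4))
    extra <- if (is.null(extra)) cbind(lbeta = eb) else
      as.matrix(expand.grid(qf50 = stats::qlogis(c(0.2, 0.5, 0.8)),
                            lbeta = eb))
  }
  if (is.null(extra)) {
    starts <- core
  } else {
    idx <- expand.grid(i = seq_len(nrow(core)), j = seq_len(nrow(extra)))
    starts <- cbind(core[idx$i, , drop = FALSE],
                    extra[idx$j, , drop = FALSE])
  }
  npar <- ncol(starts)
  lower <- c(rep(0, 2 + nc),
             if (!fix_f50) stats::qlogis(0.01),
             if (!fix_beta) log(0.1))
  upper <- c(rep(10, 2 + nc),
             if (!fix_f50) stats::qlogis(0.99),
             if (!fix_beta) log(50))
  best <- .run_multistart(resid_fn, starts, lower, upper,
                          tiebreak_f50 = if (!fix_f50) 2 + nc + 1 else NULL)
  u <- unpack(best$par)
  se <- .lm_se(best, length(obs), npar)
  res <- best$fvec
  r2 <- 1 - sum(res^2) / sum((obs - mean(obs))^2)
  structure(
    list(parameters = u$pars, se = se, residuals = res,
         deviance = best$deviance, r2 = r2, n = length(obs),
         loss = "rne", converged = best$info %in% 1:4),
    class = "blm_fit")
}

# multi-start Levenberg-Marquardt; ties by deviance then (optionally) low f50
.run_multistart <- function(resid_fn, starts, lower, upper,
                            tiebreak_f50 = NULL) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best)) { best <- fit; next }
    better <- fit$deviance < best$deviance * (1 - 1e-10)
    tie <- !better && fit$deviance <= best$deviance * (1 + 1e-10)
    if (better ||
        (tie && !is.null(tiebreak_f50) &&
         fit$par[tiebreak_f50] < best$par[tiebreak_f50])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("BLM fit failed: no start converged", call. = FALSE)
  best
}

.lm_se <- function(fit, n, npar) {
  if (n <= npar || fit$deviance <= 0) return(rep(NA_real_, npar))
  out <- tryCatch({
    s2 <- fit$deviance / (n - npar)
    v <- diag(s2 * solve(fit$hessian))
    ifelse(v >= 0, sqrt(v), NA_real_)
  }, error = function(e) rep(NA_real_, npar))
  out
}

#' @export
print.blm_fit <- function(x, ...) {
  cat(sprintf("<blm_fit> %s, loss = %s, n = %d\n",
              x$parameters$metal, x$loss, x$n))
  print(x$parameters)
  cat(sprintf("  deviance = %.4g, R2 = %.4f, converged: %s\n",
              x$deviance, x$r2, x$converged))
  invisible(x)
}
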