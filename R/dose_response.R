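#' Relative net elongation of a root-growth bioassay
#'
#' RNE% = 100 * (RE_t - RE_0) / (RE_c - RE_0): net root growth under a metal
#' treatment as a percentage of net control growth, where RE_t is the root
#' length after exposure, RE_0 the length at the start, and RE_c the control
#' length at the end. Individual replicate values may fall below 0 or exceed
#' 100; no clipping is applied.
#'
#' @param re_t Root length in the treatment (cm). Vectorized.
#' @param re_0 Original root length (cm).
#' @param re_c Root length in the control (cm); must exceed `re_0`.
#' @return RNE in percent.
#' @examples
#' relative_net_elongation(5, 1, 9)  # 50
#' @export
relative_net_elongation <- function(re_t, re_0, re_c) {
  if (any(c(re_t, re_0, re_c) < 0)) {
    stop("root lengths must be >= 0", call. = FALSE)
  }
  if (any(re_c == re_0)) {
    stop("degenerate control: control growth is zero (re_c == re_0)",
         call. = FALSE)
  }
  100 * (re_t - re_0) / (re_c - re_0)
}

#' Two-parameter log-logistic dose-response curve
#'
#' R(x) = 100 / (1 + (x / x50)^beta), the standard inhibition model with the
#' upper asymptote fixed at 100% and the lower at 0%. The response is 100 at
#' x = 0, exactly 50 at x = x50, and strictly decreasing for beta > 0.
#'
#' @param x Exposure (free-ion activity in mol/L, or toxic units). `>= 0`,
#'   vectorized.
#' @param x50 Exposure at 50% response (> 0).
#' @param beta Slope parameter (> 0).
#' @return Response in percent.
#' @examples
#' loglogistic_response(c(0, 1, 2), x50 = 1, beta = 3.76)
#' @export
loglogistic_response <- function(x, x50, beta) {
  if (any(x < 0)) stop("exposure x must be >= 0", call. = FALSE)
  if (x50 <= 0) stop("x50 must be > 0", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  100 / (1 + (x / x50)^beta)
}

#' Fit the log-logistic dose-response model
#'
#' Nonlinear least squares of observed response (percent) on exposure, with
#' x50 log-parameterised for positivity and multi-start initialisation from a
#' log-spaced grid over the dose range. Responses are used untransformed and
#' unclipped. All replicate points are fitted unless `aggregate = "mean"`
#' averages replicates per dose first.
#'
#' @param x Exposure values (>= 0; zero-dose controls are allowed).
#' @param response Observed response (percent), same length as `x`.
#' @param aggregate `"none"` (default; fit all replicate points) or `"mean"`
#'   (fit treatment means per distinct dose).
#' @param n_starts Number of x50 starting values on the log grid.
#' @param beta_starts Starting slope values tried at each x50 start.
#' @return An object of class `loglogistic_fit`: list with `x50`, `beta`,
#'   `se_x50`, `se_beta`, `r2`, `n_points`, `fitted`, `residuals`,
#'   `deviance`, `converged`.
#' @examples
#' x <- c(0, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2)
#' y <- loglogistic_response(x, 0.41, 3.76)
#' fit <- fit_loglogistic(x, y)
#' fit$x50
#' @export
fit_loglogistic <- function(x, response, aggregate = c("none", "mean"),
                            n_starts = 5, beta_starts = c(1, 3)) {
  aggregate <- match.arg(aggregate)
  if (length(x) != length(response)) {
    stop("x and response must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(response)
  x <- x[ok]; response <- response[ok]
  if (any(x < 0)) stop("exposure x must be >= 0", call. = FALSE)

  if (aggregate == "mean") {
    means <- tapply(response, x, mean)
    x <- as.numeric(names(means))
    response <- as.numeric(means)
  }

  levels_x <- sort(unique(x))
  if (length(levels_x) < 4L) {
    stop("non-identifiable: need >= 4 distinct exposure levels",
         call. = FALSE)
  }
  level_means <- tapply(response, x, mean)
  if (all(level_means > 50) || all(level_means < 50)) {
    stop(paste("non-identifiable: all dose-level mean responses lie on one",
               "side of 50%"), call. = FALSE)
  }

  xp <- levels_x[levels_x > 0]
  x50_starts <- 10^seq(log10(min(xp)), log10(max(xp)), length.out = n_starts)

  resid_fn <- function(p) {
    loglogistic_response(x, 10^p[1], exp(p[2])) - response
  }
  best <- NULL
  for (s in x50_starts) {
    for (b0 in beta_starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(log10(s), log(b0)), fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }
  if (is.null(best)) {
    stop("log-logistic fit failed: no optimiser start converged",
         call. = FALSE)
  }

  x50 <- 10^best$par[1]
  beta <- exp(best$par[2])
  fitted <- loglogistic_response(x, x50, beta)
  res <- response - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  # delta-method SEs on the natural scale from the transformed-parameter
  # covariance; NA when the information matrix is singular (e.g. exact fits)
  se <- c(NA_real_, NA_real_)
  npar <- 2L
  if (length(x) > npar && ss_res > 0) {
    cov_t <- tryCatch({
      s2 <- ss_res / (length(x) - npar)
      s2 * solve(best$hessian)
    }, error = function(e) NULL)
    if (!is.null(cov_t) && all(is.finite(diag(cov_t))) &&
        all(diag(cov_t) >= 0)) {
      se <- sqrt(diag(cov_t)) * c(x50 * log(10), beta)
    }
  }

  structure(
    list(x50 = unname(x50), beta = unname(beta),
         se_x50 = unname(se[1]), se_beta = unname(se[2]),
         r2 = r2, n_points = length(x), fitted = fitted, residuals = res,
         deviance = best$deviance,
         converged = best$info %in% 1:4),
    class = "loglogistic_fit"
  )
}

#' @export
print.loglogistic_fit <- function(x, ...) {
  cat("<loglogistic_fit>\n")
  cat(sprintf("  x50 = %.4g (se %.3g), beta = %.3f (se %.3g)\n",
              x$x50, x$se_x50, x$beta, x$se_beta))
  cat(sprintf("  n = %d, R2 = %.4f\n", x$n_points, x$r2))
  invisible(x)
}
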