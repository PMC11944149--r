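# Boltzmann distribution of elementary-mode usage probabilities and the fit
# of the evolutionary fraction b from a measured overall reaction entropy.

#' Boltzmann usage probabilities over elementary modes
#'
#' Maximizing the rate of entropy production of the culture at steady state,
#' subject to a fixed macroscopic production rate and normalization, yields a
#' Boltzmann-type distribution over modes:
#' \deqn{p_j = \exp(-\hat\xi x_j /(b Q R)) / Z, \quad
#'       Z = \sum_j \exp(-\hat\xi x_j/(b Q R))}
#' where \eqn{x_j} is the mode's reaction entropy \eqn{\Delta s_j}
#' (type 2 variant) or its affinity over temperature \eqn{A_j/T} (type 1
#' variant), \eqn{\hat\xi} is the specific glucose uptake rate, \eqn{b} the
#' fraction of the evolutionarily attainable maximum uptake rate, \eqn{Q = 1}
#' per (h gCDW) keeps the exponent dimensionless, and \eqn{R} is the gas
#' constant. Computed with log-sum-exp stabilization; \eqn{c = -\ln Z}.
#'
#' @param x per-mode values, J/(K mol glucose): \code{ds} or
#'   \code{affinity/T}.
#' @param xi_hat specific glucose uptake rate, mol/(h gCDW) (>= 0).
#' @param b evolutionary fraction, > 0.
#' @param Q normalizing rate constant, 1/(h gCDW).
#' @param R gas constant, J/(K mol).
#' @return list: \code{p}, \code{Z}, \code{logZ}, \code{c} (= -logZ).
#' @examples
#' boltzmann_probabilities(c(1000, 2000, 3000), xi_hat = 0, b = 0.4)$p
#' @export
boltzmann_probabilities <- function(x, xi_hat, b, Q = 1, R = R_GAS) {
  if (b <= 0) stop_config("b must be positive")
  if (xi_hat < 0) stop_config("xi_hat must be >= 0")
  if (length(x) == 0L) stop_config("empty mode set")
  u <- -xi_hat * x / (b * Q * R)
  m <- max(u)
  e <- exp(u - m)
  Zs <- sum(e)
  logZ <- m + log(Zs)
  list(p = e / Zs, Z = exp(logZ), logZ = logZ, c = -logZ)
}

# Expectation of x under the Boltzmann distribution at b.
.boltzmann_mean <- function(x, xi_hat, b, Q = 1, R = R_GAS) {
  sum(boltzmann_probabilities(x, xi_hat, b, Q, R)$p * x)
}

#' Fit the evolutionary fraction b from a measured reaction entropy
#'
#' Finds \eqn{b} such that the distribution's expectation matches the
#' measured overall value: \eqn{\sum_j p_j(b)\,\Delta s_j = \Delta S_R}
#' (or, for the affinity variant, the measured \eqn{A_R/T}). The expectation
#' is strictly increasing in \eqn{b}, from \eqn{\min_j x_j} (as
#' \eqn{b \to 0}) to the uniform mean (as \eqn{b \to \infty}), so the root
#' is unique inside the open interval. Two routes are provided: a bracketed
#' scalar solve on \eqn{\ln b} (default), and the Levenberg-Marquardt
#' least-squares formulation in the unknowns \eqn{(b, c)} via
#' \code{minpack.lm} as a cross-check.
#'
#' @param x per-mode values (J/(K mol glucose)): \code{ds} for the entropy
#'   (type 2) variant or \code{affinity/T} for the affinity (type 1) variant.
#' @param xi_hat specific glucose uptake rate, mol/(h gCDW), > 0.
#' @param target measured overall value on the same scale as \code{x}.
#' @param method \code{"root"} (bracketed solve) or \code{"lm"}
#'   (Levenberg-Marquardt).
#' @param b_range bracket for b.
#' @param variant label stored in the fit (\code{"entropy"} or
#'   \code{"affinity"}).
#' @param Q,R constants as in [boltzmann_probabilities()].
#' @return a \code{maxent_fit}: variant, b, c, Z, logZ, p, xi_hat, target,
#'   method.
#' @export
fit_b <- function(x, xi_hat, target, method = c("root", "lm"),
                  b_range = c(1e-4, 1e4), variant = "entropy",
                  Q = 1, R = R_GAS) {
  method <- match.arg(method)
  if (xi_hat <= 0) stop_config("xi_hat must be positive to fit b")
  lo <- min(x)
  uniform_mean <- mean(x)
  m_lo <- .boltzmann_mean(x, xi_hat, b_range[1], Q, R)
  m_hi <- .boltzmann_mean(x, xi_hat, b_range[2], Q, R)
  if (target <= m_lo)
    stop_infeasible("measured value ", signif(target, 6),
                    " at or below the attainable lower bound ",
                    signif(m_lo, 6), " (minimum mode value ", signif(lo, 6),
                    ")")
  if (target >= m_hi)
    stop_infeasible("measured value ", signif(target, 6),
                    " at the uniform limit: expectation cannot exceed ",
                    signif(m_hi, 6), " (uniform mean ",
                    signif(uniform_mean, 6), ") within b <= ", b_range[2])
  b <- if (method == "root") {
    f <- function(logb) .boltzmann_mean(x, xi_hat, exp(logb), Q, R) - target
    r <- stats::uniroot(f, log(b_range), tol = 1e-12)
    exp(r$root)
  } else {
    resid <- function(par) {
      bb <- exp(par[[1]]); cc <- par[[2]]
      u <- -xi_hat * x / (bb * Q * R) + cc
      u <- pmin(u, 700)  # overflow guard; solution region is unaffected
      p <- exp(u)
      c(sum(p) - 1, (sum(p * x) - target) / max(abs(target), 1))
    }
    start_b <- sqrt(prod(b_range))
    c0 <- -boltzmann_probabilities(x, xi_hat, start_b, Q, R)$logZ
    fit <- minpack.lm::nls.lm(par = c(log(start_b), c0), fn = resid,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-14, ptol = 1e-14))
    exp(fit$par[[1]])
  }
  bp <- boltzmann_probabilities(x, xi_hat, b, Q, R)
  structure(list(variant = variant, b = b, c = bp$c, Z = bp$Z,
                 logZ = bp$logZ, p = bp$p, xi_hat = xi_hat, target = target,
                 method = method, Q = Q, R = R),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat("maxent_fit (", x$variant, " variant): b = ", signif(x$b, 6),
      ", c = ", signif(x$c, 4), ", n = ", length(x$p), " modes\n", sep = "")
  invisible(x)
}

#' Maximum rates implied by the evolutionary fraction b
#'
#' Since the measured uptake is the fraction \eqn{b} of the attainable
#' maximum, \eqn{\mu_{max} = \mu/b}, \eqn{q_{s,max} = q_s/b}, and the minimum
#' doubling time is \eqn{\tau_{min} = \ln 2/\mu_{max}} in minutes.
#'
#' @param mu measured specific growth rate, 1/h.
#' @param qs measured specific glucose uptake rate, mmol/(h gCDW), positive
#'   magnitude.
#' @param b fitted evolutionary fraction.
#' @return list: \code{mu_max} (1/h), \code{qs_max} (mmol/(h gCDW), positive
#'   magnitude; negate for the uptake sign convention), \code{tau_min}
#'   (minutes).
#' @export
predict_max_rates <- function(mu, qs, b) {
  if (b <= 0) stop_config("b must be positive")
  mu_max <- mu / b
  list(mu_max = mu_max, qs_max = qs / b, tau_min = log(2) / mu_max * 60)
}

#' Measured growth parameters and fitted constants of the evolved strains
#'
#' The printed strain table shipped with the package: wild type plus six
#' adaptively evolved E. coli lineages, with measured specific growth rate
#' \code{mu} (1/h), glucose uptake \code{qs} (mmol/(h gCDW)), biomass yield
#' \code{yield_bg} (g/g), and the fitted constants \code{b} and \code{c}.
#'
#' @return data.frame, one row per strain.
#' @export
strain_table <- function() {
  utils::read.table(system.file("extdata", "strain_parameters.tsv",
                                package = "entroflux"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Fit both distribution variants and compare their predictions
#'
#' Fits the entropy (type 2) and affinity (type 1) variants to the same
#' strain observation and reports b, c, the implied maximum growth rate and
#' minimum doubling time, and which variant predicts a doubling time shorter
#' than the current one (the biologically consistent direction under
#' selection for faster growth). With no heat effects (all \code{dh = 0})
#' the variants coincide.
#'
#' @param mode_thermo \code{mode_thermo} data.frame (columns ds, dg,
#'   affinity).
#' @param obs list/row with \code{mu}, \code{qs} (mmol/(h gCDW)), and the
#'   measured overall values \code{dS_R} (J/(K mol)) and \code{dG_R} (J/mol)
#'   (the latter only needed for the affinity variant).
#' @param T temperature, K.
#' @return data.frame with one row per variant: b, c, mu_max, tau_min,
#'   shorter_than_current.
#' @export
compare_variants <- function(mode_thermo, obs, T = 310.15) {
  xi_hat <- obs$qs / 1000
  fits <- list(
    entropy = fit_b(mode_thermo$ds, xi_hat, obs$dS_R, variant = "entropy"),
    affinity = fit_b(mode_thermo$affinity / T, xi_hat, -obs$dG_R / T,
                     variant = "affinity"))
  tau_now <- log(2) / obs$mu * 60
  do.call(rbind, lapply(names(fits), function(v) {
    f <- fits[[v]]
    mr <- predict_max_rates(obs$mu, obs$qs, f$b)
    data.frame(variant = v, b = f$b, c = f$c, mu_max = mr$mu_max,
               tau_min = mr$tau_min,
               shorter_than_current = mr$tau_min < tau_now,
               stringsAsFactors = FALSE)
  }))
}

#' Export a fitted probability vector as TSV
#' @param fit a \code{maxent_fit}.
#' @param path output path.
#' @export
write_probabilities <- function(fit, path) {
  df <- data.frame(mode = seq_along(fit$p), p = fit$p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
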