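# Flux prediction from the fitted mode distribution and comparison with
# measured fluxes.

#' Overall growth stoichiometry from mode usage probabilities
#'
#' \eqn{\nu_i = \sum_j \nu_{j,i}\,p_j}: the probability-weighted average of
#' the glucose-normalized external stoichiometries, so the glucose
#' coefficient is exactly -1.
#'
#' @param p usage probabilities (sums to 1).
#' @param modes a glucose-normalized \code{efm_set}.
#' @return named vector of coefficients per mole glucose.
#' @export
overall_stoichiometry <- function(p, modes) {
  if (!isTRUE(modes$normalized))
    stop_config("modes must be glucose-normalized first")
  if (abs(sum(p) - 1) > 1e-8) stop_config("probabilities must sum to 1")
  nu <- as.numeric(p %*% modes$external)
  names(nu) <- colnames(modes$external)
  nu[modes$glucose_id] <- -1
  nu
}

#' Predicted external production/consumption rates
#'
#' \eqn{r_i = \sum_j \nu_{i,j}\,\hat\xi_j} with
#' \eqn{\hat\xi_j = p_j \hat\xi}; identically \eqn{\hat\xi\,\nu_i} with
#' \eqn{\nu_i} the overall stoichiometry.
#'
#' @param p usage probabilities.
#' @param modes glucose-normalized \code{efm_set}.
#' @param xi_hat specific glucose uptake rate, mol/(h gCDW).
#' @param percent report rates relative to glucose uptake = 100 percent.
#' @return named vector of rates, mol/(h gCDW) (or percent of glucose).
#' @export
external_rates <- function(p, modes, xi_hat, percent = FALSE) {
  r <- xi_hat * overall_stoichiometry(p, modes)
  if (percent) r / xi_hat * 100 else r
}

#' Predicted internal reaction rates
#'
#' \eqn{r_k = \sum_j p_j\,\hat\xi\,v_{k,j}} where \eqn{v_{k,j}} is mode j's
#' glucose-normalized flux through reaction k (reversible pairs already
#' recombined to net signed flux). The resulting rate vector lies in the
#' nullspace of the internal stoichiometric matrix.
#'
#' @inheritParams external_rates
#' @return named vector over reaction ids.
#' @export
internal_rates <- function(p, modes, xi_hat, percent = FALSE) {
  if (!isTRUE(modes$normalized))
    stop_config("modes must be glucose-normalized first")
  if (abs(sum(p) - 1) > 1e-8) stop_config("probabilities must sum to 1")
  r <- xi_hat * as.numeric(p %*% modes$fluxes)
  names(r) <- colnames(modes$fluxes)
  if (percent) r / xi_hat * 100 else r
}

#' Compare predicted with measured reaction rates
#'
#' Ordinary least squares of measured on predicted rates over the shared
#' reaction ids, on the percent-of-glucose scale by default. Outlier
#' exclusion is explicit and user-supplied, never automatic; excluded ids
#' are recorded in the result.
#'
#' @param predicted named vector of predicted rates.
#' @param measured data.frame with columns \code{reaction}, \code{value}
#'   (and optionally \code{sd}), or a named vector.
#' @param exclude reaction ids to drop before the regression.
#' @return a \code{flux_comparison}: data (reaction, measured, predicted,
#'   residual), \code{excluded}, \code{r_squared}, \code{slope},
#'   \code{intercept}, \code{n}.
#' @export
compare_to_measured <- function(predicted, measured, exclude = character()) {
  if (is.data.frame(measured)) {
    mv <- stats::setNames(measured$value, measured$reaction)
  } else mv <- measured
  ids <- setdiff(intersect(names(predicted), names(mv)), exclude)
  if (length(ids) < 3L)
    stop_config("fewer than 3 shared reactions after exclusion")
  fit <- stats::lm(mv[ids] ~ predicted[ids])
  co <- stats::coef(fit)
  y <- as.numeric(mv[ids])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    data = data.frame(reaction = ids, measured = y,
                      predicted = as.numeric(predicted[ids]),
                      residual = as.numeric(stats::residuals(fit)),
                      stringsAsFactors = FALSE),
    excluded = exclude,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    slope = as.numeric(co[2]),
    intercept = as.numeric(co[1]),
    n = length(ids)), class = "flux_comparison")
}

#' @export
print.flux_comparison <- function(x, ...) {
  cat("flux_comparison: n =", x$n, " R^2 =", signif(x$r_squared, 4),
      " slope =", signif(x$slope, 4),
      " intercept =", signif(x$intercept, 4), "\n")
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write a flux comparison report (TSV + JSON summary)
#' @param cmp a \code{flux_comparison}.
#' @param path_tsv,path_json output paths (either may be NULL).
#' @export
write_comparison <- function(cmp, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(cmp$data, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(r_squared = cmp$r_squared, slope = cmp$slope,
                              intercept = cmp$intercept, n = cmp$n,
                              excluded = cmp$excluded),
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(cmp)
}
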