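# Steady-state CSTR balances: outlet concentrations, gas/liquid partitioning,
# system entropy and Gibbs energy, type 1 / type 2 entropy production rates.
# The semicontinuous serial-transfer culture is approximated as a CSTR whose
# dilution rate equals the specific growth rate.

#' CSTR operating state
#'
#' @param feed named vector of feed concentrations, mol/L.
#' @param tau space time V/F, h.
#' @param xi_dot volumetric extent of the overall growth reaction, mol/(L h).
#' @param T temperature, K.
#' @param liquid_volume culture volume, L.
#' @param gas_flow aeration gas flow, L/h.
#' @param pressure total pressure, bar.
#' @return a \code{cstr_state} list.
#' @export
cstr_state <- function(feed, tau, xi_dot, T = 310.15,
                       liquid_volume = 0.015, gas_flow = 0.9,
                       pressure = 1) {
  if (tau <= 0) stop_config("space time tau must be positive")
  if (any(feed < 0)) stop_config("feed concentrations must be >= 0")
  structure(list(feed = feed, tau = tau, xi_dot = xi_dot, T = T,
                 liquid_volume = liquid_volume, gas_flow = gas_flow,
                 pressure = pressure), class = "cstr_state")
}

#' Outlet concentrations of a steady-state CSTR
#'
#' \code{c_i = c_i,in + tau * xi_dot * nu_i}. Slightly negative results
#' (within \code{tol}) are floored at zero with a warning; larger violations
#' indicate an infeasible operating point.
#'
#' @param state a [cstr_state()].
#' @param nu named overall stoichiometry per mole glucose (glucose -1).
#' @param tol absolute tolerance (mol/L) before an infeasibility error.
#' @return named vector of outlet concentrations, mol/L.
#' @export
outlet_concentrations <- function(state, nu, tol = 1e-9) {
  ids <- union(names(state$feed), names(nu))
  cin <- stats::setNames(rep(0, length(ids)), ids)
  cin[names(state$feed)] <- state$feed
  dn <- stats::setNames(rep(0, length(ids)), ids)
  dn[names(nu)] <- nu
  ci <- cin + state$tau * state$xi_dot * dn
  neg <- ci < 0
  if (any(ci < -tol))
    stop_infeasible("infeasible operating point: outlet concentration of ",
                    paste(ids[ci < -tol], collapse = ", "),
                    " would be negative")
  if (any(neg)) {
    warning("outlet concentration floored at 0 for: ",
            paste(ids[neg], collapse = ", "))
    ci[neg] <- 0
  }
  ci
}

#' Saturation vapor pressure of water (Antoine equation)
#' @param T temperature, K.
#' @return vapor pressure, bar.
#' @export
water_vapor_pressure <- function(T) {
  Tc <- T - 273.15
  p_mmHg <- 10^(8.07131 - 1730.63 / (233.426 + Tc))
  p_mmHg * 1.01325 / 760
}

#' Gas-phase mole fraction of a species leaving the CSTR
#'
#' Nonvolatile solutes stay in the liquid (fraction 0); sparingly soluble
#' gases (O2, CO2) are treated as pure gas-phase reactants (fraction 1);
#' water partitions between the saturated off-gas and the liquid outflow in
#' proportion to the respective molar flow rates.
#'
#' @param species one of \code{"water"}, \code{"gas"} (O2/CO2-like) or
#'   \code{"nonvolatile"}.
#' @param state a [cstr_state()].
#' @param water_molarity mol/L of liquid water.
#' @return mole fraction in the gas phase.
#' @export
gas_liquid_partition <- function(species = c("nonvolatile", "gas", "water"),
                                 state, water_molarity = 55.34) {
  species <- match.arg(species)
  if (species == "nonvolatile") return(0)
  if (species == "gas") return(1)
  psat <- water_vapor_pressure(state$T)
  # mol/h of water vapor carried out by the saturated off-gas (ideal gas,
  # R in L bar / (K mol))
  n_gas <- state$gas_flow * (psat / state$pressure) *
    state$pressure / (0.0831446 * state$T)
  liquid_outflow <- state$liquid_volume / state$tau  # L/h
  n_liq <- liquid_outflow * water_molarity
  n_gas / (n_gas + n_liq)
}

#' System entropy of the steady-state CSTR
#'
#' \code{S_sys = sum_i s_i c_i,in + tau * xi_dot * dS_R}: the entropy content
#' per unit volume at steady state, i.e. the feed term plus the reaction
#' contribution.
#'
#' @param state a [cstr_state()].
#' @param s named molar entropies at outlet conditions, J/(K mol).
#' @param dS_R overall reaction entropy, J/(K mol glucose).
#' @return S_sys, J/(K L).
#' @export
system_entropy <- function(state, s, dS_R) {
  ids <- intersect(names(state$feed), names(s))
  sum(s[ids] * state$feed[ids]) + state$tau * state$xi_dot * dS_R
}

#' System Gibbs energy and type 1 entropy production of the CSTR
#'
#' \code{G_sys = sum_i g_i c_i,in + tau * xi_dot * dG_R}, and the volumetric
#' entropy production rate from the reaction affinity,
#' \code{sigma_rxn = xi_dot * A / T} with \code{A = -dG_R}. The two forms
#' \code{G_sys = feed term + tau*xi_dot*dG_R} and
#' \code{G_sys = feed term - tau*T*sigma_rxn} are algebraically identical;
#' both are returned for verification.
#'
#' @param state a [cstr_state()].
#' @param g named molar Gibbs energies at outlet conditions, J/mol.
#' @param dG_R overall reaction Gibbs energy, J/mol glucose.
#' @return list: \code{G_sys} (J/L), \code{sigma_rxn} (J/(K L h)),
#'   \code{G_sys_via_sigma}.
#' @export
system_gibbs <- function(state, g, dG_R) {
  ids <- intersect(names(state$feed), names(g))
  feed_term <- sum(g[ids] * state$feed[ids])
  A <- -dG_R
  sigma <- state$xi_dot * A / state$T
  list(G_sys = feed_term + state$tau * state$xi_dot * dG_R,
       sigma_rxn = sigma,
       G_sys_via_sigma = feed_term - state$tau * state$T * sigma)
}

#' Type 1 and type 2 specific entropy production rates
#'
#' Type 1 is based on the reaction affinity of each mode (it includes the
#' enthalpic heat that is exported to the surroundings):
#' \code{xi_hat * sum_j p_j (-dg_j)/T}. Type 2 is based on reaction entropy
#' alone: \code{xi_hat * sum_j p_j ds_j}. With no heat effects
#' (\code{dh_j = 0}) the two coincide.
#'
#' @param p mode usage probabilities (sums to 1).
#' @param mode_thermo \code{mode_thermo} data.frame (columns ds, dg).
#' @param xi_hat specific glucose uptake rate, mol/(h gCDW).
#' @param T temperature, K.
#' @return list: \code{type1}, \code{type2} (J/(K h gCDW)), and per-mode
#'   contribution vectors \code{type1_j}, \code{type2_j}.
#' @export
entropy_production_rates <- function(p, mode_thermo, xi_hat, T = 310.15) {
  if (abs(sum(p) - 1) > 1e-8) stop_config("probabilities must sum to 1")
  t1j <- xi_hat * p * (-mode_thermo$dg) / T
  t2j <- xi_hat * p * mode_thermo$ds
  list(type1 = sum(t1j), type2 = sum(t2j), type1_j = t1j, type2_j = t2j)
}
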