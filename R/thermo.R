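# Condition-adjusted species thermodynamics: extended Debye-Hueckel
# ionic-strength correction in Alberty's transformed convention, pH and
# concentration terms, Boltzmann-weighted pseudoisomer averaging, gas/liquid
# phase averaging, and per-mode reaction properties.

#' Gas constant, J/(K mol)
#' @export
R_GAS <- 8.314

# Alberty's temperature polynomial for the dimensionless Debye-Hueckel
# coefficient alpha(T): RT*alpha(298.15 K) = 2.915 kJ/mol.
.dh_alpha <- function(T) {
  A <- 1.10708 - 1.54508e-3 * T + 5.95584e-6 * T^2  # = RT*alpha, kJ/mol
  A / (R_GAS * 1e-3 * T)
}
.dh_alpha_prime <- function(T) {
  Ap <- -1.54508e-3 + 2 * 5.95584e-6 * T            # d(RT*alpha)/dT
  A <- 1.10708 - 1.54508e-3 * T + 5.95584e-6 * T^2
  (Ap * T - A) / (R_GAS * 1e-3 * T^2)               # d(alpha)/dT
}

#' Culture conditions for thermodynamic adjustment
#'
#' @param T temperature, K.
#' @param pH culture pH.
#' @param ionic_strength ionic strength, mol/L.
#' @param concentrations named vector: mol/L for aqueous species, partial
#'   pressure in bar for gas species. Species absent from the map are
#'   evaluated at the 1 mol/L (1 bar) reference state.
#' @param gas_fractions named vector of gas-phase mole fractions for
#'   mixed-phase species (e.g. water); defaults to 0.
#' @return a \code{conditions} object (validated list).
#' @export
conditions <- function(T = 310.15, pH = 7, ionic_strength = 0.25,
                       concentrations = numeric(), gas_fractions = numeric()) {
  if (T <= 0) stop_config("temperature must be positive")
  if (ionic_strength < 0) stop_config("ionic strength must be >= 0")
  if (any(concentrations <= 0))
    stop_config("concentrations/partial pressures must be positive")
  if (any(gas_fractions < 0 | gas_fractions > 1))
    stop_config("gas fractions must lie in [0, 1]")
  structure(list(T = T, pH = pH, ionic_strength = ionic_strength,
                 concentrations = concentrations,
                 gas_fractions = gas_fractions,
                 reference_concentration = 1),
            class = "conditions")
}

#' Adjust one ionic/phase species to culture conditions
#'
#' Chemical potential (transformed formation Gibbs energy) of a single
#' pseudoisomer species at the given temperature, pH, ionic strength and
#' concentration:
#' \deqn{\mu = \Delta_f G^0 + n_H RT \ln(10)\,pH
#'   - RT\,\alpha(T)(z^2 - n_H)\sqrt{I}/(1 + 1.6\sqrt{I}) + RT\ln(c/c^0)}
#' For gas species the activity term uses the partial pressure in bar in
#' place of \eqn{c/c^0}. The enthalpy carries the Gibbs-Helmholtz-consistent
#' ionic-strength correction derived from the same \eqn{\alpha(T)} polynomial
#' (the pH and activity terms are purely entropic and leave it unchanged).
#'
#' @param dfG0,dfH0 standard formation Gibbs energy/enthalpy, kJ/mol.
#' @param z species charge.
#' @param nH hydrogen-atom count.
#' @param phase \code{"aqueous"} or \code{"gas"}.
#' @param cond a [conditions()] object.
#' @param activity concentration (mol/L) or partial pressure (bar); default
#'   the reference state 1.
#' @return list with \code{mu} and \code{h}, kJ/mol.
#' @export
adjust_species <- function(dfG0, dfH0, z, nH, phase = "aqueous", cond,
                           activity = 1) {
  if (activity <= 0) stop_config("nonpositive concentration/partial pressure")
  T <- cond$T
  RTk <- R_GAS * 1e-3 * T  # kJ/mol
  I <- cond$ionic_strength
  gam <- if (phase == "aqueous" && I > 0) sqrt(I) / (1 + 1.6 * sqrt(I)) else 0
  x <- z^2 - nH
  mu <- dfG0 +
    nH * RTk * log(10) * cond$pH -
    RTk * .dh_alpha(T) * x * gam +
    RTk * log(activity)
  h <- dfH0 + (R_GAS * 1e-3) * T^2 * .dh_alpha_prime(T) * x * gam
  list(mu = mu, h = h)
}

#' Boltzmann-weighted average over a pseudoisomer group
#'
#' A metabolite that exists in several protonation states (e.g. phosphate as
#' H3PO4 / H2PO4- / HPO4-2 / PO4-3) is treated as one pseudoisomer group with
#' composite potential \eqn{\mu_{iso} = -RT \ln \sum_i \exp(-\mu_i/RT)} and
#' per-species weights \eqn{p_i = \exp((\mu_{iso} - \mu_i)/RT)}. Effective
#' enthalpy, mean charge and mean hydrogen count are the \eqn{p_i}-weighted
#' averages. Evaluated with log-sum-exp stabilization; weights are invariant
#' to adding a constant to all potentials.
#'
#' @param species data.frame with columns \code{dfG0}, \code{dfH0}, \code{z},
#'   \code{nH}, and optionally \code{phase} (default aqueous).
#' @param cond a [conditions()] object.
#' @param activity shared concentration (mol/L) of the group.
#' @return list: \code{mu} (composite, kJ/mol), \code{h} (weighted, kJ/mol),
#'   \code{weights}, \code{z_mean}, \code{nH_mean}.
#' @export
pseudoisomer_average <- function(species, cond, activity = 1) {
  if (nrow(species) == 0L) stop("pseudoisomer group is empty")
  phase <- if ("phase" %in% names(species)) species$phase else
    rep("aqueous", nrow(species))
  adj <- lapply(seq_len(nrow(species)), function(i)
    adjust_species(species$dfG0[i], species$dfH0[i], species$z[i],
                   species$nH[i], phase[i], cond, activity))
  mu <- vapply(adj, `[[`, 0, "mu")
  h <- vapply(adj, `[[`, 0, "h")
  RTk <- R_GAS * 1e-3 * cond$T
  u <- -mu / RTk
  m <- max(u)
  w <- exp(u - m)
  Zg <- sum(w)
  w <- w / Zg
  list(mu = -RTk * (m + log(Zg)),
       h = sum(w * h),
       weights = w,
       z_mean = sum(w * species$z),
       nH_mean = sum(w * species$nH))
}

#' Molar average of liquid and gas-phase properties
#'
#' For species present in both phases (water in an aerated culture), the
#' effective property is the mole-fraction-weighted average
#' \code{(1 - x) * liquid + x * gas}.
#'
#' @param liquid,gas lists with \code{mu} and \code{h} (as returned by
#'   [adjust_species()] or [pseudoisomer_average()]).
#' @param gas_fraction gas-phase mole fraction in [0, 1].
#' @return list with averaged \code{mu} and \code{h}.
#' @export
phase_average <- function(liquid, gas, gas_fraction) {
  if (gas_fraction < 0 || gas_fraction > 1)
    stop_config("gas fraction must lie in [0, 1]")
  list(mu = (1 - gas_fraction) * liquid$mu + gas_fraction * gas$mu,
       h = (1 - gas_fraction) * liquid$h + gas_fraction * gas$h)
}

#' Read a species thermodynamic table
#'
#' TSV with columns \code{metabolite}, \code{species}, \code{dfG0},
#' \code{dfH0}, \code{z}, \code{nH}, \code{phase}; one row per
#' ionic/phase form, grouped by metabolite into pseudoisomer groups.
#'
#' @param path TSV path; default the small curated table shipped with the
#'   package (standard-state formation properties for the external
#'   metabolites of a glucose-grown culture).
#' @return data.frame.
#' @export
read_species_table <- function(path = system.file("extdata",
                                                  "species_thermo.tsv",
                                                  package = "entroflux")) {
  if (!file.exists(path)) stop_io("species table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("metabolite", "species", "dfG0", "dfH0", "z", "nH", "phase")
  if (!all(need %in% names(tab)))
    stop_config("species table must have columns: ",
                paste(need, collapse = ", "))
  tab
}

#' Condition-adjusted effective properties per metabolite
#'
#' Applies [pseudoisomer_average()] within each metabolite's aqueous group,
#' [adjust_species()] to gas forms, and [phase_average()] where both phases
#' are present (gas fraction from the conditions, default 0 i.e. liquid).
#' Molar entropy follows from the Gibbs relation, \eqn{s = (h - g)/T}.
#'
#' @param species_table data.frame as from [read_species_table()].
#' @param cond a [conditions()] object.
#' @return data.frame: metabolite, g (kJ/mol), h (kJ/mol),
#'   s (J/(K mol)), z_mean, nH_mean.
#' @export
adjusted_properties <- function(species_table, cond) {
  mets <- unique(species_table$metabolite)
  out <- lapply(mets, function(m) {
    grp <- species_table[species_table$metabolite == m, , drop = FALSE]
    act <- if (m %in% names(cond$concentrations))
      cond$concentrations[[m]] else 1
    aq <- grp[grp$phase != "gas", , drop = FALSE]
    gas <- grp[grp$phase == "gas", , drop = FALSE]
    z_mean <- nH_mean <- 0
    if (nrow(aq) && nrow(gas)) {
      pa <- pseudoisomer_average(aq, cond, act)
      pg <- adjust_species(gas$dfG0[1], gas$dfH0[1], gas$z[1], gas$nH[1],
                           "gas", cond,
                           if (m %in% names(cond$concentrations)) act else 1)
      x <- if (m %in% names(cond$gas_fractions)) cond$gas_fractions[[m]] else 0
      eff <- phase_average(pa, pg, x)
      z_mean <- (1 - x) * pa$z_mean + x * gas$z[1]
      nH_mean <- (1 - x) * pa$nH_mean + x * gas$nH[1]
    } else if (nrow(gas)) {
      eff <- adjust_species(gas$dfG0[1], gas$dfH0[1], gas$z[1], gas$nH[1],
                            "gas", cond, act)
      z_mean <- gas$z[1]; nH_mean <- gas$nH[1]
    } else {
      pa <- pseudoisomer_average(aq, cond, act)
      eff <- pa
      z_mean <- pa$z_mean; nH_mean <- pa$nH_mean
    }
    data.frame(metabolite = m, g = eff$mu, h = eff$h,
               s = (eff$h - eff$mu) / cond$T * 1000,
               z_mean = z_mean, nH_mean = nH_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Protons required for charge neutrality of a mode
#'
#' Charge balance over a mode's external stoichiometry using the mean charge
#' state of each ionizing species: the proton coefficient that closes the
#' balance is \eqn{\nu_{H^+} = -\sum_i \nu_i \bar z_i}. At pH 7 the proton's
#' formation enthalpy and transformed Gibbs energy are zero, so adding it
#' does not alter the mode's reaction thermodynamics, but the proton flux is
#' itself a testable prediction.
#'
#' @param ext_stoich named numeric vector of external coefficients.
#' @param charges named numeric vector of mean charges (from
#'   [adjusted_properties()] column \code{z_mean}).
#' @param proton_id id under which the proton coefficient is stored.
#' @return list: \code{protons} (coefficient) and \code{stoich} (updated
#'   vector including the proton entry).
#' @export
proton_balance <- function(ext_stoich, charges, proton_id = "h.Ext") {
  ids <- setdiff(names(ext_stoich), proton_id)
  missing <- setdiff(ids, names(charges))
  if (length(missing))
    stop_config("missing mean charge for: ", paste(missing, collapse = ", "))
  np <- -sum(ext_stoich[ids] * charges[ids])
  st <- ext_stoich
  st[proton_id] <- np
  list(protons = np, stoich = st)
}

#' Reaction thermodynamics of one mode (or of the overall growth reaction)
#'
#' Sums condition-adjusted molar formation properties over the external
#' stoichiometry: \eqn{\Delta g = \sum_i \nu_i g_i}, likewise for
#' \eqn{\Delta h}, and \eqn{\Delta s = \sum_i \nu_i s_i} with
#' \eqn{s_i = (h_i - g_i)/T}, so the Gibbs relation
#' \eqn{\Delta g = \Delta h - T\Delta s} holds by construction. The affinity
#' is \eqn{A = -\Delta g}.
#'
#' @param ext_stoich named numeric vector of external coefficients (per mole
#'   glucose for a normalized mode).
#' @param props data.frame from [adjusted_properties()].
#' @param cond a [conditions()] object.
#' @param balance_protons add the charge-closing proton term first.
#' @return list: \code{ds} J/(K mol glucose), \code{dh} and \code{dg} J/mol
#'   glucose, \code{affinity} = -dg, \code{protons}.
#' @export
mode_reaction_properties <- function(ext_stoich, props, cond,
                                     balance_protons = TRUE) {
  protons <- 0
  if (balance_protons) {
    z <- stats::setNames(props$z_mean, props$metabolite)
    pb <- proton_balance(ext_stoich, z)
    protons <- pb$protons
    # proton contributes zero to dg/dh in the transformed convention
  }
  ids <- names(ext_stoich)
  missing <- setdiff(ids, props$metabolite)
  if (length(missing))
    stop_config("missing adjusted properties for: ",
                paste(missing, collapse = ", "))
  i <- match(ids, props$metabolite)
  dg <- sum(ext_stoich * props$g[i]) * 1000  # J/mol glucose
  dh <- sum(ext_stoich * props$h[i]) * 1000
  ds <- sum(ext_stoich * props$s[i])         # J/(K mol glucose)
  list(ds = ds, dh = dh, dg = dg, affinity = -dg, protons = protons)
}

#' Reaction thermodynamics for every mode in a set
#'
#' @param modes a glucose-normalized \code{efm_set}.
#' @param props data.frame from [adjusted_properties()].
#' @param cond a [conditions()] object.
#' @param balance_protons see [mode_reaction_properties()].
#' @return \code{mode_thermo} data.frame: mode, ds, dh, dg, affinity, protons.
#' @export
mode_thermo_table <- function(modes, props, cond, balance_protons = TRUE) {
  out <- lapply(seq_len(modes$n), function(j) {
    st <- modes$external[j, ]
    st <- st[st != 0]
    mt <- mode_reaction_properties(st, props, cond, balance_protons)
    data.frame(mode = rownames(modes$external)[j], ds = mt$ds, dh = mt$dh,
               dg = mt$dg, affinity = mt$affinity, protons = mt$protons,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("mode_thermo", "data.frame")
  res
}

#' Overall growth-reaction thermodynamics from a measured stoichiometry
#'
#' Same computation as [mode_reaction_properties()], applied to the measured
#' overall growth equation of a strain (per mole glucose).
#'
#' @inheritParams mode_reaction_properties
#' @return list: \code{dS_R} J/(K mol), \code{dH_R} and \code{dG_R} J/mol,
#'   \code{affinity}, \code{protons}.
#' @export
overall_reaction_properties <- function(ext_stoich, props, cond,
                                        balance_protons = TRUE) {
  mt <- mode_reaction_properties(ext_stoich, props, cond, balance_protons)
  list(dS_R = mt$ds, dH_R = mt$dh, dG_R = mt$dg, affinity = mt$affinity,
       protons = mt$protons)
}

#' Write a mode thermodynamics table as TSV
#' @param mt a \code{mode_thermo} data.frame.
#' @param path output path.
#' @export
write_mode_thermo <- function(mt, path) {
  df <- mt
  names(df) <- c("mode", "ds_J_per_K_mol_glc", "dh_J_per_mol_glc",
                 "dg_J_per_mol_glc", "affinity_J_per_mol_glc", "protons_mol")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
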