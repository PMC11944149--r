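# Seeded synthetic-data generators: toy networks with analytically known
# elementary-mode counts, synthetic mode thermodynamics emulating the
# qualitative structure of a real network (all modes spontaneous and
# exothermic, entropy positively correlated with affinity), and synthetic
# strain observations drawn from a Boltzmann distribution with known b.

#' Toy metabolic networks with known elementary-mode counts
#'
#' \describe{
#'   \item{chain}{linear uptake-conversion-excretion path: 1 mode.}
#'   \item{diamond}{two parallel two-step branches: 2 modes.}
#'   \item{branched8}{8 reactions, 2 branch points: 4 modes.}
#'   \item{cycle}{two parallel one-step branches plus a glucose-independent
#'     futile loop: 3 modes, of which 1 consumes no glucose.}
#' }
#'
#' @param name network name.
#' @return a \code{reaction_network} with attribute \code{expected_modes}.
#' @export
toy_network <- function(name = c("chain", "diamond", "branched8", "cycle")) {
  name <- match.arg(name)
  lines <- switch(name,
    chain = c("v1: glc.Ext => glc",
              "v2: glc => 2 pyr",
              "v3: pyr => pyr.Ext"),
    diamond = c("vup: glc.Ext => glc",
                "va1: glc => a",
                "va2: a => p",
                "vb1: glc => b",
                "vb2: b => p",
                "vout: p => p.Ext"),
    branched8 = c("vup: glc.Ext => glc",
                  "va1: glc => i1",
                  "va2: glc => i2",
                  "vj1: i1 => m",
                  "vj2: i2 => m",
                  "vb1: m => p",
                  "vb2: m => p",
                  "vout: p => p.Ext"),
    cycle = c("vup: glc.Ext => glc",
              "p1: glc => ac",
              "p2: glc => ac",
              "vout: ac => ac.Ext",
              "c1: x => y",
              "c2: y => x"))
  net <- parse_reaction_list(lines)
  attr(net, "expected_modes") <- switch(name, chain = 1L, diamond = 2L,
                                        branched8 = 4L, cycle = 3L)
  attr(net, "expected_nonglucose") <- if (name == "cycle") 1L else 0L
  net
}

#' Synthetic per-mode reaction thermodynamics
#'
#' Samples mode entropies uniformly in \code{ds_range} and couples enthalpies
#' to them: \code{dh = -a * T * ds * (1 + noise)} under the correlated model
#' (so every mode is exothermic and spontaneous, and affinity correlates
#' positively with entropy, as in a real aerobic network), or \code{dh = 0}
#' under the zero model (in which \code{affinity/T = ds} exactly and the two
#' distribution variants coincide).
#'
#' @param n_modes number of modes.
#' @param ds_range range of reaction entropies, J/(K mol glucose).
#' @param dh_model \code{"correlated"} or \code{"zero"}.
#' @param a enthalpy coupling factor (dimensionless, > 0).
#' @param noise_sd relative sd of the enthalpy noise.
#' @param T temperature, K.
#' @param seed RNG seed.
#' @return \code{mode_thermo} data.frame (mode, ds, dh, dg, affinity,
#'   protons = 0).
#' @export
synthetic_thermo <- function(n_modes, ds_range = c(1000, 3000),
                             dh_model = c("correlated", "zero"), a = 4,
                             noise_sd = 0.05, T = 310.15, seed = 1) {
  dh_model <- match.arg(dh_model)
  set.seed(seed)
  ds <- stats::runif(n_modes, ds_range[1], ds_range[2])
  dh <- if (dh_model == "zero") rep(0, n_modes) else
    -a * T * ds * (1 + stats::rnorm(n_modes, 0, noise_sd))
  dg <- dh - T * ds
  res <- data.frame(mode = paste0("m", seq_len(n_modes)), ds = ds, dh = dh,
                    dg = dg, affinity = -dg, protons = 0,
                    stringsAsFactors = FALSE)
  class(res) <- c("mode_thermo", "data.frame")
  res
}

#' Synthetic external-stoichiometry system with consistent mode entropies
#'
#' Builds a set of modes as external stoichiometries over glucose (-1),
#' biomass, a few byproducts and an entropy-carrier product (CO2-like), with
#' per-species molar entropies chosen so that each mode's reaction entropy
#' \code{ds = sum(nu * s)} lands at a sampled target in \code{ds_range}.
#' This gives a fully consistent chain stoichiometry -> thermodynamics ->
#' distribution for end-to-end recovery tests with stoichiometric noise.
#'
#' @param n_modes number of modes.
#' @param ds_range target entropy range, J/(K mol glucose).
#' @param seed RNG seed.
#' @return list: \code{ext_stoich} (modes-by-species matrix),
#'   \code{species_s} (named molar entropies, J/(K mol)), \code{ds} (mode
#'   entropies), \code{mw} (named molar masses, g/mol), \code{biomass_id},
#'   \code{glucose_id}.
#' @export
synthetic_system <- function(n_modes = 50, ds_range = c(1000, 3000),
                             seed = 1) {
  set.seed(seed)
  # entropy is carried mostly by the volatile products (CO2- and water-like
  # species), as in a real aerobic growth equation, so coefficient noise
  # partially averages out in the overall reaction entropy
  s <- c(glc.Ext = 50, bio.Ext = 80, by1.Ext = 150, by2.Ext = 250,
         co2.Ext = 400, h2o.Ext = 300)
  mw <- c(glc.Ext = 180.16, bio.Ext = 24.22, by1.Ext = 60.05,
          by2.Ext = 46.07, co2.Ext = 44.01, h2o.Ext = 18.02)
  ds_target <- stats::runif(n_modes, ds_range[1], ds_range[2])
  nu_bio <- stats::runif(n_modes, 1.5, 3.5)
  nu_by1 <- stats::runif(n_modes, 0, 0.5)
  nu_by2 <- stats::runif(n_modes, 0, 0.5)
  base <- -s[["glc.Ext"]] + nu_bio * s[["bio.Ext"]] +
    nu_by1 * s[["by1.Ext"]] + nu_by2 * s[["by2.Ext"]]
  res <- ds_target - base
  share <- stats::runif(n_modes, 0.4, 0.6)
  nu_co2 <- share * res / s[["co2.Ext"]]
  nu_h2o <- (1 - share) * res / s[["h2o.Ext"]]
  stopifnot(all(res > 0))
  ext <- cbind(glc.Ext = -1, bio.Ext = nu_bio, by1.Ext = nu_by1,
               by2.Ext = nu_by2, co2.Ext = nu_co2, h2o.Ext = nu_h2o)
  rownames(ext) <- paste0("m", seq_len(n_modes))
  list(ext_stoich = ext, species_s = s, ds = as.numeric(ext %*% s),
       mw = mw, biomass_id = "bio.Ext", glucose_id = "glc.Ext")
}

#' Synthetic strain observation with known ground-truth b
#'
#' Draws the mode distribution at \code{b_true}, forms the overall growth
#' stoichiometry as the probability-weighted mode average, optionally applies
#' multiplicative Gaussian noise to the external coefficients (glucose stays
#' at -1, preserving normalization), and recomputes the observed overall
#' reaction entropy from the (noisy) stoichiometry and the species
#' entropies. The specific growth rate follows from the biomass coefficient,
#' \code{mu = nu_bio * mw_bio * xi_hat}. Regenerating with the same seed
#' reproduces identical output.
#'
#' @param system a [synthetic_system()].
#' @param b_true ground-truth evolutionary fraction.
#' @param xi_hat specific glucose uptake, mol/(h gCDW).
#' @param noise_sd relative sd of the stoichiometric noise (0 = exact).
#' @param seed RNG seed for the noise.
#' @return list: \code{p_star}, \code{nu} (clean), \code{nu_obs} (noisy),
#'   \code{dS_R} (observed, J/(K mol)), \code{mu} (1/h), \code{qs}
#'   (mmol/(h gCDW)), \code{yield_bg} (g/g), \code{b_true}, \code{xi_hat},
#'   \code{noise_sd}, \code{seed}.
#' @export
synthetic_strain <- function(system, b_true, xi_hat = 0.012, noise_sd = 0,
                             seed = 1) {
  p_star <- boltzmann_probabilities(system$ds, xi_hat, b_true)$p
  nu <- as.numeric(p_star %*% system$ext_stoich)
  names(nu) <- colnames(system$ext_stoich)
  nu_obs <- nu
  if (noise_sd > 0) {
    set.seed(seed)
    others <- setdiff(names(nu), system$glucose_id)
    nu_obs[others] <- nu[others] *
      (1 + stats::rnorm(length(others), 0, noise_sd))
  }
  dS_R <- sum(nu_obs * system$species_s[names(nu_obs)])
  mw_bio <- system$mw[[system$biomass_id]]
  mu <- nu_obs[[system$biomass_id]] * mw_bio * xi_hat
  list(p_star = p_star, nu = nu, nu_obs = nu_obs, dS_R = dS_R, mu = mu,
       qs = xi_hat * 1000,
       yield_bg = nu_obs[[system$biomass_id]] * mw_bio /
         system$mw[[system$glucose_id]],
       b_true = b_true, xi_hat = xi_hat, noise_sd = noise_sd, seed = seed)
}

#' Write fixture files for a toy network
#'
#' Writes the network reaction list, its enumerated (glucose-normalized)
#' mode matrix, a synthetic mode-thermodynamics table, and a synthetic
#' strain observation (YAML) into a directory.
#'
#' @param name toy network name (see [toy_network()]).
#' @param dir output directory (created if needed).
#' @param b_true,xi_hat,seed passed to the synthetic generators.
#' @return invisibly, the named list of file paths.
#' @export
write_fixtures <- function(name, dir, b_true = 0.4, xi_hat = 0.012,
                           seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- toy_network(name)
  modes <- normalize_to_glucose(enumerate_modes(net))
  thermo <- synthetic_thermo(modes$n, seed = seed)
  p <- boltzmann_probabilities(thermo$ds, xi_hat, b_true)$p
  obs <- list(mu = 0.9, qs = xi_hat * 1000,
              dS_R = sum(p * thermo$ds), b_true = b_true, seed = seed)
  paths <- list(network = file.path(dir, "network.txt"),
                modes = file.path(dir, "modes.tsv"),
                thermo = file.path(dir, "mode_thermo.tsv"),
                strain = file.path(dir, "strain.yml"))
  writeLines(format_reaction_list(net), paths$network)
  write_modes(modes, paths$modes)
  write_mode_thermo(thermo, paths$thermo)
  yaml::write_yaml(obs, paths$strain)
  invisible(paths)
}
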