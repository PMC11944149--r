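# End-to-end orchestration: network -> modes -> thermodynamics -> fit ->
# predicted fluxes -> comparison, with all artifacts written to a directory.

#' Read and validate a pipeline run configuration
#'
#' A configuration is a YAML file (or an equivalent R list) with fields:
#' \code{fixture} (toy-network name) or \code{network} (reaction-list path);
#' \code{glucose_id}; \code{thermo} (\code{type: synthetic} with
#' \code{ds_range}/\code{dh_model}/\code{seed}, or \code{type: table} with
#' \code{species} path and a \code{conditions} block); \code{strain} (path to
#' a YAML with \code{mu}, \code{qs}, \code{dS_R}, or an inline block, or
#' \code{synthetic: true} with \code{b_true}); \code{variant}
#' (\code{entropy}/\code{affinity}); \code{measured} (optional TSV path);
#' \code{exclusions}; \code{seed}.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_io("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or YAML path")
  if (is.null(config$fixture) && is.null(config$network))
    stop_config("config needs either 'fixture' or 'network'")
  if (!is.null(config$network) && !file.exists(config$network))
    stop_config("network file does not exist: ", config$network)
  config$glucose_id <- config$glucose_id %||% "glc.Ext"
  config$variant <- config$variant %||% "entropy"
  if (!config$variant %in% c("entropy", "affinity"))
    stop_config("variant must be 'entropy' or 'affinity'")
  config$seed <- config$seed %||% 1L
  config$exclusions <- config$exclusions %||% character()
  config$thermo <- config$thermo %||% list(type = "synthetic")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full prediction pipeline
#'
#' Stages: (1) load or build the network; (2) enumerate and
#' glucose-normalize elementary modes; (3) compute per-mode thermodynamics
#' (from a species table at the configured conditions, or synthetically);
#' (4) fit the Boltzmann distribution to the strain observation; (5) predict
#' external and internal rates; (6) compare with measured fluxes (or with
#' the self-prediction when none are supplied). Every stage writes its
#' artifact before the next starts, outputs are deterministic given the
#' config, and the config itself is echoed into \code{report.json}.
#'
#' @param config see [read_run_config()].
#' @param out output directory.
#' @param quiet suppress per-stage log messages (stderr).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out, quiet = FALSE) {
  config <- read_run_config(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message("[entroflux] ", ...)

  # stage 1: network
  net <- if (!is.null(config$fixture)) toy_network(config$fixture) else
    parse_reaction_list(config$network, is_file = TRUE)
  writeLines(format_reaction_list(net), file.path(out, "network.txt"))
  log("network: ", nrow(net$reactions), " reactions, ",
      nrow(net$metabolites), " metabolites")

  # stage 2: modes
  modes <- normalize_to_glucose(enumerate_modes(net), config$glucose_id)
  write_modes(modes, file.path(out, "modes.tsv"))
  log("modes: ", modes$n, " glucose-consuming elementary modes")

  # stage 3: thermodynamics
  th <- config$thermo
  thermo <- if (identical(th$type, "table")) {
    spec <- read_species_table(th$species %||% system.file(
      "extdata", "species_thermo.tsv", package = "entroflux"))
    cb <- th$conditions %||% list()
    cond <- conditions(T = cb$T %||% 310.15, pH = cb$pH %||% 7,
                       ionic_strength = cb$ionic_strength %||% 0.25,
                       concentrations = unlist(cb$concentrations) %||%
                         numeric(),
                       gas_fractions = unlist(cb$gas_fractions) %||%
                         numeric())
    mode_thermo_table(modes, adjusted_properties(spec, cond), cond)
  } else {
    synthetic_thermo(modes$n, ds_range = unlist(th$ds_range) %||%
                       c(1000, 3000),
                     dh_model = th$dh_model %||% "correlated",
                     seed = th$seed %||% config$seed)
  }
  write_mode_thermo(thermo, file.path(out, "mode_thermo.tsv"))
  log("thermo: ds in [", signif(min(thermo$ds), 4), ", ",
      signif(max(thermo$ds), 4), "] J/(K mol)")

  # stage 4: strain observation + fit
  sb <- config$strain %||% list(synthetic = TRUE)
  if (is.character(sb)) sb <- yaml::read_yaml(sb)
  if (isTRUE(sb$synthetic)) {
    b_true <- sb$b_true %||% 0.4
    xi_hat <- sb$xi_hat %||% 0.012
    p_true <- boltzmann_probabilities(
      if (config$variant == "entropy") thermo$ds else thermo$affinity / 310.15,
      xi_hat, b_true)$p
    sb <- list(mu = sb$mu %||% 0.9, qs = xi_hat * 1000,
               dS_R = sum(p_true * thermo$ds),
               dG_R = sum(p_true * thermo$dg))
  }
  xi_hat <- sb$qs / 1000
  x <- if (config$variant == "entropy") thermo$ds else thermo$affinity / 310.15
  target <- if (config$variant == "entropy") sb$dS_R else -sb$dG_R / 310.15
  fit <- fit_b(x, xi_hat, target, variant = config$variant)
  mr <- predict_max_rates(sb$mu, sb$qs, fit$b)
  jsonlite::write_json(
    list(variant = fit$variant, b = fit$b, c = fit$c, Z = fit$Z,
         xi_hat_mol_per_h_g = xi_hat, mu_max_per_h = mr$mu_max,
         qs_max_mmol_per_h_g = mr$qs_max, tau_min_minutes = mr$tau_min),
    file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA)
  write_probabilities(fit, file.path(out, "probabilities.tsv"))
  log("fit: b = ", signif(fit$b, 6), ", c = ", signif(fit$c, 4))

  # stage 5: predictions
  r_int <- internal_rates(fit$p, modes, xi_hat, percent = TRUE)
  r_ext <- external_rates(fit$p, modes, xi_hat, percent = TRUE)
  pred <- data.frame(reaction = c(names(r_int), names(r_ext)),
                     kind = c(rep("internal", length(r_int)),
                              rep("external", length(r_ext))),
                     rate_percent_of_glucose = c(r_int, r_ext),
                     stringsAsFactors = FALSE)
  utils::write.table(pred, file.path(out, "predicted_fluxes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("predicted ", length(r_int), " internal and ", length(r_ext),
      " external rates")

  # stage 6: comparison
  measured <- if (!is.null(config$measured)) {
    utils::read.table(config$measured, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    data.frame(reaction = names(r_int), value = as.numeric(r_int),
               stringsAsFactors = FALSE)
  }
  cmp <- compare_to_measured(r_int, measured, exclude = config$exclusions)
  write_comparison(cmp, file.path(out, "comparison.tsv"),
                   file.path(out, "comparison.json"))
  log("comparison: R^2 = ", signif(cmp$r_squared, 4))

  jsonlite::write_json(
    list(config = config,
         counts = list(reactions = nrow(net$reactions), modes = modes$n,
                       nonglucose = if (is.null(modes$nonglucose)) 0 else
                         nrow(modes$nonglucose$fluxes)),
         fit = list(b = fit$b, c = fit$c),
         comparison = list(r_squared = cmp$r_squared, slope = cmp$slope)),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(network = net, modes = modes, thermo = thermo, fit = fit,
                 predicted = pred, comparison = cmp))
}
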