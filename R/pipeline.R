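## End-to-end orchestration: simulate -> quench -> CRE -> thermo -> bind ->
## stats, driven by a validated config (YAML file or R list). The Rscript
## front-end in inst/cli wraps these functions with subcommands.

.known_config_keys <- c("seed", "temperature", "thresholds", "windows",
                        "species", "reference_table", "output_dir",
                        "energy_unit")

.known_species_keys <- c("xyz", "energy_unit", "gibbs", "simulate",
                         "sim_model", "sim_params")

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or accepts an R list) describing an end-to-end run:
#' a seed, temperature, CRE thresholds, staged windows, up to three species
#' (`complex`, `host`, `ligand`) each defined by either an `xyz` ensemble
#' file, an explicit `gibbs` free-energy vector, or a `simulate` block of
#' toy-model/sampling parameters, plus an optional `reference_table` CSV
#' for benchmark statistics. Unknown keys are rejected.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$temperature <- as.numeric(config$temperature %||% 298.15)
  config$energy_unit <- config$energy_unit %||% "hartree"
  th <- config$thresholds %||% list()
  config$thresholds <- do.call(cre_thresholds, th)
  config$windows <- as.numeric(config$windows %||% c(15, 10, 6))
  if (!is.null(config$species)) {
    for (sp in names(config$species)) {
      unknown <- setdiff(names(config$species[[sp]]), .known_species_keys)
      if (length(unknown))
        stop("unknown key(s) in species '", sp, "': ",
             paste(unknown, collapse = ", "))
    }
  }
  class(config) <- c("pipeline_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.species_gibbs <- function(sp_def, config, sp_name) {
  if (!is.null(sp_def$gibbs)) {
    return(list(G = as.numeric(sp_def$gibbs), n_conformers = length(sp_def$gibbs)))
  }
  if (!is.null(sp_def$xyz)) {
    ens <- read_multixyz(sp_def$xyz,
                         energy_unit = sp_def$energy_unit %||%
                           config$energy_unit,
                         temperature = config$temperature)
  } else if (!is.null(sp_def$sim_model)) {
    # pre-built model object (programmatic use)
    ens <- quench_ensemble(sp_def$sim_model,
                           run_mtd(sp_def$sim_model, sp_def$sim_params))
  } else if (!is.null(sp_def$simulate)) {
    sim <- sp_def$simulate
    model <- toy_torsion_model(
      n_torsions = sim$n_torsions %||% 2L,
      coupling = sim$coupling %||% 0,
      seed = config$seed)
    params <- mtd_params(steps = sim$steps %||% 2000L,
                         T = sim$T %||% 300,
                         k_push = sim$k_push %||% 1.5,
                         alpha = sim$alpha %||% 0.8,
                         seed = config$seed + match(sp_name,
                                                    c("complex", "host",
                                                      "ligand")))
    ens <- quench_ensemble(model, run_mtd(model, params))
  } else {
    stop("species '", sp_name,
         "' needs one of: gibbs, xyz, simulate")
  }
  refined <- staged_refine(ens, windows = config$windows,
                           thresholds = config$thresholds)
  flat <- cre_flatten(refined$cre, temperature = config$temperature)
  list(G = ensemble_gibbs(flat), n_conformers = length(refined$cre$groups),
       stage_counts = refined$stage_counts)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: per-species ensemble
#' acquisition (file read or seeded toy-model simulation followed by
#' snapshot quenching), staged CRE refinement, Boltzmann thermochemistry,
#' binding free energies, and (when a reference table is configured)
#' benchmark statistics. Deterministic for a given config and seed.
#'
#' @param config A [pipeline_config], YAML path, or list.
#' @param write_report If `TRUE` and `output_dir` is configured, the report
#'   is also written to `output_dir/report.json`.
#' @return A report list with a `binding` ([binding_free_energies] result)
#'   when the three species are configured, per-species summaries, and a
#'   `stats` block when a reference table is given.
#' @export
run_pipeline <- function(config, write_report = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  report <- list(seed = config$seed, temperature = config$temperature)
  if (!is.null(config$species)) {
    species <- lapply(names(config$species), function(sp)
      .species_gibbs(config$species[[sp]], config, sp))
    names(species) <- names(config$species)
    report$species <- lapply(species, function(s)
      list(n_structures = length(s$G), n_conformers = s$n_conformers,
           g_min = min(s$G)))
    if (all(c("complex", "host", "ligand") %in% names(species))) {
      b <- binding_free_energies(species$complex$G, species$host$G,
                                 species$ligand$G, T = config$temperature)
      report$binding <- list(dg_top = b$dg_top, dg_ens = b$dg_ens,
                             dg_ens_tscr = b$dg_ens_tscr,
                             t_dscr = b$t_dscr)
    }
  }
  if (!is.null(config$reference_table)) {
    tab <- read_reference_table(config$reference_table)
    report$stats <- list()
    for (fl in c("top", "ensemble")) {
      col <- if (fl == "top") "dg_top" else "dg_ens"
      if (col %in% names(tab)) {
        dv <- deviations(tab, fl)
        es <- error_summary(dv)
        report$stats[[fl]] <- list(mae = es$mae, rmse = es$rmse,
                                   sd = es$sd, n = es$n,
                                   overbinding = overbinding_count(dv))
      }
    }
  }
  if (write_report && !is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
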