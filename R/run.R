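# Pipeline drivers behind the command-line interface (inst/cli/eflux.R).
# Each run writes, next to its results, a provenance record (JSON) with the
# package version, input paths, seeds and tolerances needed to re-execute
# it exactly.

#' Read and validate a run configuration
#'
#' Configurations are YAML key-value files. Recognized keys: `model`
#' (SBML or JSON path, required), `expression` (TSV/CSV path, required for
#' fitting/sampling), `gene_map` (optional two-column TSV),
#' `gene_column`/`value_column` (default `gene`/`value`),
#' `measured_growth`, `measured_uptakes` (map exchange id -> rate),
#' `pc_range` (two numbers, default 0 600), `growth_tolerance` (default
#' 1e-3), `constrain_exchanges` (default false), `missing_policy`
#' (default "max"), `sampler` (`n_points`, `thinning`, `seed`,
#' `n_warmup`, `objective_fraction`), `output_dir` (default `"."`).
#'
#' @param path YAML file path.
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must set 'model'")
  defaults <- list(
    gene_column = "gene", value_column = "value",
    pc_range = c(0, 600), growth_tolerance = 1e-3,
    constrain_exchanges = FALSE, missing_policy = "max",
    output_dir = ".",
    sampler = list()
  )
  sampler_defaults <- list(n_points = 10000, thinning = 200, seed = 1,
                           n_warmup = NULL, objective_fraction = 0.999)
  cfg <- utils::modifyList(defaults, cfg)
  cfg$sampler <- utils::modifyList(sampler_defaults,
                                   if (is.list(cfg$sampler)) cfg$sampler else list())
  for (p in c("model", "expression", "gene_map")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config path '", p, "' does not exist: ", cfg[[p]])
  }
  num_pos <- list(growth_tolerance = cfg$growth_tolerance,
                  n_points = cfg$sampler$n_points,
                  thinning = cfg$sampler$thinning)
  for (nm in names(num_pos)) {
    if (!is.numeric(num_pos[[nm]]) || num_pos[[nm]] <= 0)
      stop("config '", nm, "' must be a positive number")
  }
  class(cfg) <- "run_config"
  cfg
}

load_model_any <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) load_json_model(path)
  else load_sbml_model(path)
}

config_profile <- function(config) {
  if (is.null(config$expression)) stop("config must set 'expression'")
  profile <- read_expression_table(config$expression,
                                   gene_column = config$gene_column,
                                   value_column = config$value_column)
  if (!is.null(config$gene_map))
    profile <- apply_gene_map(profile, config$gene_map)
  profile
}

config_uptakes <- function(config) {
  if (is.null(config$measured_uptakes)) return(NULL)
  unlist(config$measured_uptakes)
}

write_provenance <- function(config, stage, extra, path) {
  rec <- list(
    stage = stage,
    package = "efluxpc",
    package_version = as.character(utils::packageVersion("efluxpc")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)
  )
  rec <- c(rec, extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Fit the proportionality constant from a run configuration
#'
#' Executes load -> normalize -> PC scan -> fit, then writes the coarse
#' scan table (`pc_scan.tsv`: delta, growth, status), a fit summary
#' (`pc_fit.json`) and a provenance record (`provenance_fit.json`) into the
#' configured output directory.
#'
#' @param config a `run_config` (or path to one).
#' @return the `pc_fit_result`, invisibly.
#' @export
run_fit_pc <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$measured_growth))
    stop("config must set 'measured_growth' to fit the PC")
  model <- load_model_any(config$model)
  profile <- config_profile(config)
  fit <- fit_pc(model, profile,
                measured_uptakes = config_uptakes(config),
                measured_growth = config$measured_growth,
                range = as.numeric(config$pc_range),
                tolerance = config$growth_tolerance,
                constrain_exchanges = isTRUE(config$constrain_exchanges),
                missing_policy = config$missing_policy)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  scan_path <- file.path(config$output_dir, "pc_scan.tsv")
  utils::write.table(as.data.frame(fit$scan), scan_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- fit[c("delta_fit", "measured_growth", "achieved_growth",
                  "plateau_growth", "plateau_onset", "status", "tolerance")]
  jsonlite::write_json(report, file.path(config$output_dir, "pc_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_provenance(config, "fit-pc", list(status = fit$status),
                   file.path(config$output_dir, "provenance_fit.json"))
  invisible(fit)
}

#' Sample the flux polytope at a given proportionality constant
#'
#' Applies the expression-derived bounds at the PC `delta`, fixes the
#' biomass flux at (a fraction of) its optimum, runs the ACHR sampler, and
#' writes the sampled flux matrix (`samples.tsv.gz`, reactions as columns),
#' the per-reaction mean/sd summary (`flux_summary.tsv`) and a provenance
#' record into the configured output directory.
#'
#' @param config a `run_config` (or path to one).
#' @param delta the proportionality constant, non-negative.
#' @return the `flux_sample_set`, invisibly.
#' @export
run_sample <- function(config, delta) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop("delta must be a single non-negative number")
  model <- load_model_any(config$model)
  profile <- config_profile(config)
  uptakes <- config_uptakes(config)
  if (length(uptakes)) model <- apply_uptake_constraints(model, uptakes)
  scaled <- scale_expression(profile, delta)
  activity <- compute_reaction_scores(model, scaled,
                                      missing_policy = config$missing_policy)
  constrained <- apply_eflux_bounds(
    model, activity,
    constrain_exchanges = isTRUE(config$constrain_exchanges))
  check <- solve_fba(constrained)
  if (check$status != "optimal")
    stop("model is infeasible at PC = ", delta,
         "; no flux distribution satisfies the expression-derived bounds")
  fixed <- fix_objective_at_optimum(constrained,
                                    fraction = config$sampler$objective_fraction)
  state <- generate_warmup(fixed, n_warmup = config$sampler$n_warmup,
                           seed = config$sampler$seed)
  samples <- achr_sample(state, n_points = config$sampler$n_points,
                         thinning = config$sampler$thinning)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  gz <- gzfile(file.path(config$output_dir, "samples.tsv.gz"), "w")
  utils::write.table(samples$points, gz, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(gz)
  summary_tab <- summarize_samples(samples)
  utils::write.table(as.data.frame(summary_tab),
                     file.path(config$output_dir, "flux_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, "sample",
                   list(delta = delta, settings = samples$settings),
                   file.path(config$output_dir, "provenance_sample.json"))
  invisible(samples)
}
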