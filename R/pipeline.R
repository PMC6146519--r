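# Pipeline orchestration: simulate -> preprocess -> fit -> decode -> report,
# driven by one YAML configuration with structured stderr logging.

#' Pipeline configuration
#'
#' Loads a YAML configuration and fills unset fields from the canonical
#' profile `"wap2016"`, whose defaults reproduce the reference analysis
#' settings: 20 km/h speed filter, 12 h maximum gap, 24 h minimum span, 10 m
#' / 20 s dive definition, 6 h model interval, and 2 chains of 30,000
#' iterations with 28,000 burn-in thinned by 4.
#'
#' @param path optional YAML file; fields override the profile.
#' @param overrides optional named list applied on top of the file.
#' @param profile profile name (only `"wap2016"` ships).
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL,
                            profile = "wap2016") {
  base <- yaml::read_yaml(system.file("extdata", "profiles",
                                      paste0(profile, ".yaml"),
                                      package = "nestcrw"))
  merge_cfg <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(b[[nm]]) && is.list(a[[nm]]))
        merge_cfg(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- base
  if (!is.null(path)) cfg <- merge_cfg(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_cfg(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_sim_config <- function(cfg) {
  s <- cfg$simulate
  tp <- if (is.null(s$true_params)) default_params() else
    crw_params(gamma = unlist(s$true_params$gamma),
               theta = unlist(s$true_params$theta),
               process_sd = unlist(s$true_params$process_sd),
               alpha_top = unlist(s$true_params$alpha_top),
               alpha_sub = matrix(unlist(s$true_params$alpha_sub), 2, 2,
                                  byrow = TRUE),
               dive_mu = unlist(s$true_params$dive_mu),
               dive_sd = unlist(s$true_params$dive_sd))
  simulation_config(
    n_animals = s$n_animals %||% 11,
    steps_per_animal = s$steps_per_animal %||% 107,
    true_params = tp,
    fixes_per_interval_rate = s$fixes_per_interval_rate %||% 7.9,
    dives_per_interval_rate = s$dives_per_interval_rate %||% 22.4,
    missing_interval_prob = s$missing_interval_prob %||% 0.1,
    seed = s$seed %||% 1L)
}

input_hash <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(character(0))
  stats::setNames(as.character(tools::md5sum(paths)), basename(paths))
}

#' Simulate a dataset from a pipeline configuration
#'
#' Writes `fixes.csv`, `dives.csv`, `truth.csv`, `truth_dives.csv` and the
#' `config.json` sidecar into the configured data directory. Rerunning with
#' the same configuration produces identical files.
#'
#' @param config [pipeline_config()].
#' @return Invisibly, the named file paths.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim_cfg <- resolve_sim_config(config)
  log_line("simulate", "start", n_animals = sim_cfg$n_animals,
           steps = sim_cfg$steps_per_animal, seed = sim_cfg$seed)
  ds <- simulate_dataset(sim_cfg)
  dir <- config$paths$data_dir %||% stop("paths.data_dir not set",
                                         call. = FALSE)
  paths <- write_dataset(ds, dir)
  log_line("simulate", "done", fixes = nrow(ds$fixes), dives = nrow(ds$dives))
  invisible(paths)
}

#' Preprocess and fit the model from a pipeline configuration
#'
#' Reads the configured fixes and dive files, runs the filtering and
#' regularization chain, fits the sampler, and writes the Gelman-Rubin table
#' (`rhat.csv`), an acceptance/configuration log (`fit_log.json`) and the
#' draws (`draws.rds`) to the output directory. In strict mode a maximum
#' r-hat at or above 1.1 is an error.
#'
#' @param config [pipeline_config()].
#' @param strict error when any r-hat >= 1.1 (default). Ignored with one
#'   chain.
#' @param dry_run print the resolved configuration and exit.
#' @return Invisibly, the `crw_draws` object (or the resolved config under
#'   `dry_run`).
#' @export
cmd_fit <- function(config, strict = TRUE, dry_run = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dry_run) {
    cat(yaml::as.yaml(unclass(config)))
    return(invisible(config))
  }
  dir <- config$paths$data_dir
  out_dir <- config$paths$out_dir %||% dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fix_path <- file.path(dir, "fixes.csv")
  dive_path <- file.path(dir, "dives.csv")
  log_line("fit", "inputs", hash = paste(input_hash(c(fix_path, dive_path)),
                                         collapse = ","))
  fixes <- read_fixes(fix_path)
  dives <- read_dives(dive_path)
  fl <- config$filters %||% list()
  prep <- preprocess(fixes, dives,
                     max_speed = fl$max_speed_kmh %||% 20,
                     max_gap = fl$max_gap_h %||% 12,
                     min_span = fl$min_span_h %||% 24,
                     min_depth = fl$min_dive_depth_m %||% 10,
                     min_duration = fl$min_dive_duration_s %||% 20)
  if (!length(prep$tracks)) stop("no tracks survive preprocessing",
                                 call. = FALSE)
  log_line("fit", "preprocessed", tracks = length(prep$tracks),
           fixes = prep$report$n_fixes_out,
           dives = prep$report$n_dives_out)
  mc <- config$mcmc %||% list()
  mcfg <- mcmc_config(n_chains = mc$n_chains %||% 2,
                      n_iter = mc$n_iter %||% 30000,
                      n_burnin = mc$n_burnin %||% 28000,
                      thin = mc$thin %||% 4,
                      seed = mc$seed %||% 1L)
  draws <- run_mcmc(prep$tracks, mcfg, verbose = isTRUE(config$verbose))
  rh <- if (mcfg$n_chains >= 2) rhat_table(draws) else NULL
  if (!is.null(rh))
    utils::write.csv(rh, file.path(out_dir, "rhat.csv"), row.names = FALSE)
  saveRDS(draws, file.path(out_dir, "draws.rds"))
  jsonlite::write_json(
    list(config = unclass(mcfg),
         max_rhat = if (!is.null(rh)) max(rh$rhat, na.rm = TRUE) else NULL,
         accept = lapply(draws$chains, function(ch)
           list(y_rate = ch$accept$y_rate,
                p_rate = as.list(ch$accept$p_rate)))),
    file.path(out_dir, "fit_log.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(rh)) {
    mx <- max(rh$rhat, na.rm = TRUE)
    log_line("fit", "converged", max_rhat = round(mx, 4))
    if (strict && mx >= 1.1)
      stop(sprintf("chains not converged: max r-hat %.3f >= 1.1", mx),
           call. = FALSE)
  }
  invisible(draws)
}

#' Decode and summarize a fitted model
#'
#' Runs decoding and every behavioral summary and writes them as delimited
#' text plus one JSON report. Outputs are a deterministic function of the
#' stored draws, so rerunning is idempotent.
#'
#' @param config [pipeline_config()].
#' @param draws optional `crw_draws`; defaults to `draws.rds` in the output
#'   directory.
#' @return Invisibly, the report list.
#' @export
cmd_report <- function(config, draws = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$out_dir %||% config$paths$data_dir
  if (is.null(draws)) {
    dpath <- file.path(out_dir, "draws.rds")
    if (!file.exists(dpath)) stop("no draws found at ", dpath, call. = FALSE)
    draws <- readRDS(dpath)
  }
  dec <- decode(draws)
  props <- state_time_proportions(dec)
  depth <- depth_distribution_summary(dec, draws)
  monthly <- temporal_frequency(dec, draws, "month",
                                config$report$n_uncertainty_draws %||% 50)
  hourly <- temporal_frequency(dec, draws, "hour",
                               config$report$n_uncertainty_draws %||% 50)
  deep <- deep_dive_count(dec, config$report$deep_dive_threshold_m %||% 400)
  utils::write.csv(props$per_individual,
                   file.path(out_dir, "state_proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(depth, file.path(out_dir, "depth_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(monthly, file.path(out_dir, "monthly_frequency.csv"),
                   row.names = FALSE)
  utils::write.csv(hourly, file.path(out_dir, "hourly_frequency.csv"),
                   row.names = FALSE)
  report <- list(state_proportions = props$summary,
                 depth_summary = depth,
                 deep_dives = deep)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  log_line("report", "done", out = out_dir)
  invisible(report)
}
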