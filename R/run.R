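log_msg <- function(level, threshold, ...) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  if (levels[[level]] >= levels[[threshold]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

write_csv_with_header <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

env_names_for <- function(config) {
  labels <- vapply(config$guild, `[[`, character(1), "label")
  c(paste0(labels, "_only"), if (length(labels) > 1L) "mixed")
}

single_env_config <- function(config, label) {
  labels <- vapply(config$guild, `[[`, character(1), "label")
  p <- match(label, labels)
  env <- config$environment
  environment_config(config$guild[p], 1, env$total_visits, env$n_iterations,
                     env$seed)
}

#' Run the full visitation analysis described by a configuration
#'
#' Executes the interactive simulator for the requested environment(s)
#' (each pollinator alone and/or the mixed guild), the additive baseline
#' where the guild has at least two pollinators, and the binned/smoothed
#' per-phenotype summaries of visits, removal and export. When `out_dir`
#' is given, writes per-flower CSVs, smoothed-landscape CSVs and a
#' `summary.json` (configuration echo, seed, config hash, package version,
#' per-metric optima); every CSV carries the seed, config hash and package
#' version as `#` header comments.
#'
#' @param config A [load_config()] / [reference_config()] object.
#' @param environment `"all"`, `"mixed"`, or `"<label>_only"` for a guild
#'   label (e.g. `"bee_only"`).
#' @param seed,iterations Optional overrides of the configured values.
#' @param n_bins,bandwidth Optional overrides of the analysis block.
#' @param out_dir Output directory (created if missing); `NULL` skips file
#'   output.
#' @param log_level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return Invisibly, a list with `results` (named `simulation_result`
#'   list), `additive` (`additive_baseline` or `NULL`), `smoothed` (nested
#'   list env -> metric -> `smoothed_landscape`), `summary` (the list
#'   written as `summary.json`) and `files` (paths written).
#' @export
run_simulation <- function(config, environment = "all", seed = NULL,
                           iterations = NULL, n_bins = NULL, bandwidth = NULL,
                           out_dir = NULL, log_level = "INFO") {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$environment$seed <- as.integer(seed)
  if (!is.null(iterations))
    config$environment$n_iterations <- as.integer(iterations)
  if (!is.null(n_bins)) config$analysis$n_bins <- as.integer(n_bins)
  if (!is.null(bandwidth)) config$analysis$bandwidth <- as.numeric(bandwidth)

  valid_envs <- env_names_for(config)
  envs <- if (identical(environment, "all")) valid_envs
          else environment
  bad <- setdiff(envs, valid_envs)
  if (length(bad))
    stop("unknown environment(s): ", paste(bad, collapse = ", "),
         "; valid: all, ", paste(valid_envs, collapse = ", "), call. = FALSE)

  hash <- config_hash(config)
  version <- as.character(utils::packageVersion("floralscape"))
  meta <- list(seed = config$environment$seed, config_hash = hash,
               package = paste0("floralscape ", version))
  log_msg("INFO", log_level, "seed ", config$environment$seed,
          ", config hash ", hash)

  metrics <- c("visits", "removal", "export")
  results <- list()
  smoothed <- list()
  files <- character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  for (e in envs) {
    log_msg("INFO", log_level, "simulating environment: ", e)
    env_cfg <- if (e == "mixed") config$environment
               else single_env_config(config, sub("_only$", "", e))
    res <- simulate_environment(config$population, env_cfg)
    results[[e]] <- res
    smoothed[[e]] <- lapply(stats::setNames(metrics, metrics), function(m)
      bin_and_smooth(res, m, config$analysis$n_bins,
                     config$analysis$bandwidth))
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0("per_flower_", e, ".csv"))
      write_csv_with_header(res$tallies, f, meta)
      files <- c(files, f)
      for (m in metrics) {
        sm <- smoothed[[e]][[m]]
        f <- file.path(out_dir, paste0("smoothed_", e, "_", m, ".csv"))
        write_csv_with_header(
          data.frame(bin_centre = sm$bin_centre, value = sm$smoothed),
          f, meta)
        files <- c(files, f)
      }
    }
  }

  additive <- NULL
  additive_smoothed <- NULL
  if (("mixed" %in% envs) && length(config$guild) > 1L) {
    log_msg("INFO", log_level, "computing additive baseline")
    additive <- additive_baseline(config$population, config$environment)
    additive_smoothed <- lapply(stats::setNames(metrics, metrics), function(m)
      bin_and_smooth(additive, m, config$analysis$n_bins,
                     config$analysis$bandwidth))
    smoothed[["additive"]] <- additive_smoothed
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "additive_flower_means.csv")
      write_csv_with_header(additive$flower_means, f, meta)
      files <- c(files, f)
      for (m in metrics) {
        sm <- additive_smoothed[[m]]
        f <- file.path(out_dir, paste0("smoothed_additive_", m, ".csv"))
        write_csv_with_header(
          data.frame(bin_centre = sm$bin_centre, value = sm$smoothed),
          f, meta)
        files <- c(files, f)
      }
    }
  }

  optima <- lapply(smoothed, function(per_env)
    lapply(per_env, function(sm) summarize_optima(sm)))
  summary <- list(config = config_to_list(config), seed = config$environment$seed,
                  config_hash = hash, package_version = version,
                  environments = envs, optima = optima)
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  }
  invisible(list(results = results, additive = additive, smoothed = smoothed,
                 summary = summary, files = files))
}

#' Command-line entry point for the visitation simulator
#'
#' Thin flag-parsing wrapper around [run_simulation()], used by the
#' `floralscape-sim` script installed under
#' `system.file("scripts", package = "floralscape")`. User errors produce
#' a diagnostic on standard error and a nonzero status, never a stack
#' trace.
#'
#' @param args Character vector of command-line flags (defaults to the
#'   process's trailing arguments): `--config PATH` (required), `--seed
#'   INT`, `--iterations INT`, `--environment NAME` (`all`, `mixed` or
#'   `<label>_only`), `--out-dir PATH`, `--bins INT`, `--bandwidth FLOAT`,
#'   `--log-level LEVEL`.
#' @return The exit status, invisibly: 0 on success, 1 on any failure.
#' @export
run_simulation_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    prog = "floralscape-sim",
    description = "Stochastic pollinator visitation and pollen export simulator",
    option_list = list(
      optparse::make_option("--config", type = "character",
                            help = "JSON run configuration [required]"),
      optparse::make_option("--seed", type = "integer", default = NULL,
                            help = "override the configured seed"),
      optparse::make_option("--iterations", type = "integer", default = NULL,
                            help = "override the configured iteration count"),
      optparse::make_option("--environment", type = "character",
                            default = "all",
                            help = "all, mixed or <label>_only [default %default]"),
      optparse::make_option("--out-dir", type = "character", default = "out",
                            dest = "out_dir",
                            help = "output directory [default %default]"),
      optparse::make_option("--bins", type = "integer", default = NULL,
                            help = "override the number of phenotype bins"),
      optparse::make_option("--bandwidth", type = "double", default = NULL,
                            help = "override the smoothing bandwidth"),
      optparse::make_option("--log-level", type = "character",
                            default = "INFO", dest = "log_level",
                            help = "DEBUG, INFO, WARN or ERROR [default %default]")
    ))
  status <- tryCatch({
    opt <- optparse::parse_args(parser, args = args)
    if (is.null(opt$config))
      stop("--config is required", call. = FALSE)
    if (!opt$log_level %in% c("DEBUG", "INFO", "WARN", "ERROR"))
      stop("--log-level must be DEBUG, INFO, WARN or ERROR", call. = FALSE)
    config <- load_config(opt$config)
    run_simulation(config, environment = opt$environment, seed = opt$seed,
                   iterations = opt$iterations, n_bins = opt$bins,
                   bandwidth = opt$bandwidth, out_dir = opt$out_dir,
                   log_level = opt$log_level)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
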