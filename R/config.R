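#' Serialize a fitness curve to a plain list (JSON-ready)
#'
#' @param curve A `fitness_curve`.
#' @return A named list mirroring the JSON configuration dialect:
#'   `{form, optimum, peak_value, width | value | table, label}`.
#' @export
curve_to_list <- function(curve) {
  stopifnot(inherits(curve, "fitness_curve"))
  switch(curve$form,
    gaussian = list(form = "gaussian", optimum = curve$optimum,
                    peak_value = curve$peak_value, width = curve$width,
                    label = curve$label),
    flat = list(form = "flat", value = curve$peak_value,
                label = curve$label),
    tabulated = list(form = "tabulated",
                     table = list(phenotype = curve$table$phenotype,
                                  value = curve$table$value),
                     label = curve$label)
  )
}

#' Build a fitness curve from a plain list (parsed JSON)
#'
#' Gaussian curves may be given either directly (`optimum`, `peak_value`,
#' `width`) or in two-point calibration form (`optimum`, `peak_value`,
#' `reference_point`, `reference_value`), as in the bundled
#' `reference.json`.
#'
#' @param spec Named list with a `form` field.
#' @return A `fitness_curve`.
#' @export
curve_from_list <- function(spec) {
  if (!is.list(spec) || is.null(spec$form))
    stop("curve specification needs a `form` field", call. = FALSE)
  label <- if (is.null(spec$label)) "" else spec$label
  known <- switch(spec$form,
    gaussian = c("form", "optimum", "peak_value", "width",
                 "reference_point", "reference_value", "label"),
    flat = c("form", "value", "label"),
    tabulated = c("form", "table", "label"),
    stop("unknown curve form: ", spec$form, call. = FALSE))
  reject_unknown(spec, known, paste0("curve (form ", spec$form, ")"))
  switch(spec$form,
    gaussian = {
      if (!is.null(spec$width)) {
        make_gaussian_curve(spec$optimum, spec$peak_value, spec$width,
                            label = label)
      } else if (!is.null(spec$reference_point) &&
                 !is.null(spec$reference_value)) {
        calibrate_gaussian_curve(spec$optimum, spec$peak_value,
                                 spec$reference_point, spec$reference_value,
                                 label = label)
      } else {
        stop("gaussian curve needs either `width` or `reference_point` ",
             "and `reference_value`", call. = FALSE)
      }
    },
    flat = make_flat_curve(spec$value, label = label),
    tabulated = {
      tb <- spec$table
      make_tabulated_curve(unlist(tb$phenotype), unlist(tb$value),
                           label = label)
    }
  )
}

#' Export a tabulated curve to two-column CSV
#'
#' @param curve A tabulated `fitness_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fitness_curve"))
  if (curve$form != "tabulated")
    stop("only tabulated curves export to CSV; evaluate on a grid first",
         call. = FALSE)
  utils::write.csv(curve$table, path, row.names = FALSE)
  invisible(path)
}

reject_unknown <- function(block, known, where) {
  extra <- setdiff(names(block), known)
  if (length(extra))
    stop(sprintf("config field \"%s\": unknown key(s) %s in %s block",
                 extra[1L], paste0("\"", extra, "\"", collapse = ", "),
                 where), call. = FALSE)
  invisible(NULL)
}

require_keys <- function(block, keys, where) {
  miss <- setdiff(keys, names(block))
  if (length(miss))
    stop(sprintf("config field \"%s\": required in %s block but missing",
                 miss[1L], where), call. = FALSE)
  invisible(NULL)
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration with `population`, `guild`, `environment`
#' and (optional) `analysis` blocks, validates every field, rejects
#' unknown keys by name, and applies defaults (20 bins, bandwidth 0.15)
#' where the analysis block is silent. All defaults are recorded in the
#' returned object so runs are self-describing.
#'
#' @param path Path to a JSON file; the bundled reference parameterization
#'   is at `system.file("extdata", "reference.json", package = "floralscape")`.
#' @return An object of class `run_config`: a list with `population`
#'   (`flower_population`), `guild` (list of `pollinator_spec`),
#'   `environment` (`environment_config`) and `analysis` (list with
#'   `n_bins`, `bandwidth`).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  config_from_list(raw)
}

#' Build a run configuration from a plain list
#'
#' @param raw Named list, as parsed from the JSON dialect of
#'   [load_config()].
#' @return A `run_config` object.
#' @export
config_from_list <- function(raw) {
  reject_unknown(raw, c("population", "guild", "environment", "analysis"),
                 "top-level")
  require_keys(raw, c("population", "guild", "environment"), "top-level")

  pb <- raw$population
  reject_unknown(pb, c("n_flowers", "range_lo", "range_hi", "pollen_budget"),
                 "population")
  require_keys(pb, c("n_flowers", "range_lo", "range_hi", "pollen_budget"),
               "population")
  population <- build_population(pb$n_flowers, pb$range_lo, pb$range_hi,
                                 pb$pollen_budget)

  if (!is.list(raw$guild) || length(raw$guild) == 0L)
    stop("config field \"guild\": must be a nonempty list of pollinators",
         call. = FALSE)
  guild <- lapply(raw$guild, function(g) {
    reject_unknown(g, c("label", "attraction", "removal",
                        "transfer_efficiency"), "pollinator")
    require_keys(g, c("label", "attraction", "removal",
                      "transfer_efficiency"), "pollinator")
    pollinator_spec(g$label, curve_from_list(g$attraction),
                    curve_from_list(g$removal), g$transfer_efficiency)
  })

  eb <- raw$environment
  reject_unknown(eb, c("mixture", "total_visits", "n_iterations", "seed"),
                 "environment")
  require_keys(eb, c("total_visits", "n_iterations", "seed"), "environment")
  mixture <- if (is.null(eb$mixture)) NULL else unlist(eb$mixture)
  if (!is.null(mixture) && abs(sum(mixture) - 1) > 1e-12)
    stop(sprintf("config field \"mixture\": weights must sum to 1 (got %g)",
                 sum(mixture)), call. = FALSE)
  environment <- environment_config(guild, mixture, eb$total_visits,
                                    eb$n_iterations, eb$seed)

  ab <- if (is.null(raw$analysis)) list() else raw$analysis
  reject_unknown(ab, c("n_bins", "bandwidth"), "analysis")
  analysis <- list(n_bins = if (is.null(ab$n_bins)) 20L
                            else as.integer(ab$n_bins),
                   bandwidth = if (is.null(ab$bandwidth)) 0.15
                               else as.numeric(ab$bandwidth))
  if (analysis$n_bins < 3L)
    stop("config field \"n_bins\": must be >= 3", call. = FALSE)
  if (analysis$bandwidth <= 0 || analysis$bandwidth >= 1)
    stop("config field \"bandwidth\": must lie in (0, 1)", call. = FALSE)

  structure(list(population = population, guild = guild,
                 environment = environment, analysis = analysis),
            class = "run_config")
}

#' Serialize a run configuration back to a plain list
#'
#' Inverse of [config_from_list()]; `config_from_list(config_to_list(x))`
#' compares equal to `x`, and [write_config()] followed by [load_config()]
#' round-trips through JSON.
#'
#' @param config A `run_config`.
#' @return A named list in the JSON dialect, defaults included.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pop <- config$population
  env <- config$environment
  list(
    population = list(n_flowers = pop$n_flowers,
                      range_lo = min(pop$phenotypes),
                      range_hi = max(pop$phenotypes),
                      pollen_budget = pop$pollen_budget),
    guild = lapply(config$guild, function(g)
      list(label = g$label,
           attraction = curve_to_list(g$attraction),
           removal = curve_to_list(g$removal),
           transfer_efficiency = g$transfer_efficiency)),
    environment = list(mixture = env$mixture,
                       total_visits = env$total_visits,
                       n_iterations = env$n_iterations,
                       seed = env$seed),
    analysis = config$analysis
  )
}

#' Write a run configuration to JSON
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' MD5 hash of a run configuration
#'
#' Hashes the canonical JSON serialization, so logically identical
#' configurations hash identically whatever file they came from.
#'
#' @param config A `run_config`.
#' @return A 32-character MD5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' The bundled reference parameterization
#'
#' Loads the packaged `reference.json` configuration: 100 flowers with evenly
#' spaced phenotypes on \[0, 1\] and 160000 pollen grains each; a bee
#' (optimum 0.25, transfer efficiency 0.02) and a hummingbird (optimum
#' 0.75, efficiency 0.04), each with attraction 0.9 at its own optimum and
#' 0.1 at the other's, and removal 10000 grains per visit at its own
#' optimum and 2500 at the other's; equal mixture; 3500 visits per
#' iteration; 10 iterations.
#'
#' @param seed Optional seed overriding the bundled one.
#' @return A `run_config`.
#' @export
reference_config <- function(seed = NULL) {
  cfg <- load_config(system.file("extdata", "reference.json",
                                 package = "floralscape"))
  if (!is.null(seed)) {
    cfg$environment$seed <- as.integer(seed)
  }
  cfg
}

#' Generate a reproducible random guild + population fixture
#'
#' Randomized two-or-more-pollinator guilds for property-based tests.
#' Each pollinator draws an optimum, attraction peak and cross-value,
#' removal peak and cross-value, and transfer efficiency uniformly within
#' the stated ranges; curves are calibrated through the drawn optimum and a
#' reference point half an axis away. `fixture = 0` ignores the
#' randomization and returns the exact bundled reference guild.
#'
#' @param seed Integer seed for the draw.
#' @param n_pollinators Number of pollinators (at least 1).
#' @param ranges Named list of 2-vectors: `optimum`, `attraction_peak`,
#'   `attraction_cross`, `removal_peak`, `removal_cross_frac` (cross value
#'   as a fraction of the peak), `efficiency`.
#' @param fixture Fixture index; 0 selects the reference guild verbatim.
#' @return A list with `guild` (list of `pollinator_spec`), `mixture`
#'   (uniform weights) and `population` (100 flowers on \[0, 1\], budget
#'   160000).
#' @export
generate_fixture_guild <- function(seed, n_pollinators = 2L,
                                   ranges = list(
                                     optimum = c(0.1, 0.9),
                                     attraction_peak = c(0.5, 0.95),
                                     attraction_cross = c(0.02, 0.3),
                                     removal_peak = c(4000, 16000),
                                     removal_cross_frac = c(0.1, 0.6),
                                     efficiency = c(0.01, 0.08)),
                                   fixture = 1L) {
  if (fixture == 0L) {
    cfg <- reference_config()
    return(list(guild = cfg$guild,
                mixture = cfg$environment$mixture,
                population = cfg$population))
  }
  n_pollinators <- as.integer(n_pollinators)
  if (is.na(n_pollinators) || n_pollinators < 1L)
    stop("`n_pollinators` must be a positive integer", call. = FALSE)
  needed <- c("optimum", "attraction_peak", "attraction_cross",
              "removal_peak", "removal_cross_frac", "efficiency")
  if (!all(needed %in% names(ranges)))
    stop("`ranges` must supply: ", paste(needed, collapse = ", "),
         call. = FALSE)
  bad <- vapply(ranges[needed], function(r)
    length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L], logical(1))
  if (any(bad))
    stop("invalid range(s): ", paste(needed[bad], collapse = ", "),
         call. = FALSE)
  runif2 <- function(r) stats::runif(1, r[1L], r[2L])
  set.seed(seed + 1000L * fixture)
  guild <- lapply(seq_len(n_pollinators), function(i) {
    opt <- runif2(ranges$optimum)
    ref <- if (opt < 0.5) opt + 0.5 else opt - 0.5
    ap <- runif2(ranges$attraction_peak)
    ac <- min(runif2(ranges$attraction_cross), 0.9 * ap)
    rp <- runif2(ranges$removal_peak)
    rc <- rp * runif2(ranges$removal_cross_frac)
    pollinator_spec(
      label = sprintf("pollinator_%d", i),
      attraction = calibrate_gaussian_curve(opt, ap, ref, ac,
                                            label = sprintf("attraction_%d", i)),
      removal = calibrate_gaussian_curve(opt, rp, ref, rc,
                                         label = sprintf("removal_%d", i)),
      transfer_efficiency = runif2(ranges$efficiency))
  })
  list(guild = guild,
       mixture = rep(1 / n_pollinators, n_pollinators),
       population = build_population(100L, 0, 1, 160000))
}
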