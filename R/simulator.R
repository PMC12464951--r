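#' Pollinator specification
#'
#' One visitor type: an attraction curve (visitation probability weight per
#' phenotype, values in \[0, 1\]), a removal curve (pollen grains removed per
#' visit), and a pollen transfer efficiency (the fraction of removed pollen
#' subsequently exported rather than lost to grooming or consumption; e.g.
#' 0.02 for bees, 0.04 for hummingbirds).
#'
#' @param label Visitor label (e.g. `"bee"`).
#' @param attraction `fitness_curve` with values in \[0, 1\].
#' @param removal Nonnegative `fitness_curve` (grains per visit).
#' @param transfer_efficiency Fraction in \[0, 1\].
#' @return An object of class `pollinator_spec`.
#' @export
pollinator_spec <- function(label, attraction, removal, transfer_efficiency) {
  stopifnot(inherits(attraction, "fitness_curve"),
            inherits(removal, "fitness_curve"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a nonempty string", call. = FALSE)
  if (!is.numeric(transfer_efficiency) || length(transfer_efficiency) != 1L ||
      transfer_efficiency < 0 || transfer_efficiency > 1)
    stop("`transfer_efficiency` must lie in [0, 1]", call. = FALSE)
  if (attraction$peak_value > 1 ||
      (attraction$form == "tabulated" && any(attraction$table$value > 1)))
    stop("attraction values must lie in [0, 1]", call. = FALSE)
  structure(list(label = label, attraction = attraction, removal = removal,
                 transfer_efficiency = transfer_efficiency),
            class = "pollinator_spec")
}

#' @export
print.pollinator_spec <- function(x, ...) {
  cat(sprintf("<pollinator_spec \"%s\": transfer efficiency %.3g>\n",
              x$label, x$transfer_efficiency))
  print(x$attraction)
  print(x$removal)
  invisible(x)
}

#' Build a flower population with evenly spaced phenotypes
#'
#' @param n_flowers Number of flowers (at least 2).
#' @param range_lo,range_hi Phenotype range, spanned inclusively and evenly.
#' @param pollen_budget Pollen grains produced per flower (equal for all).
#' @return An object of class `flower_population` with elements `phenotypes`
#'   (ascending) and `pollen_budget`.
#' @export
build_population <- function(n_flowers = 100L, range_lo = 0, range_hi = 1,
                             pollen_budget = 160000) {
  n_flowers <- as.integer(n_flowers)
  if (is.na(n_flowers) || n_flowers < 2L)
    stop("`n_flowers` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(range_lo) || !is.numeric(range_hi) || range_lo >= range_hi)
    stop("`range_lo` must be strictly below `range_hi`", call. = FALSE)
  flower_population(seq(range_lo, range_hi, length.out = n_flowers),
                    pollen_budget)
}

#' Flower population from explicit phenotypes
#'
#' Low-level constructor; [build_population()] is the usual entry point.
#'
#' @param phenotypes Ascending numeric vector of flower phenotypes.
#' @param pollen_budget Pollen grains per flower (positive, equal for all).
#' @return An object of class `flower_population`.
#' @export
flower_population <- function(phenotypes, pollen_budget) {
  phenotypes <- as.numeric(phenotypes)
  if (length(phenotypes) < 1L || any(!is.finite(phenotypes)) ||
      is.unsorted(phenotypes))
    stop("`phenotypes` must be finite and sorted ascending", call. = FALSE)
  if (!is.numeric(pollen_budget) || length(pollen_budget) != 1L ||
      pollen_budget <= 0)
    stop("`pollen_budget` must be a single positive number", call. = FALSE)
  structure(list(n_flowers = length(phenotypes), phenotypes = phenotypes,
                 pollen_budget = pollen_budget),
            class = "flower_population")
}

#' @export
print.flower_population <- function(x, ...) {
  cat(sprintf("<flower_population: %d flowers on [%g, %g], budget %g grains>\n",
              x$n_flowers, min(x$phenotypes), max(x$phenotypes),
              x$pollen_budget))
  invisible(x)
}

#' Environment configuration for the visitation simulator
#'
#' @param guild List of [pollinator_spec()] objects.
#' @param mixture Abundance weights, one per pollinator, nonnegative and
#'   summing to 1 (defaults to equal abundances).
#' @param total_visits Visits per iteration across all flowers and
#'   pollinators.
#' @param n_iterations Independent seeded repetitions of the visit process.
#' @param seed Base random seed; iteration `i` uses `seed + i`.
#' @return An object of class `environment_config`.
#' @export
environment_config <- function(guild, mixture = NULL, total_visits = 3500L,
                               n_iterations = 10L, seed = 1L) {
  if (!is.list(guild) || length(guild) == 0L ||
      !all(vapply(guild, inherits, logical(1), "pollinator_spec")))
    stop("`guild` must be a nonempty list of pollinator_spec objects",
         call. = FALSE)
  if (is.null(mixture))
    mixture <- rep(1 / length(guild), length(guild))
  if (length(mixture) != length(guild) || any(mixture < 0))
    stop("`mixture` needs one nonnegative weight per pollinator",
         call. = FALSE)
  if (abs(sum(mixture) - 1) > 1e-12)
    stop("`mixture` weights must sum to 1", call. = FALSE)
  total_visits <- as.integer(total_visits)
  n_iterations <- as.integer(n_iterations)
  if (is.na(total_visits) || total_visits < 1L)
    stop("`total_visits` must be a positive integer", call. = FALSE)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("`n_iterations` must be a positive integer", call. = FALSE)
  structure(list(guild = guild, mixture = as.numeric(mixture),
                 total_visits = total_visits, n_iterations = n_iterations,
                 seed = as.integer(seed)),
            class = "environment_config")
}

#' @export
print.environment_config <- function(x, ...) {
  cat(sprintf("<environment_config: %d pollinator(s) [%s], mixture (%s), %d visits x %d iterations, seed %d>\n",
              length(x$guild),
              paste(vapply(x$guild, `[[`, character(1), "label"),
                    collapse = ", "),
              paste(signif(x$mixture, 3), collapse = ", "),
              x$total_visits, x$n_iterations, x$seed))
  invisible(x)
}

#' Simulate pollinator visitation with pollen depletion
#'
#' Runs the interactive visitation model: in each of `n_iterations`
#' independently seeded iterations, every flower starts with its full
#' pollen budget and exactly `total_visits` visit events are executed in
#' sequence. Each event (1) draws a pollinator from the mixture weights,
#' (2) draws a target flower with probability proportional to that
#' pollinator's attraction value at each flower's phenotype, (3) removes
#' `min(removal_curve(phenotype), remaining pollen)` grains from the
#' flower, and (4) credits `removed * transfer_efficiency` grains to the
#' flower's pollen export; the remainder is lost from the system.
#'
#' Attraction is independent of remaining pollen: depletion reduces what a
#' visit removes, not how attractive a flower is, so visits to fully
#' depleted flowers are allowed and remove nothing. This bounding of both
#' visits and pollen is what makes contributions non-additive: a visit (or
#' grain) taken by one pollinator is unavailable to the other. Identical
#' `(config, seed)` pairs reproduce results bit-for-bit; pollinators with
#' zero mixture weight are dropped before sampling, so a degenerate mixture
#' equals the corresponding single-pollinator environment exactly.
#'
#' @param population A [build_population()] / [flower_population()] object.
#' @param env An [environment_config()].
#' @return An object of class `simulation_result`: a list with
#'   * `tallies`: data frame with one row per (iteration, flower,
#'     pollinator): `iteration`, `flower_id`, `phenotype`, `pollinator`,
#'     `visits`, `pollen_removed`, `pollen_exported`;
#'   * `flower_means`: per-flower across-iteration means of the per-iteration
#'     totals (`visits`, `removal`, `export`), summed over pollinators;
#'   * `population`, `env`: the configuration echo.
#' @export
simulate_environment <- function(population, env) {
  stopifnot(inherits(population, "flower_population"),
            inherits(env, "environment_config"))
  keep <- env$mixture > 0
  guild <- env$guild[keep]
  w <- env$mixture[keep]
  k <- length(guild)
  z <- population$phenotypes
  nf <- population$n_flowers
  budget <- population$pollen_budget
  tv <- env$total_visits

  attr_mat <- vapply(guild, function(p) curve_value(p$attraction, z),
                     numeric(nf))
  attr_mat <- matrix(attr_mat, nrow = nf)
  if (any(attr_mat < 0) || any(attr_mat > 1))
    stop("attraction curves must evaluate in [0, 1] over the population",
         call. = FALSE)
  if (any(colSums(attr_mat) <= 0))
    stop("a pollinator's attraction is zero for every flower: no flower ",
         "can be chosen", call. = FALSE)
  rem_mat <- vapply(guild, function(p) curve_value(p$removal, z), numeric(nf))
  rem_mat <- matrix(rem_mat, nrow = nf)
  if (any(rem_mat < 0))
    stop("removal curves must be nonnegative", call. = FALSE)
  eff <- vapply(guild, `[[`, numeric(1), "transfer_efficiency")
  labels <- vapply(guild, `[[`, character(1), "label")

  n_cells <- nf * k
  tallies <- vector("list", env$n_iterations)
  for (it in seq_len(env$n_iterations)) {
    set.seed(env$seed + it)
    pol <- if (k == 1L) rep(1L, tv) else
      sample.int(k, tv, replace = TRUE, prob = w)
    flw <- integer(tv)
    for (p in seq_len(k)) {
      idx <- which(pol == p)
      if (length(idx))
        flw[idx] <- sample.int(nf, length(idx), replace = TRUE,
                               prob = attr_mat[, p])
    }
    r <- rem_mat[cbind(flw, pol)]
    # Depletion acts per flower in event order; since attraction ignores
    # depletion, capping cumulative removal at the budget within each
    # flower's own visit sequence reproduces the sequential process.
    o <- order(flw)
    cum <- stats::ave(r[o], flw[o], FUN = cumsum)
    removed <- numeric(tv)
    removed[o] <- pmin(cum, budget) - pmin(cum - r[o], budget)
    cell <- flw + (pol - 1L) * nf
    visits_c <- tabulate(cell, nbins = n_cells)
    removed_c <- exported_c <- numeric(n_cells)
    rs <- rowsum(cbind(removed, removed * eff[pol]), cell)
    ci <- as.integer(rownames(rs))
    removed_c[ci] <- rs[, 1L]
    exported_c[ci] <- rs[, 2L]
    tallies[[it]] <- data.frame(
      iteration = it,
      flower_id = rep(seq_len(nf), k),
      phenotype = rep(z, k),
      pollinator = rep(labels, each = nf),
      visits = visits_c,
      pollen_removed = removed_c,
      pollen_exported = exported_c
    )
  }
  tallies <- do.call(rbind, tallies)

  # every (iteration, flower) pair is present, so the across-iteration mean
  # of per-iteration totals is the grand per-flower sum over n_iterations
  per_flower <- function(col)
    rowsum(tallies[[col]], tallies$flower_id)[, 1L] / env$n_iterations
  flower_means <- data.frame(
    flower_id = seq_len(nf),
    phenotype = z,
    visits = as.numeric(per_flower("visits")),
    removal = as.numeric(per_flower("pollen_removed")),
    export = as.numeric(per_flower("pollen_exported"))
  )
  structure(list(tallies = tallies, flower_means = flower_means,
                 population = population, env = env),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %d flowers, %d iteration(s) x %d visits, guild [%s]>\n",
              x$population$n_flowers, x$env$n_iterations, x$env$total_visits,
              paste(vapply(x$env$guild, `[[`, character(1), "label"),
                    collapse = ", ")))
  invisible(x)
}

#' Additive single-environment baseline
#'
#' The non-interactive comparison: each pollinator is simulated alone, in a
#' single-pollinator environment with the same `total_visits` and
#' `n_iterations` (so each visitor delivers its full visit load,
#' undiminished by the others), and the per-flower mean visits, removal and
#' export are summed across pollinators. Because nothing couples the runs,
#' the sums can exceed physical bounds -- summed removal may exceed the
#' pollen a flower actually produces -- which is exactly the artefact the
#' interactive model corrects.
#'
#' Single environments use derived seeds `seed + 10000 * pollinator_index`
#' for independent streams. A single-pollinator guild has no interaction to
#' remove: the baseline then equals that environment's means (a notice is
#' emitted, not an error).
#'
#' @inheritParams simulate_environment
#' @return An object of class `additive_baseline`: a list with
#'   `flower_means` (columns `flower_id`, `phenotype`, `visits`, `removal`,
#'   `export`: sums across pollinators of single-environment means) and
#'   `per_pollinator` (the underlying `simulation_result` objects, named by
#'   label).
#' @export
additive_baseline <- function(population, env) {
  stopifnot(inherits(population, "flower_population"),
            inherits(env, "environment_config"))
  if (length(env$guild) == 1L)
    message("single-pollinator guild: the additive baseline equals the ",
            "single environment")
  singles <- vector("list", length(env$guild))
  names(singles) <- vapply(env$guild, `[[`, character(1), "label")
  for (p in seq_along(env$guild)) {
    env_p <- environment_config(guild = env$guild[p], mixture = 1,
                                total_visits = env$total_visits,
                                n_iterations = env$n_iterations,
                                seed = env$seed + 10000L * p)
    singles[[p]] <- simulate_environment(population, env_p)
  }
  fm <- singles[[1L]]$flower_means
  if (length(singles) > 1L) {
    for (p in 2L:length(singles)) {
      fm$visits <- fm$visits + singles[[p]]$flower_means$visits
      fm$removal <- fm$removal + singles[[p]]$flower_means$removal
      fm$export <- fm$export + singles[[p]]$flower_means$export
    }
  }
  structure(list(flower_means = fm, per_pollinator = singles,
                 population = population, env = env),
            class = "additive_baseline")
}

#' @export
print.additive_baseline <- function(x, ...) {
  cat(sprintf("<additive_baseline: %d single-pollinator environment(s) summed [%s]>\n",
              length(x$per_pollinator),
              paste(names(x$per_pollinator), collapse = ", ")))
  invisible(x)
}
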