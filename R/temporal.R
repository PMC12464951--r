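#' Temporal series of adaptive landscapes
#'
#' Pollinator climates vary among years and within seasons, so the
#' landscape a plant experiences is a weighted collection of epoch
#' landscapes. Weights accommodate unequal epoch lengths or frequencies and
#' are normalized to sum to 1 on construction.
#'
#' @param landscapes Nonempty list of `fitness_curve` objects, one per
#'   epoch.
#' @param weights Nonnegative epoch weights, not all zero; defaults to
#'   equal. Normalized to sum to 1.
#' @param grid A [phenotype_grid()] on which the series is aggregated.
#' @return An object of class `temporal_series`.
#' @export
temporal_series <- function(landscapes, weights = NULL,
                            grid = phenotype_grid()) {
  if (!is.list(landscapes) || length(landscapes) == 0L ||
      !all(vapply(landscapes, inherits, logical(1), "fitness_curve")))
    stop("`landscapes` must be a nonempty list of fitness_curve objects",
         call. = FALSE)
  if (is.null(weights))
    weights <- rep(1, length(landscapes))
  if (length(weights) != length(landscapes) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("`weights` must be nonnegative, one per epoch, not all zero",
         call. = FALSE)
  stopifnot(inherits(grid, "phenotype_grid"))
  structure(list(landscapes = landscapes,
                 weights = as.numeric(weights) / sum(weights), grid = grid),
            class = "temporal_series")
}

#' @export
print.temporal_series <- function(x, ...) {
  cat(sprintf("<temporal_series: %d epoch(s), weights (%s)>\n",
              length(x$landscapes),
              paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

series_values <- function(series) {
  z <- series$grid$points
  v <- vapply(series$landscapes, curve_value, numeric(length(z)), z = z)
  v <- matrix(v, nrow = length(z))
  if (any(v < 0))
    stop("epoch landscapes must be nonnegative", call. = FALSE)
  v
}

#' Geometric-mean fitness landscape over time
#'
#' Under temporally varying selection the favoured phenotype maximizes the
#' geometric mean fitness across epochs: `exp(sum_i w_i * log(f_i(z)))`
#' with weights summing to 1. The geometric mean is highly sensitive to low
#' values -- a single zero-fitness epoch (with positive weight) forces the
#' mean to zero at that phenotype, however productive the other epochs are,
#' which is why selection rarely favours exclusive reliance on a
#' temporally unreliable pollinator.
#'
#' @param series A [temporal_series()].
#' @return A tabulated `fitness_curve` on the series grid.
#' @export
geometric_mean_landscape <- function(series) {
  stopifnot(inherits(series, "temporal_series"))
  v <- series_values(series)
  w <- series$weights
  active <- w > 0
  # limit convention: any zero epoch value with positive weight pins the
  # geometric mean to exactly 0, bypassing log(0)
  lv <- log(v[, active, drop = FALSE])
  gm <- exp(as.vector(lv %*% w[active]))
  gm[rowSums(v[, active, drop = FALSE] == 0) > 0] <- 0
  make_tabulated_curve(series$grid$points, gm, label = "geometric mean")
}

#' Arithmetic-mean fitness landscape over time
#'
#' The weighted pointwise mean of the epoch landscapes: the comparison
#' baseline for [geometric_mean_landscape()]. By the AM-GM inequality it is
#' never below the geometric mean and is insensitive to occasional
#' zero-fitness epochs, which makes it overvalue unreliable contributors.
#'
#' @inheritParams geometric_mean_landscape
#' @return A tabulated `fitness_curve` on the series grid.
#' @export
arithmetic_mean_landscape <- function(series) {
  stopifnot(inherits(series, "temporal_series"))
  v <- series_values(series)
  make_tabulated_curve(series$grid$points, as.vector(v %*% series$weights),
                       label = "arithmetic mean")
}
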