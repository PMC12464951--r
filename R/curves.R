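#' Fitness curves: visitor-specific contributions to plant fitness
#'
#' A fitness curve maps a (normalized) floral phenotype to a nonnegative
#' contribution. Depending on its role the value is a visitation probability,
#' a pollen-removal amount (grains per visit), or a relative fitness. Three
#' forms are supported:
#'
#' * `gaussian`: `peak_value * exp(-(z - optimum)^2 / (2 * width^2))` --
#'   strictly positive, maximal at `optimum`, decreasing with distance.
#' * `flat`: the constant `peak_value` at every phenotype.
#' * `tabulated`: linear interpolation between knots, clamped to the
#'   endpoint values outside the knot range.
#'
#' @param optimum Phenotype at which a Gaussian curve peaks.
#' @param peak_value Curve value at the optimum (or everywhere, for flat
#'   curves). Must be nonnegative.
#' @param width Gaussian standard deviation on the phenotype axis
#'   (positive).
#' @param label Free-text label carried through summaries and output files.
#' @return An object of class `fitness_curve`.
#' @seealso [calibrate_gaussian_curve()] to build a Gaussian through two
#'   printed values, [curve_value()] to evaluate.
#' @examples
#' g <- make_gaussian_curve(0.25, 0.9, 0.24, label = "bee attraction")
#' curve_value(g, c(0.25, 0.75))
#' @export
make_gaussian_curve <- function(optimum, peak_value, width, label = "") {
  stopifnot(is.numeric(optimum), length(optimum) == 1L, is.finite(optimum))
  if (!is.numeric(peak_value) || length(peak_value) != 1L || peak_value < 0)
    stop("`peak_value` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("`width` must be a single positive number", call. = FALSE)
  new_fitness_curve(form = "gaussian", optimum = optimum,
                    peak_value = peak_value, width = width, label = label)
}

#' Calibrate a Gaussian fitness curve through two points
#'
#' Builds the unique Gaussian curve that takes `peak_value` at its own
#' optimum and `reference_value` at a second phenotype. This is how the
#' visitation and removal curves of a two-pollinator guild are specified:
#' each pollinator's curve is pinned at its own optimum and at the other
#' pollinator's optimum (e.g. 90% visitation probability at its own optimum
#' and 10% at the other, or 10000 grains removed per visit at its own
#' optimum and 2500 at the other). The width follows in closed form:
#'
#' `width = |reference_point - optimum| / sqrt(2 * log(peak_value / reference_value))`
#'
#' @param optimum Phenotype of the curve's peak.
#' @param peak_value Value at the optimum; must exceed `reference_value`.
#' @param reference_point A second phenotype, distinct from `optimum`.
#' @param reference_value Value the curve must take at `reference_point`;
#'   strictly between 0 and `peak_value`. Equal values describe a flat
#'   curve: use [make_flat_curve()] for that.
#' @param label Free-text label.
#' @return A Gaussian `fitness_curve` with `curve_value(., optimum) ==
#'   peak_value` and `curve_value(., reference_point) == reference_value`
#'   to machine precision.
#' @examples
#' att <- calibrate_gaussian_curve(0.25, 0.9, 0.75, 0.1)
#' curve_value(att, c(0.25, 0.75)) # 0.9, 0.1
#' @export
calibrate_gaussian_curve <- function(optimum, peak_value, reference_point,
                                     reference_value, label = "") {
  stopifnot(is.numeric(optimum), is.numeric(reference_point))
  if (reference_point == optimum)
    stop("`reference_point` must differ from `optimum`", call. = FALSE)
  if (!is.numeric(peak_value) || peak_value <= 0 ||
      !is.numeric(reference_value) || reference_value <= 0)
    stop("`peak_value` and `reference_value` must be positive", call. = FALSE)
  if (reference_value >= peak_value)
    stop("degenerate calibration: `reference_value` must be strictly below ",
         "`peak_value` (a Gaussian cannot rise away from its optimum; ",
         "use make_flat_curve() for a constant contribution)", call. = FALSE)
  width <- abs(reference_point - optimum) /
    sqrt(2 * log(peak_value / reference_value))
  make_gaussian_curve(optimum, peak_value, width, label = label)
}

#' Flat (phenotype-independent) fitness curve
#'
#' A constant contribution, used for visitors whose fitness contribution
#' changes little across the phenotype range, or as the additive identity
#' (`value = 0`).
#'
#' @param value The constant value, nonnegative.
#' @inheritParams make_gaussian_curve
#' @return A flat `fitness_curve`.
#' @export
make_flat_curve <- function(value, label = "") {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0)
    stop("`value` must be a single nonnegative number", call. = FALSE)
  new_fitness_curve(form = "flat", optimum = NA_real_, peak_value = value,
                    width = NA_real_, label = label)
}

#' Tabulated fitness curve
#'
#' A curve given by value knots at strictly increasing phenotypes.
#' Evaluation interpolates linearly between knots and clamps to the nearest
#' endpoint value outside the knot range. Combined landscapes
#' ([combine_additive()], [combine_components()]) are returned in this form.
#'
#' @param phenotype Strictly increasing numeric vector of knot phenotypes.
#' @param value Nonnegative values, one per knot.
#' @inheritParams make_gaussian_curve
#' @return A tabulated `fitness_curve`.
#' @export
make_tabulated_curve <- function(phenotype, value, label = "") {
  phenotype <- as.numeric(phenotype)
  value <- as.numeric(value)
  if (length(phenotype) < 2L || length(phenotype) != length(value))
    stop("need at least two (phenotype, value) knots of equal length",
         call. = FALSE)
  if (any(diff(phenotype) <= 0))
    stop("knot phenotypes must be strictly increasing", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("knot values must be finite and nonnegative", call. = FALSE)
  new_fitness_curve(form = "tabulated", optimum = NA_real_,
                    peak_value = max(value), width = NA_real_,
                    table = data.frame(phenotype = phenotype, value = value),
                    label = label)
}

new_fitness_curve <- function(form, optimum, peak_value, width,
                              table = NULL, label = "") {
  structure(list(form = form, optimum = optimum, peak_value = peak_value,
                 width = width, table = table, label = as.character(label)),
            class = "fitness_curve")
}

#' Evaluate a fitness curve
#'
#' @param curve A `fitness_curve`.
#' @param z Numeric vector of phenotypes.
#' @return Numeric vector of curve values, same length as `z`.
#' @export
curve_value <- function(curve, z) {
  stopifnot(inherits(curve, "fitness_curve"), is.numeric(z))
  switch(curve$form,
    gaussian = curve$peak_value *
      exp(-(z - curve$optimum)^2 / (2 * curve$width^2)),
    flat = rep(curve$peak_value, length(z)),
    tabulated = stats::approx(curve$table$phenotype, curve$table$value,
                              xout = z, rule = 2)$y,
    stop("unknown curve form: ", curve$form, call. = FALSE)
  )
}

#' Phenotype of a curve's own optimum
#'
#' For Gaussian curves this is the `optimum` field; for tabulated curves the
#' knot with the maximum value (the lowest-phenotype knot on ties). Flat
#' curves have no optimum and return `NA`.
#'
#' @param curve A `fitness_curve`.
#' @return A phenotype, or `NA_real_` for flat curves.
#' @export
curve_optimum <- function(curve) {
  stopifnot(inherits(curve, "fitness_curve"))
  switch(curve$form,
    gaussian = curve$optimum,
    flat = NA_real_,
    tabulated = curve$table$phenotype[which.max(curve$table$value)]
  )
}

#' @export
print.fitness_curve <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" \"", x$label, "\"") else ""
  switch(x$form,
    gaussian = cat(sprintf(
      "<fitness_curve%s: gaussian, optimum %.4g, peak %.4g, width %.4g>\n",
      lab, x$optimum, x$peak_value, x$width)),
    flat = cat(sprintf("<fitness_curve%s: flat, value %.4g>\n",
                       lab, x$peak_value)),
    tabulated = cat(sprintf(
      "<fitness_curve%s: tabulated, %d knots on [%.4g, %.4g], max %.4g>\n",
      lab, nrow(x$table), min(x$table$phenotype), max(x$table$phenotype),
      max(x$table$value)))
  )
  invisible(x)
}

#' Evenly spaced phenotype grid
#'
#' The evaluation grid for combining curves and summarizing landscapes.
#' Phenotypes are dimensionless and conventionally normalized to \[0, 1\].
#'
#' @param lo,hi Grid endpoints, `lo < hi`.
#' @param n_points Number of grid points (at least 3); endpoints included.
#' @return An object of class `phenotype_grid` with a `points` element.
#' @export
phenotype_grid <- function(lo = 0, hi = 1, n_points = 1001L) {
  if (!is.numeric(lo) || !is.numeric(hi) || !is.finite(lo) || !is.finite(hi) ||
      lo >= hi)
    stop("`lo` must be strictly below `hi`", call. = FALSE)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3L)
    stop("`n_points` must be an integer >= 3", call. = FALSE)
  structure(list(lo = lo, hi = hi, n_points = n_points,
                 points = seq(lo, hi, length.out = n_points)),
            class = "phenotype_grid")
}

#' @export
print.phenotype_grid <- function(x, ...) {
  cat(sprintf("<phenotype_grid: %d points on [%g, %g]>\n",
              x$n_points, x$lo, x$hi))
  invisible(x)
}
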