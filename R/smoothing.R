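#' Bin per-flower results and smooth over phenotype
#'
#' Groups flowers into equal-width phenotype bins, averages the per-flower
#' iteration means within each bin, and applies local-mean smoothing over
#' the bin centres with a box window of half-width `bandwidth` (expressed
#' as a fraction of the phenotype axis). Empty bins are recorded as missing
#' and skipped by the smoother. Before smoothing, the occupancy-weighted
#' mean of the binned values equals the overall per-flower mean.
#'
#' @param x A `simulation_result` or `additive_baseline` (anything with a
#'   `flower_means` data frame carrying `phenotype`, `visits`, `removal`,
#'   `export`).
#' @param metric One of `"visits"`, `"removal"`, `"export"`.
#' @param n_bins Number of equal-width bins (at least 3).
#' @param bandwidth Smoothing half-window as a fraction of the axis, in
#'   (0, 1). Values approaching 0 leave the binned means unsmoothed.
#' @return An object of class `smoothed_landscape`: a list with
#'   `bin_centre`, `smoothed`, `binned`, `occupancy`, `metric`, `n_bins`,
#'   `bandwidth`.
#' @export
bin_and_smooth <- function(x, metric = c("visits", "removal", "export"),
                           n_bins = 20L, bandwidth = 0.15) {
  metric <- match.arg(metric)
  fm <- x$flower_means
  if (is.null(fm))
    stop("`x` must carry a `flower_means` data frame ",
         "(simulation_result or additive_baseline)", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 3L)
    stop("`n_bins` must be an integer >= 3", call. = FALSE)
  if (!is.numeric(bandwidth) || bandwidth <= 0 || bandwidth >= 1)
    stop("`bandwidth` must lie strictly between 0 and 1", call. = FALSE)
  z <- fm$phenotype
  v <- fm[[metric]]
  lo <- min(z); hi <- max(z)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(z, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  binned <- rep(NA_real_, n_bins)
  occupancy <- tabulate(idx, nbins = n_bins)
  sums <- rowsum(v, idx)
  binned[as.integer(rownames(sums))] <- sums[, 1L] / occupancy[occupancy > 0]
  centres <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  half <- bandwidth * (hi - lo)
  ok <- !is.na(binned)
  smoothed <- vapply(seq_len(n_bins), function(j) {
    inw <- ok & abs(centres - centres[j]) <= half + 1e-12
    if (!any(inw)) NA_real_ else mean(binned[inw])
  }, numeric(1))
  structure(list(bin_centre = centres, smoothed = smoothed, binned = binned,
                 occupancy = occupancy, metric = metric, n_bins = n_bins,
                 bandwidth = bandwidth),
            class = "smoothed_landscape")
}

#' @export
print.smoothed_landscape <- function(x, ...) {
  cat(sprintf("<smoothed_landscape: %s, %d bins, bandwidth %g>\n",
              x$metric, x$n_bins, x$bandwidth))
  invisible(x)
}

#' Locate the optimum of a smoothed landscape
#'
#' @param smoothed A [bin_and_smooth()] result.
#' @return A list with `phenotype` (the bin centre of the maximum smoothed
#'   value; ties broken toward the lowest phenotype) and `value`.
#' @export
summarize_optima <- function(smoothed) {
  stopifnot(inherits(smoothed, "smoothed_landscape"))
  v <- smoothed$smoothed
  if (all(is.na(v)))
    stop("all smoothed values are missing", call. = FALSE)
  v[is.na(v)] <- -Inf
  i <- which.max(v)  # first maximum: ties go to the lowest bin centre
  list(phenotype = smoothed$bin_centre[i], value = smoothed$smoothed[i])
}
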