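#' Additive combination of visitor-specific fitness curves
#'
#' The combined adaptive surface under the assumption that each visitor's
#' contribution is independent of the others: the pointwise sum of the input
#' curves, tabulated on the supplied grid. Commutative and associative up to
#' floating-point tolerance.
#'
#' @param curves Nonempty list of `fitness_curve` objects.
#' @param grid A [phenotype_grid()].
#' @param label Label for the combined curve.
#' @return A tabulated `fitness_curve` on the grid points.
#' @export
combine_additive <- function(curves, grid = phenotype_grid(),
                             label = "additive combination") {
  if (!is.list(curves) || length(curves) == 0L ||
      !all(vapply(curves, inherits, logical(1), "fitness_curve")))
    stop("`curves` must be a nonempty list of fitness_curve objects",
         call. = FALSE)
  stopifnot(inherits(grid, "phenotype_grid"))
  z <- grid$points
  total <- Reduce(`+`, lapply(curves, curve_value, z = z))
  make_tabulated_curve(z, total, label = label)
}

#' Combine male and female fitness components
#'
#' Total fitness through both sexual pathways, either as the pointwise sum
#' (total reproductive output through two channels) or the pointwise
#' product, tabulated on the grid. With a flat female component under
#' `mode = "sum"` the combined optimum equals the male optimum: a flat
#' component cannot move the argmax.
#'
#' @param female,male Nonnegative `fitness_curve` objects.
#' @param mode `"sum"` (default) or `"product"`.
#' @inheritParams combine_additive
#' @return A tabulated `fitness_curve`.
#' @export
combine_components <- function(female, male, mode = c("sum", "product"),
                               grid = phenotype_grid()) {
  mode <- match.arg(mode)
  stopifnot(inherits(female, "fitness_curve"), inherits(male, "fitness_curve"),
            inherits(grid, "phenotype_grid"))
  z <- grid$points
  fv <- curve_value(female, z)
  mv <- curve_value(male, z)
  if (any(fv < 0) || any(mv < 0))
    stop("component curves must be nonnegative", call. = FALSE)
  v <- if (mode == "sum") fv + mv else fv * mv
  make_tabulated_curve(z, v, label = paste0(mode, " of components"))
}

#' Summarize an adaptive landscape on a grid
#'
#' Locates local and global optima, classifies modality, and measures the
#' valley depth and maximum steepness of a fitness curve evaluated on an
#' evenly spaced grid.
#'
#' Local optima are grid points whose value strictly exceeds both
#' neighbours; a plateau of equal values that exceeds its neighbours is
#' reported once, at its lowest-phenotype point. A maximum at a grid
#' endpoint (value strictly above its single neighbour) also counts as a
#' local optimum, so the global optimum is always a member of the list
#' unless the landscape is flat. The landscape is classified `flat` when
#' all grid values agree within a relative tolerance of 1e-12. Valley depth
#' is the global maximum minus the highest minimum separating two adjacent
#' local optima (0 unless multimodal). Steepness is the maximum absolute
#' slope `|dvalue/dphenotype|` over adjacent grid points.
#'
#' @param curve A `fitness_curve`.
#' @param grid A [phenotype_grid()].
#' @return An object of class `landscape_summary`: a list with elements
#'   `global_optimum`, `global_max`, `local_optima` (data frame of
#'   `phenotype`, `value`), `modality` (`"unimodal"`, `"multimodal"` or
#'   `"flat"`), `valley_depth` and `steepness`.
#' @export
summarize_landscape <- function(curve, grid = phenotype_grid()) {
  stopifnot(inherits(curve, "fitness_curve"), inherits(grid, "phenotype_grid"))
  z <- grid$points
  v <- curve_value(curve, z)
  if (any(!is.finite(v)))
    stop("curve evaluates to non-finite values on the grid", call. = FALSE)
  steep <- max(abs(diff(v)) / diff(z))
  scale <- max(abs(v))
  if (scale == 0 || (max(v) - min(v)) <= 1e-12 * scale) {
    return(structure(list(global_optimum = z[1L], global_max = v[1L],
                          local_optima = data.frame(phenotype = numeric(0),
                                                    value = numeric(0)),
                          modality = "flat", valley_depth = 0,
                          steepness = steep),
                     class = "landscape_summary"))
  }
  # collapse plateaus, keep the lowest-phenotype index of each run
  r <- rle(v)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  rv <- r$values
  nr <- length(rv)
  left <- c(-Inf, rv[-nr])   # -Inf: an endpoint run needs only beat its
  right <- c(rv[-1L], -Inf)  # single inner neighbour
  is_max <- rv > left & rv > right
  opt_idx <- run_start[is_max]
  local <- data.frame(phenotype = z[opt_idx], value = v[opt_idx])
  gi <- opt_idx[which.max(v[opt_idx])]
  modality <- if (nrow(local) > 1L) "multimodal" else "unimodal"
  valley <- 0
  if (modality == "multimodal") {
    seps <- vapply(seq_len(length(opt_idx) - 1L), function(i)
      min(v[opt_idx[i]:opt_idx[i + 1L]]), numeric(1))
    valley <- max(v) - max(seps)
  }
  structure(list(global_optimum = z[gi], global_max = v[gi],
                 local_optima = local, modality = modality,
                 valley_depth = valley, steepness = steep),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf("<landscape_summary: %s; global optimum %.4g (value %.4g); %d local optimum(a); valley depth %.4g; steepness %.4g>\n",
              x$modality, x$global_optimum, x$global_max,
              nrow(x$local_optima), x$valley_depth, x$steepness))
  invisible(x)
}

#' Which visitor's own optimum is closest to the combined optimum?
#'
#' A combined landscape whose peak broadly matches one visitor's own
#' optimum suggests that visitor dominates the adaptive surface; a peak far
#' from every contributor marks adaptive generalization. Flat visitor
#' curves have no optimum and are excluded with a warning; ties are broken
#' toward the visitor listed first.
#'
#' @param combined A `landscape_summary` of the combined curve.
#' @param visitors Named list of `fitness_curve` objects (names are visitor
#'   labels), or an unnamed list of curves carrying their own labels.
#' @return A list with elements `label` and `distance` (absolute phenotype
#'   distance from the combined global optimum).
#' @export
nearest_contributor <- function(combined, visitors) {
  stopifnot(inherits(combined, "landscape_summary"))
  if (!is.list(visitors) || length(visitors) == 0L)
    stop("`visitors` must be a nonempty list of fitness_curve objects",
         call. = FALSE)
  labs <- names(visitors)
  if (is.null(labs))
    labs <- vapply(visitors, function(cv) cv$label, character(1))
  labs[!nzchar(labs)] <- paste0("visitor_", which(!nzchar(labs)))
  opts <- vapply(visitors, curve_optimum, numeric(1))
  if (any(is.na(opts)))
    warning("flat visitor curve(s) have no optimum and were excluded: ",
            paste(labs[is.na(opts)], collapse = ", "), call. = FALSE)
  keep <- !is.na(opts)
  if (!any(keep))
    stop("no visitor curve has a defined optimum", call. = FALSE)
  d <- abs(opts[keep] - combined$global_optimum)
  i <- which.min(d)  # first minimum: ties go to the earliest-listed visitor
  list(label = labs[keep][i], distance = unname(d[i]))
}
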