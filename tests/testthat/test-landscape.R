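test_that("additive combination equals independent per-point summation", {
  grid <- phenotype_grid(0, 1, 101)
  curves <- list(make_gaussian_curve(0.25, 0.9, 0.24),
                 make_gaussian_curve(0.75, 0.5, 0.1),
                 make_flat_curve(0.3))
  comb <- combine_additive(curves, grid)
  # oracle: explicit loop, no vectorized reuse of the implementation path
  expected <- numeric(grid$n_points)
  for (i in seq_len(grid$n_points))
    for (cv in curves)
      expected[i] <- expected[i] + curve_value(cv, grid$points[i])
  expect_identical(comb$table$value, expected)
  expect_error(combine_additive(list(), grid), "nonempty")

  # commutative up to floating tolerance
  comb_rev <- combine_additive(rev(curves), grid)
  expect_equal(comb_rev$table$value, comb$table$value)
})

test_that("a flat contribution never moves the combined optimum", {
  grid <- phenotype_grid(0, 1, 1001)
  g <- make_gaussian_curve(0.75, 0.9, 0.24)
  comb <- combine_additive(list(make_flat_curve(0.5), g), grid)
  s <- summarize_landscape(comb, grid)
  expect_equal(s$global_optimum, 0.75)

  # property: adding any flat curve preserves the argmax
  set.seed(7)
  for (i in 1:20) {
    base <- make_gaussian_curve(runif(1, 0.1, 0.9), runif(1, 0.5, 3),
                                runif(1, 0.05, 0.3))
    s0 <- summarize_landscape(base, grid)
    shifted <- combine_additive(list(base, make_flat_curve(runif(1, 0, 10))),
                                grid)
    expect_equal(summarize_landscape(shifted, grid)$global_optimum,
                 s0$global_optimum)
  }
})

test_that("two equal Gaussians merge or split according to their separation", {
  grid <- phenotype_grid(0, 1, 10001)

  close_pair <- combine_additive(list(make_gaussian_curve(0.4, 1, 0.2),
                                      make_gaussian_curve(0.6, 1, 0.2)), grid)
  s1 <- summarize_landscape(close_pair, grid)
  bf1 <- brute_force_two_gaussians(0.4, 1, 0.2, 0.6, 1, 0.2)
  expect_equal(s1$modality, "unimodal")
  expect_equal(bf1$n_maxima, 1L)
  expect_equal(s1$global_optimum, 0.5, tolerance = 1e-4)
  expect_equal(s1$global_optimum, bf1$argmax)

  far_pair <- combine_additive(list(make_gaussian_curve(0.2, 1, 0.1),
                                    make_gaussian_curve(0.8, 1, 0.1)), grid)
  s2 <- summarize_landscape(far_pair, grid)
  bf2 <- brute_force_two_gaussians(0.2, 1, 0.1, 0.8, 1, 0.1)
  expect_equal(s2$modality, "multimodal")
  expect_equal(bf2$n_maxima, 2L)
  expect_equal(sort(s2$local_optima$phenotype), sort(bf2$maxima),
               tolerance = 1e-3)
  expect_gt(s2$valley_depth, 0)
  # the separating valley sits at the symmetry point
  mid <- 0.5
  expect_equal(s2$global_max - s2$valley_depth,
               curve_value(far_pair, mid), tolerance = 1e-6)
})

test_that("modality classification matches brute force across separations", {
  grid <- phenotype_grid(0, 1, 10001)
  w <- 0.08
  for (sep in c(0.5, 1.5, 2.5, 4) * w) {
    o1 <- 0.5 - sep / 2
    o2 <- 0.5 + sep / 2
    comb <- combine_additive(list(make_gaussian_curve(o1, 1, w),
                                  make_gaussian_curve(o2, 1, w)), grid)
    s <- summarize_landscape(comb, grid)
    bf <- brute_force_two_gaussians(o1, 1, w, o2, 1, w)
    expect_equal(s$modality == "multimodal", bf$n_maxima > 1L,
                 info = sprintf("separation %g widths", sep / w))
  }
})

test_that("landscape summary follows the stated grid definitions", {
  grid <- phenotype_grid(0, 1, 5)
  tc <- make_tabulated_curve(grid$points, c(1, 3, 2, 5, 4))
  s <- summarize_landscape(tc, grid)
  expect_equal(s$local_optima$phenotype, c(0.25, 0.75))
  expect_equal(s$global_optimum, 0.75)
  expect_equal(s$global_max, 5)
  expect_equal(s$modality, "multimodal")
  expect_equal(s$valley_depth, 3)  # 5 - 2

  # plateaus reported once, at their lowest-phenotype point
  tp <- make_tabulated_curve(grid$points, c(1, 3, 3, 3, 1))
  sp <- summarize_landscape(tp, grid)
  expect_equal(sp$local_optima$phenotype, 0.25)
  expect_equal(sp$modality, "unimodal")

  sf <- summarize_landscape(make_flat_curve(0.5), grid)
  expect_equal(sf$modality, "flat")
  expect_equal(sf$steepness, 0)
  expect_equal(sf$valley_depth, 0)
  expect_equal(nrow(sf$local_optima), 0L)
})

test_that("Gaussian steepness converges to peak * exp(-1/2) / width", {
  g <- make_gaussian_curve(0.6, 1, 0.2)
  closed_form <- 1 * exp(-0.5) / 0.2
  s_coarse <- summarize_landscape(g, phenotype_grid(0, 1, 10001))
  expect_equal(s_coarse$steepness, closed_form, tolerance = 1e-2)
  expect_equal(s_coarse$steepness, 3.033, tolerance = 1e-3)
  expect_equal(s_coarse$global_optimum, 0.6, tolerance = 1e-4)
  s_fine <- summarize_landscape(g, phenotype_grid(0, 1, 100001))
  expect_equal(s_fine$steepness, closed_form, tolerance = 1e-3)
})

test_that("male/female components combine by sum or product", {
  grid <- phenotype_grid(0, 1, 1001)
  male <- make_gaussian_curve(0.7, 2, 0.2)

  # a flat female component leaves the optimum to the male component
  both <- combine_components(make_flat_curve(1), male, "sum", grid)
  expect_equal(summarize_landscape(both, grid)$global_optimum, 0.7)

  # equal opposed components compromise at the midpoint
  f <- make_gaussian_curve(0.3, 1, 0.25)
  m <- make_gaussian_curve(0.7, 1, 0.25)
  mid <- combine_components(f, m, "sum", grid)
  bf <- brute_force_two_gaussians(0.3, 1, 0.25, 0.7, 1, 0.25, n = 10001)
  expect_equal(summarize_landscape(mid, grid)$global_optimum, 0.5,
               tolerance = 1e-3)
  expect_equal(bf$argmax, 0.5, tolerance = 1e-4)

  # multiplicative zero propagates
  gate <- make_tabulated_curve(c(0, 0.5, 0.50001, 1), c(0, 0, 1, 1))
  prod <- combine_components(gate, male, "product", grid)
  low <- grid$points <= 0.5
  expect_true(all(curve_value(prod, grid$points[low]) == 0))
  expect_true(any(curve_value(prod, grid$points[!low]) > 0))

  expect_error(combine_components(f, m, "geometric"), "arg")
})

test_that("nearest_contributor identifies the visitor behind the peak", {
  grid <- phenotype_grid(0, 1, 1001)
  bee <- make_gaussian_curve(0.25, 0.9, 0.24)
  hawkmoth <- make_gaussian_curve(0.75, 0.9, 0.24)
  comb <- combine_additive(list(make_flat_curve(0.5), hawkmoth), grid)
  s <- summarize_landscape(comb, grid)
  nc <- nearest_contributor(s, list(bee = bee, hawkmoth = hawkmoth))
  expect_equal(nc$label, "hawkmoth")
  expect_equal(nc$distance, 0)

  # exact tie: first-listed visitor wins
  s_mid <- summarize_landscape(
    combine_additive(list(make_gaussian_curve(0.4, 1, 0.2),
                          make_gaussian_curve(0.6, 1, 0.2)), grid), grid)
  nc_tie <- nearest_contributor(
    s_mid, list(a = make_gaussian_curve(0.4, 1, 0.2),
                b = make_gaussian_curve(0.6, 1, 0.2)))
  expect_equal(nc_tie$label, "a")
  expect_equal(nc_tie$distance, 0.1, tolerance = 1e-3)

  # flat visitors have no optimum
  expect_warning(
    nc2 <- nearest_contributor(s, list(steady = make_flat_curve(0.5),
                                       hawkmoth = hawkmoth)),
    "excluded")
  expect_equal(nc2$label, "hawkmoth")
  expect_error(
    suppressWarnings(nearest_contributor(s, list(make_flat_curve(1)))),
    "no visitor curve")
})
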