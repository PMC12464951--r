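# Shared fixtures: the bundled two-pollinator reference guild and an
# independent brute-force landscape oracle used to cross-check the
# summarize_landscape code path.

ref_cfg <- function(seed = NULL) reference_config(seed)

bee_spec <- function() ref_cfg()$guild[[1L]]
bird_spec <- function() ref_cfg()$guild[[2L]]

# Direct-formula brute force for a sum of two Gaussians: evaluates the
# exponentials inline (no fitness_curve machinery), locates the argmax and
# counts strict interior maxima on a dense grid.
brute_force_two_gaussians <- function(o1, p1, w1, o2, p2, w2,
                                      n = 10001L, lo = 0, hi = 1) {
  z <- seq(lo, hi, length.out = n)
  v <- p1 * exp(-(z - o1)^2 / (2 * w1^2)) + p2 * exp(-(z - o2)^2 / (2 * w2^2))
  interior_max <- which(diff(sign(diff(v))) == -2L) + 1L
  list(z = z, v = v,
       argmax = z[which.max(v)],
       n_maxima = length(interior_max),
       maxima = z[interior_max])
}

# A tiny environment for fast deterministic checks.
tiny_env <- function(guild, mixture = NULL, total_visits = 50L,
                     n_iterations = 2L, seed = 42L) {
  environment_config(guild, mixture, total_visits, n_iterations, seed)
}
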