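test_that("build_population spans the range evenly with equal budgets", {
  pop <- build_population(100, 0, 1, 160000)
  expect_equal(pop$n_flowers, 100L)
  expect_equal(pop$phenotypes, seq(0, 1, length.out = 100))
  expect_equal(pop$pollen_budget, 160000)

  expect_equal(build_population(2, 0, 1, 10)$phenotypes, c(0, 1))
  expect_error(build_population(1, 0, 1, 10), ">= 2")
  expect_error(build_population(10, 1, 0, 10), "strictly below")
  expect_error(build_population(10, 0, 1, 0), "positive")
})

test_that("a single visit removes and exports the calibrated amounts", {
  # hummingbird visiting a fresh flower at its own optimum: the full
  # calibrated removal, 4% of it exported
  flower <- flower_population(0.75, 160000)
  env <- environment_config(list(bird_spec()), 1, total_visits = 1,
                            n_iterations = 1, seed = 3)
  res <- simulate_environment(flower, env)
  expect_equal(res$tallies$visits, 1L)
  expect_equal(res$tallies$pollen_removed, 10000)
  expect_equal(res$tallies$pollen_exported, 400)

  # removal is bounded by the pollen remaining
  poor <- flower_population(0.5, 1000)   # curve value 10000/sqrt(2) ~ 7071
  res2 <- simulate_environment(poor, environment_config(
    list(bird_spec()), 1, total_visits = 1, n_iterations = 1, seed = 3))
  expect_equal(res2$tallies$pollen_removed, 1000)
  # further visits find the flower empty and remove nothing
  res3 <- simulate_environment(poor, environment_config(
    list(bird_spec()), 1, total_visits = 10, n_iterations = 1, seed = 3))
  expect_equal(sum(res3$tallies$visits), 10L)
  expect_equal(sum(res3$tallies$pollen_removed), 1000)
})

test_that("every iteration executes exactly the configured number of visits", {
  cfg <- ref_cfg(seed = 11)
  res <- simulate_environment(cfg$population, cfg$environment)
  per_iter <- tapply(res$tallies$visits, res$tallies$iteration, sum)
  expect_true(all(per_iter == 3500L))
  expect_equal(length(per_iter), 10L)
})

test_that("pollen accounting respects budgets and transfer efficiencies", {
  cfg <- ref_cfg(seed = 5)
  res <- simulate_environment(cfg$population, cfg$environment)
  key <- paste(res$tallies$iteration, res$tallies$flower_id)
  removed <- tapply(res$tallies$pollen_removed, key, sum)
  exported <- tapply(res$tallies$pollen_exported, key, sum)
  expect_true(all(removed >= 0))
  expect_true(all(removed <= 160000 + 1e-9))
  expect_true(all(exported <= removed * 0.04 + 1e-9))
  # per-pollinator export is exactly removed * that pollinator's efficiency
  eff <- ifelse(res$tallies$pollinator == "bee", 0.02, 0.04)
  expect_equal(res$tallies$pollen_exported,
               res$tallies$pollen_removed * eff)
})

test_that("identical seeds reproduce results exactly; seeds matter", {
  cfg <- ref_cfg(seed = 21)
  cfg$environment$n_iterations <- 2L
  a <- simulate_environment(cfg$population, cfg$environment)
  b <- simulate_environment(cfg$population, cfg$environment)
  expect_identical(a$tallies, b$tallies)
  cfg$environment$seed <- 22L
  c <- simulate_environment(cfg$population, cfg$environment)
  expect_false(identical(a$tallies$visits, c$tallies$visits))
})

test_that("a degenerate mixture equals the single-pollinator environment", {
  cfg <- ref_cfg()
  pop <- cfg$population
  mixed10 <- environment_config(cfg$guild, c(1, 0), total_visits = 500,
                                n_iterations = 3, seed = 9)
  bee_only <- environment_config(cfg$guild[1], 1, total_visits = 500,
                                 n_iterations = 3, seed = 9)
  expect_identical(simulate_environment(pop, mixed10)$tallies,
                   simulate_environment(pop, bee_only)$tallies)
})

test_that("visit allocation follows normalized attraction weights", {
  # depletion disabled (zero removal): visit counts are multinomial with
  # probabilities proportional to attraction
  pop <- build_population(10, 0, 1, 100)
  att <- calibrate_gaussian_curve(0.4, 0.9, 0.9, 0.2)
  spec <- pollinator_spec("probe", att, make_flat_curve(0),
                          transfer_efficiency = 0.05)
  env <- environment_config(list(spec), 1, total_visits = 5000,
                            n_iterations = 4, seed = 17)
  res <- simulate_environment(pop, env)
  observed <- tapply(res$tallies$visits, res$tallies$flower_id, sum)
  p <- curve_value(att, pop$phenotypes)
  p <- p / sum(p)
  expect_true(all(20000 * p >= 5))  # chi-square validity
  gof <- suppressWarnings(stats::chisq.test(observed, p = p))
  expect_gt(gof$p.value, 0.01)
  expect_true(all(res$tallies$pollen_removed == 0))
})

test_that("misconfigured environments fail with clear errors", {
  cfg <- ref_cfg()
  dead <- pollinator_spec("ghost", make_flat_curve(0), make_flat_curve(10),
                          0.5)
  env <- environment_config(list(dead), 1, 10, 1, 1)
  expect_error(simulate_environment(cfg$population, env),
               "no flower can be chosen")
  expect_error(environment_config(cfg$guild, c(0.6, 0.6)), "sum to 1")
  expect_error(environment_config(list(), NULL), "nonempty")
})

test_that("the additive baseline sums independent single-pollinator runs", {
  cfg <- ref_cfg(seed = 31)
  cfg$environment$n_iterations <- 3L
  add <- additive_baseline(cfg$population, cfg$environment)
  expect_named(add$per_pollinator, c("bee", "hummingbird"))
  manual <- add$per_pollinator$bee$flower_means$export +
    add$per_pollinator$hummingbird$flower_means$export
  expect_equal(add$flower_means$export, manual)
  # seed offsets: each single run is reproducible in isolation
  env1 <- environment_config(cfg$guild[1], 1, cfg$environment$total_visits,
                             3L, cfg$environment$seed + 10000L)
  expect_identical(add$per_pollinator$bee$tallies,
                   simulate_environment(cfg$population, env1)$tallies)

  # a single-pollinator guild: baseline equals the environment, with a notice
  solo <- environment_config(cfg$guild[1], 1, 200, 2, 8)
  expect_message(add1 <- additive_baseline(cfg$population, solo),
                 "single-pollinator")
  env_solo <- environment_config(cfg$guild[1], 1, 200, 2, 8 + 10000L)
  expect_equal(add1$flower_means,
               simulate_environment(cfg$population, env_solo)$flower_means)
})
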