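# floralscape

Floral adaptive landscapes from visitor-specific fitness contributions.

Plants pollinated by several visitor types — say bees and hummingbirds —
experience an adaptive landscape built from each visitor's fitness
contribution, and that landscape is generally **not** the sum of the
single-visitor curves. Visits and pollen grains are finite: a grain removed
by a visitor that grooms and eats most of it is a grain a more efficient
visitor can no longer export. floralscape is for evolutionary ecologists who
want to explore how these opportunity trade-offs reshape floral optima,
without field data: everything is driven by a plain-text description of a
flower population, a pollinator guild and an environment.

## What it computes

**Curve algebra.** Visitor-specific fitness curves on a normalized
phenotype axis: Gaussian $v(z) = p\,e^{-(z-\mu)^2/2\sigma^2}$, flat, or
tabulated. A Gaussian is calibrated through two printed values with
$\sigma = |z_{\mathrm{ref}}-\mu| / \sqrt{2\ln(p/v_{\mathrm{ref}})}$.
Curves combine additively (`combine_additive()`) or as male x female
fitness components (`combine_components()`, sum or product), and
`summarize_landscape()` reports optima, modality (unimodal / multimodal /
flat), valley depth and steepness; `nearest_contributor()` asks which
visitor's own optimum the combined peak matches.

**Stochastic visitation simulator.** `simulate_environment()` runs seeded
iterations of exactly `total_visits` visit events: each event draws a
pollinator from the mixture weights, draws a flower in proportion to that
pollinator's attraction at each phenotype, removes
`min(removal_curve(z), remaining pollen)` grains, and exports
`removed x transfer_efficiency` of them; the rest is lost.
`additive_baseline()` simulates each pollinator alone with the same visit
load and sums the means — the "no interaction" comparison, which can
(informatively) exceed physical bounds. `bin_and_smooth()` +
`summarize_optima()` turn per-flower tallies into the smoothed
per-phenotype landscapes and their peaks.

**Temporal aggregation.** `geometric_mean_landscape()` computes
$\exp\{\sum_i w_i \ln f_i(z)\}$ across epochs — the quantity selection
maximizes under temporal variation, pinned to 0 wherever any epoch has zero
fitness — against the arithmetic-mean baseline.

## Worked example

The bundled reference configuration describes 100 flowers (160 000 pollen
grains each, phenotypes evenly spanning [0, 1]) visited 3 500 times per
iteration by an equal mixture of a bee (optimum 0.25, transfer efficiency
2%) and a hummingbird (optimum 0.75, efficiency 4%), each with attraction
0.9 at its own optimum and 0.1 at the other's, and removal 10 000 versus
2 500 grains per visit.

```r
library(floralscape)

att <- calibrate_gaussian_curve(0.25, 0.9, 0.75, 0.1, label = "bee attraction")
att
#> <fitness_curve "bee attraction": gaussian, optimum 0.25, peak 0.9, width 0.2385>
round(curve_value(att, c(0.25, 0.5, 0.75)), 4)
#> [1] 0.9000 0.5196 0.1000

cfg <- reference_config(seed = 1)
mixed    <- simulate_environment(cfg$population, cfg$environment)
baseline <- additive_baseline(cfg$population, cfg$environment)

str(summarize_optima(bin_and_smooth(mixed, "export")))
#> List of 2
#>  $ phenotype: num 0.925
#>  $ value    : num 6277
str(summarize_optima(bin_and_smooth(baseline, "export")))
#> List of 2
#>  $ phenotype: num 0.575
#>  $ value    : num 8549
max(baseline$flower_means$removal)
#> [1] 320000
```

Read: in the mixed environment the pollen-export optimum (0.925) is *more
extreme* than the hummingbird's own optimum (0.75) — the best phenotype
filters out the wasteful bee — while the additive baseline misleadingly
puts the optimum at an intermediate 0.575 and claims peak removal of
320 000 grains from flowers that only produce 160 000.

The same analysis from a shell, with CSV and JSON outputs:

```sh
Rscript inst/scripts/floralscape-sim \
  --config inst/extdata/reference.json --environment all --seed 7 --out-dir out/
```

writes per-flower tallies, smoothed landscapes (interactive and additive)
and a `summary.json` with per-metric optima; every file embeds the seed,
config hash and package version, and reruns with the same flags are
byte-identical.

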