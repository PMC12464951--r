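---
title: "Methods: composing and simulating floral adaptive landscapes"
author: "floralscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composing and simulating floral adaptive landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralscape)
```

## The problem

A flower visited by several pollinator functional groups does not experience
one fitness function per visitor plus a free lunch: visits and pollen grains
are finite. A bee that removes pollen and grooms most of it away has consumed
a resource a hummingbird could have exported. The plant's adaptive landscape
— total fitness as a function of floral phenotype — is therefore generally
*not* the sum of the single-visitor fitness curves, and the phenotype it
favours can lie outside every visitor's own optimum. floralscape provides
the pieces needed to explore this: a deterministic algebra of
visitor-specific fitness curves, a stochastic visitation/pollen-export
simulator with its additive baseline, and geometric-mean aggregation across
temporally varying pollinator climates.

## Fitness curves and their algebra

All phenotypes live on a dimensionless normalized axis, conventionally
$[0, 1]$; the two reference pollinator optima are placed at 0.25 and 0.75.
There is no numeric trait scale in the source material for these landscapes,
so a fixed normalized placement is what makes every example reproducible.

A `fitness_curve` is one of:

* **gaussian** — $v(z) = p\,e^{-(z - \mu)^2 / 2\sigma^2}$, with optimum
  $\mu$, peak value $p$ and width $\sigma$;
* **flat** — a constant (a visitor whose contribution barely changes over
  the range, or the additive identity at 0);
* **tabulated** — linear interpolation between knots, clamped to the
  endpoint values outside the knot range. Combined landscapes are returned
  in this form.

The reference curves are specified by only two printed values — the value
at the visitor's own optimum and at the other visitor's optimum — which,
given the optimum, determine a Gaussian exactly. `calibrate_gaussian_curve()`
solves the closed form

$$\sigma = \frac{|z_{\mathrm{ref}} - \mu|}{\sqrt{2\ln(p / v_{\mathrm{ref}})}},$$

so e.g. a 0.9/0.1 attraction pair half an axis apart gives
$\sigma = 0.5/\sqrt{2\ln 9} \approx 0.2385$. Equal peak and reference values
have no Gaussian solution (infinite width) and are rejected; a constant
contribution is requested explicitly via `make_flat_curve()`. Treating the
drawn curves as exact Gaussians is a modelling choice, not a claim about
any empirical system: the family is the simplest one pinned down by two
values, and the tabulated form is available for anything else.

`combine_additive()` tabulates the pointwise sum on a caller-supplied grid;
it accumulates with a left fold so the result is bit-identical to a naive
per-point loop. `combine_components()` merges male and female fitness
pathways by pointwise sum (default) or product. The sum is the default
because total reproductive output through two channels is conventionally
additive; the product is exposed under its own name for users who want
fitness pathways to gate each other multiplicatively, so no silent choice
is made between the two readings.

`summarize_landscape()` works on an evenly spaced grid: local optima are
grid points whose value strictly exceeds both neighbours; a plateau of
equal values is reported once at its lowest-phenotype point; a maximum at a
grid endpoint (value strictly above its single inner neighbour) also
counts, so the global optimum is always a member of the local-optima list
on non-flat landscapes — without that, a monotone landscape would have a
global optimum belonging to no local optimum. A landscape is classified
flat when all grid values agree within a relative tolerance of $10^{-12}$
(floating-point robustness, not a biological threshold). Valley depth is
the global maximum minus the highest minimum separating two adjacent local
optima; steepness is the maximum absolute slope over adjacent grid pairs,
which for a Gaussian converges to $p\,e^{-1/2}/\sigma$ as the grid is
refined. `nearest_contributor()` breaks exact ties toward the
earliest-listed visitor, again for determinism; flat visitors have no
optimum and are excluded with a warning.

## The stochastic visitation model

`simulate_environment()` simulates a population of flowers (default: 100
flowers, evenly spaced phenotypes spanning both optima, 160 000 pollen
grains each) visited by a guild (reference guild: a bee, optimum 0.25,
transfer efficiency 2%, and a hummingbird, optimum 0.75, efficiency 4%;
attraction 0.9/0.1 and removal 10 000/2 500 at own/other optimum). Each of
the `n_iterations` (default 10) iterations resets every flower to its full
budget and executes exactly `total_visits` (default 3 500) events:

1. a pollinator is drawn from the mixture weights;
2. a target flower is drawn with probability proportional to that
   pollinator's attraction value at each flower's phenotype;
3. the visit removes `min(removal_curve(z), remaining)` grains;
4. `removed × transfer_efficiency` grains are credited to the flower's
   pollen export; the rest is lost from the system (grooming, consumption).

Model assumptions worth making explicit:

* **Fixed visit total.** Exactly `total_visits` events occur per
  iteration, allocated by per-event categorical draws. This keeps the
  visit budget pinned at its configured value while preserving per-event
  randomness; the opportunity trade-off (a visit used by one pollinator is
  unavailable to the other) follows directly from the fixed total.
* **Attraction ignores depletion.** Depletion reduces what a visit
  removes, not how attractive a flower is, and emptied flowers still
  receive (fruitless) visits. Because of this independence, the
  event-by-event process factorizes: all draws can be made up front and
  removal capped cumulatively per flower, which is how the implementation
  vectorizes the sequential model without changing its distribution.
* **Source-side accounting only.** Export is credited to the flower whose
  pollen was removed; deposition on recipient stigmas, carryover chains,
  selfing and seed set are out of scope.
* **No evolution.** The model scores a single selective episode; it does
  not iterate generations.

Reproducibility: iteration $i$ is seeded with `seed + i`, and the additive
baseline's single-pollinator runs with `seed + 10000 × pollinator index`,
giving independent, individually re-runnable streams. Pollinators with zero
mixture weight are dropped before sampling, so a degenerate mixture
`(1, 0)` is bit-identical to the corresponding single-pollinator
environment.

`additive_baseline()` answers "what would we conclude if contributions
added?": each pollinator is simulated alone with the *same* visit total and
the per-flower means are summed. Nothing couples the runs, so summed
removal can exceed what a flower actually produces — the diagnostic
artefact of assuming additivity with finite resources.

## Binning and smoothing

`bin_and_smooth()` groups flowers into `n_bins` equal-width phenotype bins
(default 20, i.e. five flowers per bin for the reference population),
averages the per-flower iteration means within bins, and smooths over bin
centres with a local mean whose box half-window is `bandwidth` (default
0.15) as a fraction of the axis. The smoothing procedure behind any
particular published panel is generally unstated, so the choice here is
deliberately the simplest explicit one, recorded in the output object and
overridable from the configuration and CLI; defaults were fixed before the
figure-reproduction checks were run and are part of the study conditions.
Empty bins are recorded as missing and skipped. Before smoothing, the
occupancy-weighted mean of binned values equals the overall per-flower mean
to $10^{-9}$ relative error — the binning invariant the tests assert.
`summarize_optima()` reports the bin centre of the maximum smoothed value,
ties toward the lowest phenotype.

## Temporal variation

Pollinator climates vary among years and within seasons. Under temporal
variation, selection favours the phenotype with the highest *geometric*
mean fitness across epochs, $\exp\{\sum_i w_i \ln f_i(z)\}$ with
normalized weights, which is highly sensitive to low values: any epoch with
zero fitness at a phenotype (with positive weight) pins the geometric mean
to exactly 0 there. That limit convention is implemented directly, rather
than through `log(0)` arithmetic, to avoid underflow paths.
`arithmetic_mean_landscape()` is the comparison baseline; by AM–GM it is
never below the geometric mean. The practical consequence, exercised in the
tests, is that a spectacular but intermittent contributor loses to a modest
reliable one under the geometric mean while the arithmetic mean chases the
spectacular peak. Epoch weights are exposed (and normalized on
construction) rather than fixed, because the appropriate weighting of
seasons versus years is a question about the study system, not the method.

## What the synthetic fixtures do and do not show

`generate_fixture_guild()` produces seeded random guilds (optima, peaks,
cross-values, efficiencies within stated ranges) plus the exact reference
guild as fixture 0. These fixtures emulate the *structure* of a pollinator
guild — unimodal preference curves, bounded attraction, efficiencies well
below 1 — under idealized conditions: Gaussian curves, equal budgets,
uniform phenotype spacing, visitor behaviour constant in time. Passing
tests on them demonstrate the internal consistency of the framework
(conservation, determinism, the additive-versus-interactive contrast), not
that any real guild behaves this way: real attraction curves need not be
unimodal or symmetric, budgets and phenotypes are heterogeneous, and
pollinator behaviour responds to standing crop in ways the
attraction-independence assumption deliberately excludes.

## Problem sizes and numerical choices

The packaged analyses run at full configured size: landscape diagnostics on
grids of 1 001–10 001 points (100 001 for the steepness-convergence check),
and the simulator at 100 flowers × 3 500 visits × 10 iterations, with the
figure-level contrasts replicated over ten seeds; the whole suite completes
in seconds because event capping is vectorized per flower. Other
conventions, gathered in one place: flat-classification tolerance
$10^{-12}$ relative; plateau optima reported at their lowest phenotype;
`nearest_contributor` and `summarize_optima` ties toward the first /
lowest; tabulated curves clamp outside their knots; removal is bounded by
remaining pollen rather than retiring emptied flowers.

## Known limitations

Single-trait landscapes only (no multivariate phenotypes); no estimation
from field data (spline fitting of empirical fitness measurements is a data
analysis task outside this package); no recipient-side pollination events,
carryover, or geitonogamy; no demographic or evolutionary dynamics. These
boundaries are deliberate: the package isolates the combinatorial and
resource-limitation logic of multi-visitor fitness landscapes in its
simplest reproducible form.
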