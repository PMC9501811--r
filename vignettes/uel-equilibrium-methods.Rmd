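---
title: "Predicting upper elevational range limits from global climatic niches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting upper elevational range limits from global climatic niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(uelshift)
library(dplyr)
```

## The question

Species colonizing mountain roadsides often stop well short of the highest
elevations their physiology should tolerate. `uelshift` asks, for each
species, whether its *observed* upper elevational limit (UEL) — the highest
survey plot in which it was recorded — is in **climatic equilibrium** with
the limit implied by its *global* climatic niche. Operationally, a species
is at equilibrium when its observed UEL falls inside the 95% confidence
interval of a climatically predicted UEL; when the observed limit sits
below that interval there is unfilled, climatically suitable habitat above
it.

## The prediction pipeline

The predicted limit is built in four steps.

**1. Environmental space.** A principal component analysis of the (centred
and scaled) climate variables of a large global background sample defines a
two-axis environmental plane. Axis signs are fixed so the
largest-magnitude loading on each axis is positive, making scores
platform-reproducible. Occurrence records — filtered to coordinate
uncertainty strictly below 1 km — and the regional survey points are
projected into this plane with the background's centring and scaling
(`env_pca()`, `project_env()`).

**2. Gridded niche.** The plane is divided into an `R x R` lattice
(default `R = 100`) spanning the background score range padded by one
bandwidth. A Gaussian product-kernel density of the occurrence scores,
with Scott's rule bandwidth per axis (`sd * n^(-1/6)`), is evaluated at
the cell centres and normalized to unit mass (`build_env_grid()`). The
species' global niche is the smallest set of densest cells holding 99% of
that mass; ties at the cut are included (`delineate_niche()`). We read
"leaving out the most extreme 1% of the niche surface" as a *density-mass*
quantile, the standard contouring convention, rather than 1% of occupied
area; the level is a parameter (`level`), so either reading can be
explored. Occurrence density is deliberately *not* divided by background
availability for delineation (the niche is intersected with the regional
space explicitly in step 3); an availability-corrected variant sits behind
`correction = TRUE`.

**3. Suitability classification.** Every regional point inherits the
label of its enclosing grid cell: zone A (suitable) inside the niche mask,
zone B (unsuitable) outside. Points beyond the background's score range
are unsuitable by definition — the global background spans the realizable
climates. Attaching elevations (natively for synthetic regions,
nearest-cell DEM lookup otherwise) and sorting yields a presence/absence
series along elevation: A maps to 1, B to 0 (`classify_points()`,
`attach_elevation()`, `make_pa_series()`).

**4. Response curves and the outer border.** The seven
Huisman–Olff–Fresco (HOF) response shapes are fitted to the series by
maximum Bernoulli likelihood on the `[0, 1]`-rescaled gradient
(`fit_hof()`), and the best shape is chosen by AIC with ties going to the
simpler model (`select_hof()`). The predicted UEL of one fit is its
**outer border**: the highest elevation at which the fitted probability
still reaches `exp(-2)` of its maximum, located by a dense (1 m) lattice
scan refined by bisection to 0.01 m (fine enough that the response at the
reported border stays within `1e-3` of the threshold even for steep
fits), and censored at the gradient top when
the response never falls below the threshold (`outer_border()`).

Uncertainty comes from stratified subsampling (`resample_ob()`): each of
100 replicates draws 25% of the 1's and 25% of the 0's *separately*,
without replacement (the stratification protects species with few suitable
points), refits the whole model family, and records the outer border;
censored replicates contribute the gradient top and are counted. The
predicted UEL is the mean outer border, with a 2.5–97.5 percentile
interval (a normal-approximation interval is reported alongside, the two
being near-identical in practice). `classify_equilibrium()` then compares
the observed limit with the interval.

## Numerical choices in the HOF fit

* **Likelihood.** Bernoulli maximum likelihood with probabilities clipped
  to `[1e-9, 1 - 1e-9]`; the clip only matters for perfectly separable
  series.
* **Free parameters.** `k` = 1, 2, 3, 3, 4, 4, 5 for types I–VII, with
  the maximum response fixed at 1 for presence/absence data. The bimodal
  types share shape parameters between humps; the second hump is shifted
  by `f` (type VII adds a height ratio). Published parameterizations of
  VI–VII vary; ours is isolated in one function and documented.
* **Bounds.** Slopes `b`, `d` lie in `(0, 1000]`. The sigmoid evaluation
  is overflow-safe at any slope, so the cap is not a stability constraint;
  it merely needs to exceed the steepest transition the data spacing can
  resolve. Intercept-type parameters that set a transition *location*
  (`a`, and `c` on the descending side) must range over
  `+/- 1.1 x` the slope cap, because the inflection sits at `-a/b`: a
  tighter intercept bound silently pins steep transitions to the gradient
  edge, which in early development made the stacked-hump type VI
  masquerade as a super-steep monotone curve and win AIC on step-like
  data. Pure *level* parameters (`a` in type I, `c` in type III) keep the
  range `[-25, 25]`, which already spans probabilities within `1e-10` of
  0 and 1.
* **Optimization.** Ten Latin-hypercube starts per type; slopes sampled
  log-uniformly over `[0.5, 1000]`, locations uniformly over the padded
  gradient, intercepts derived from them. Each start runs a short
  Nelder-Mead screen inside the box (via a sigmoid reparameterization);
  the winner is polished to convergence. Model I has a closed-form fit.
  Everything is seed-deterministic.
* **Degenerate series.** All-presence or all-absence series yield a
  flagged type-I plateau (the outer border is then censored); series with
  fewer than `min_presences = 5` presences are "unfittable" and are
  skipped with a log entry rather than crashing a cohort run.

## What the synthetic generator emulates

The generator (`make_world()`, `make_region()`, `synthetic_species()`,
`sample_occurrences()`, `make_survey()`) reproduces the statistical
structure the analysis assumes, with an analytically known truth:

* **Background.** Points with synthetic coordinates; climate vectors are
  a loading matrix times a few latent gradients plus independent noise,
  giving the strong collinearity of real bioclim sets (three latents
  explain >95% of variance at the default noise). The first latent is a
  temperature in °C tied to latitude; latitudes are drawn symmetrically
  and temperature falls linearly with `|lat|`, so the availability density
  of temperature is *flat* across its span. This matters: if regional
  mountain climates sit in an availability rarity tail, the occurrence
  density truncates the niche's cold bound and the pipeline inherits a
  generator artifact rather than a property of the method.
* **Region.** A transect over 1900–3600 m (the study-system road span)
  whose temperature falls at 6.1 °C/km, the region's mean adiabatic lapse
  rate. The map is noiseless by default; `microclimate_sd` adds per-point
  temperature jitter emulating sub-kilometre topographic variation, which
  is what makes the regional suitability series interleave near the
  boundary instead of being a perfectly separable step.
* **Species.** An axis-aligned Gaussian niche in latent space. Its 99%
  quantile ellipsoid intersected with the (noiseless) elevation–climate
  line gives a closed-form true UEL (`true_uel()`), mirroring the 99%
  delineation downstream so recovery tests are interpretable. A
  `dispersal_deficit` places the realized limit below the climatic one.
* **Occurrences.** Background points accepted with probability equal to
  Gaussian suitability, so occurrence density is suitability times
  availability, as in real archives; a lognormal coordinate uncertainty
  (median 300 m, log-sd 1) makes the 1 km filter remove a seed-stable
  ~11%.
* **Surveys.** Plots every 100 m (50 m available), two epochs, per-plot
  detection probability, and random traits (residence time, dispersal
  mode, life span) that are independent of the dynamics unless the
  `trait_effect` knob is turned for power studies.

What it does **not** emulate: real geography and land masks, spatial
autocorrelation of sampling effort, non-Gaussian niche shapes, and biotic
or disturbance constraints on the realized limit. Passing recovery tests
therefore demonstrates internal consistency of the method under its own
assumptions, not field validity.

## The reference recovery study, and what its interval does not cover

`equilibrium_recovery_study()` is the package's calibration experiment:
100 independent worlds (default sizes: 10,000 background points, ~2,000
requested occurrences, 2,000 regional points, microclimate 0.3 °C, species
temperature tolerance sd 2 °C, true limit 2800 m), each run through the
full pipeline, with classifications at dispersal deficits of 0 and 500 m.

A species lagging 500 m below its climatic limit is reliably detected
(`below` in essentially every world). The interval itself, however, is
**anti-conservative**: the stratified 25% subsample only propagates
*regional subsampling* variance (interval half-width ~25 m under the
reference conditions), while three error sources it cannot see are of the
same order or larger:

1. *niche-estimation noise* — the 99% contour of a kernel density built
   from a finite occurrence sample wobbles by tens of metres of
   elevation-equivalent between worlds;
2. *grid quantization* — at `R = 100` one environmental cell corresponds
   to roughly ±35 m of elevation at the study lapse rate;
3. *systematic offsets* — kernel smoothing inflates the niche outward;
   the `exp(-2)` convention sits in the outer tail of any label noise
   (about `+1.1 x` the microclimate-equivalent elevation width); and a
   two-axis summary understates a higher-dimensional niche's extremes.
   Under the defaults these partially cancel (the mean prediction bias is
   a few tens of metres on a 1700 m gradient), but their variance does
   not.

Consequently the 95% interval covers the analytic true limit in only a
minority of worlds, and a species at exact equilibrium is frequently
classified as `below` or `above`. This undercoverage is a property of the
resampling design itself — resampling the regional series cannot express
uncertainty in the niche that generated it — and it is consistent with
the broader observation that predicted limits carry more uncertainty than
their formal intervals admit. Users comparing observed limits against
these intervals should treat `equilibrium` as a strong claim and `below`
/ `above` calls near the interval edge as fragile; the study function
reports the full per-world table so the bias and coverage can be
inspected directly.

## The comparative statistics

* `wilcoxon_uel()` — temporal comparison of observed limits between
  epochs. Exact null enumeration up to `n = 10` (all rank assignments,
  or all sign patterns for the paired variant), midranks for ties, and a
  continuity- and tie-corrected normal approximation beyond. The default
  is the *unpaired* rank-sum statistic: with species matched across
  years a signed-rank test would be the textbook choice, but the
  rank-sum statistic is the one whose scale matches the reported
  temporal W in this literature; the paired variant is one flag away and
  both are tested against enumeration.
* `classify_change()` / `change_summary()` — per-species change classes
  with a stability threshold defaulting to 0 m (any movement counts);
  the survey's 100 m plot quantization can be absorbed by setting the
  threshold accordingly.
* `regress_obs_pred()` — OLS of observed on predicted limits with both
  the correlation test and the slope-versus-1 test
  (`t = (1 - b) / se(b)`, `df = n - 2`); a slope below 1 means species
  with high predicted limits fall proportionally further short of them.
* `trait_model()` — sequential (Type-I) ANOVA of a response on residence
  time, dispersal mode and life span, in that fixed order (Df 1/2/2),
  with listwise deletion and single-level factors dropped; Type-II sums
  of squares are available by flag.
* `standardized_delta()` — `|UELo - UELp| / UELp`. The source formula is
  printed without its division bar; the ratio reading is the only one
  that matches "standardized difference".

## Problem sizes and determinism

Unit tests run on worlds of a few thousand points; the reference study
uses 100 worlds at the sizes above and completes in a few minutes on one
core, with the seven-model fit in compiled code and the kernel density as
a single matrix product per grid. Every stochastic step takes an explicit
seed, generators are pure functions of (config, seed), and a pipeline
rerun with the same configuration is byte-identical.

## A worked miniature

```{r mini, message = FALSE, warning = FALSE}
wc <- world_config(n_background = 4000, latent_dim = 2, seed = 7)
world <- make_world(wc)
rc <- region_config(n_points = 1200, microclimate_sd = 0.3, seed = 8)
region <- make_region(rc, wc)
sp <- synthetic_species("demo", niche_center = c(13, 0),
                        niche_sd = c(2.5, 1.5))
true_uel(sp, rc)

occ <- sample_occurrences(sp, world, 450, seed = 9)
pca <- env_pca(world)
grid <- build_env_grid(project_env(pca, world), project_env(pca, occ))
niche <- delineate_niche(grid)
pa <- make_pa_series(attach_elevation(
  classify_points(niche, grid, project_env(pca, region))))

fit <- select_hof(pa, seed = 1)
glance(fit)
pred <- resample_ob(pa, n_reps = 50, seed = 2, species = "demo")
pred
classify_equilibrium(true_uel(sp, rc)$uel, pred)
```

```{r mini-plots, message = FALSE, warning = FALSE}
autoplot(grid, niche = niche)
autoplot(fit, pa_series = pa)
autoplot(pred)
```
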