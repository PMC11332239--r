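---
title: "Quantifying plumage colour and modelling visual attractiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plumage colour and modelling visual attractiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumagescore)
```

## The scientific problem

People find some bird species more beautiful than others. Crowd-sourced
rating campaigns can attach an attractiveness score to (nearly) every
species, and the analytic question is then: which measurable traits of a
bird — its colours, the elaboration of those colours, ornaments such as
crests and long tails, its size, and non-visual attributes such as range
size — predict that score?

`plumagescore` implements the full chain of that analysis as a reusable,
tested pipeline:

1. **Colour quantification** (`rgb_to_lab()`, `build_histogram()`,
   `categorize()`, `split_light_dark()`, `colour_diversity()`,
   `colour_elaboration()`, `color_profile()`): plumage illustrations are
   converted to CIELAB and binned on a 3-D grid; occupied cells are the
   species' *colour loci*.
2. **Rating consensus** (`fit_consensus()`, `transform_response()`): raw
   1–10 crowd ratings are reduced to one consensus score per species × sex
   unit, adjusted for photo quality and rater language.
3. **Trait preparation** (`prepare_traits()` and friends): allometric
   residuals for ornament sizes, categorical reclassifications, log
   transforms, z-scaling, and a collinearity screen.
4. **Beta GLMM** (`beta_glmm()`, `run_model_battery()`, `validate()`): the
   consensus score on (0,1) is regressed on the prepared traits with nested
   taxonomic random intercepts under a beta likelihood, fitted by Laplace
   approximation.
5. **Synthetic data** (`taxonomy_spec()`, `generate_plumage_image()`,
   `simulate_attractiveness()`, `simulate_ratings()`,
   `simulate_scenario()`): every stage has a generator with known ground
   truth, so the pipeline is testable end to end without any external data.

`run_pipeline()` orchestrates stages 1–4 from a single config (R list or
YAML) and writes CSV outputs plus a checksummed JSON manifest.

## Colour model

Illustrations are 8-bit sRGB rasters with a foreground mask. Foreground
pixels are converted sRGB → XYZ (D65) → CIELAB, the standard approximately
perceptually uniform space with lightness $L \in [0, 100]$ and chromatic
axes $a$ (green–red) and $b$ (blue–yellow).

The grid (`lab_grid()`) splits each chromatic axis into 12 bins and the
achromatic axis into 4, giving $12 \times 12 \times 4 = 576$ cells. Bins
are half-open $[lo, hi)$ with a closed top bin. The chromatic ranges are
not dictated by the grid definition itself; the package defaults to
$a, b \in [-110, 110]$, which covers the whole sRGB gamut. Pixels outside
the configured range clamp into the edge bins and are counted and
reported.

Cells are aggregated to ten named categories — blue, purple, red, yellow,
green, rufous, brown, grey, white, black — by rules on the cell centroid's
hue angle $\mathrm{atan2}(b, a)$, chroma $\sqrt{a^2 + b^2}$ and lightness:
near-achromatic cells split into black / grey / white by lightness; warm
hues split into red / rufous / brown by chroma; pale low-chroma yellows
fall to brown. The authors of the original category map did not publish a
cell-level table, so this rule-based map is a *versioned convention*: it is
materialised as an editable CSV (`write_category_map()`), every cell maps
to exactly one category, and any alternative map with full coverage can be
substituted. Seven categories (blue, brown, green, grey, purple, red,
rufous) additionally carry a light/dark tone: with four L bins the only
symmetric reading is bottom two bins = dark, top two = light. White, black
and yellow are defined by lightness itself, so a tone split is not
meaningful for them.

Two summary statistics are computed from the histogram, both on occupied
cell centroids weighted by pixel proportion (not raw pixels — the locus is
the analysis unit):

* **Colour diversity**: the number of occupied loci. An occupancy
  threshold (default 0) can suppress anti-aliasing speckle.
* **Colour elaboration**: the proportion-weighted mean Euclidean distance
  $\Delta E^*_{ab}$ between the species' loci and the global average
  colour of the panel (a brown-grey in realistic panels). It is zero iff
  all colour mass sits at the global mean, equals $d$ for a single colour
  at distance $d$, and is additive in the weights. Unweighted and
  raw-pixel variants exist for sensitivity analysis. Plain Euclidean
  $\Delta E^*_{ab}$ is used because the space is already approximately
  perceptually uniform.

## Consensus scores from crowd ratings

Ratings arrive as integers 1–10 per (rater, photo) pair; photos carry a
1–5 quality score and raters a language. The consensus model is a Gaussian
linear mixed model (ML, via `lme4`):

$$\mathrm{rating} \sim \mathrm{quality} + \mathrm{language} + \mathrm{sex}
  + (1\,|\,\mathrm{photo}) + (1\,|\,\mathrm{unit}) + (1\,|\,\mathrm{genus})
  + (1\,|\,\mathrm{family}) + (1\,|\,\mathrm{order})$$

The likelihood of the consensus model used for the original published
scores is not public; the Gaussian LMM here is a documented
approximation of its stated structure, adequate for recovering unit
rankings (rank correlation with simulated truth exceeds 0.95 at ~50
ratings per unit). One structural choice deserves emphasis: the unit-level
random intercept is the **species × sex** unit, not the species. Scores
are reported per species and sex, and a species-level intercept cannot
separate the sexes of a dichromatic species; the sex fixed effect alone
would force every species to show the same male–female gap.

Predictions are made at reference conditions — best photo quality (5) and
the majority language — plus the unit's (and its taxonomy's) BLUPs. The
resulting score lives on 0–9 (the 1–10 scale minus 1); dividing by 10
gives the beta-model response. Because the transform can produce exactly
0, boundary values are squeezed with $(y(n-1)+0.5)/n$. By default only
boundary values are squeezed, so interior scores stay exactly
$\mathrm{raw}/10$; an `"all"` mode applies the compression everywhere.

## Trait preparation

* **Ornament allometry**: relative beak and tail length are the residuals
  of OLS regressions of log length on log body mass across the panel.
  Log-log is the standard allometric form; a linear-scale option exists
  because the original specification of this regression does not state the
  scale.
* **Reclassifications** (exact, total mappings with errors on unknown
  labels): IUCN categories collapse to Threatened / Non-threatened /
  Unknown; trophic labels to carnivore (predators, scavengers,
  invertivores) / omnivore / herbivore; migration to migratory (partial or
  full) / non-migratory.
* **Transforms**: body mass and range size are log-transformed; latitude
  enters as |latitude|; all continuous predictors are z-scaled (sample-SD
  convention of `scale()`), and the scaling constants are stored so the
  transform inverts to 1e-10.
* **Collinearity screen**: all pairwise Pearson correlations are reported
  and pairs above |r| = 0.6 flagged. Nothing is dropped silently; the
  documented drop list defaults to colour diversity (`loci`), which
  correlates strongly with several colour proportions and is analysed in a
  separate model instead. Crest (scored 0–3) is treated as a continuous
  variable and z-scaled like the others.

## The beta GLMM

The response $y \in (0,1)$ is modelled as
$y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ — mean $\mu$, precision
$\phi$ — with

$$\mathrm{logit}(\mu) = X\beta + \sum_k Z_k u_k, \qquad
  u_k \sim N(0, \sigma_k^2 I)$$

for random intercepts over order, family, genus and species. The logit
link is the beta-regression default (the original analysis does not state
its link); precision is constant (no dispersion model); taxonomic factors
enter as independent random-intercept terms, with globally unique labels
making the nesting implicit. The main model's fixed effects are sex
(reference class: undefined sex), body mass, crest, relative beak and tail
length, colour elaboration, and the six focal colour proportions (black,
white, yellow, blue, red, green); the extended model adds trophic level,
IUCN status, range size, |latitude| and migration.
`run_model_battery()` additionally fits three sex-subset models (dropping
the sex term and the species random factor), dark- and light-colour
variants of red/blue/green, a colour-diversity (loci) model, and a
dull-colours model (brown, grey, rufous, purple). The loci and dull
models keep colour elaboration, since only the colour-proportion
variables are being replaced.

### Estimation

The marginal likelihood integrates over $u$; `beta_glmm()` maximises its
Laplace approximation
$$\ell(\beta, \sigma, \phi) \approx
  \log f(y, \hat u) - \tfrac12 \log \det A(\hat u), \qquad
  A = Z^\top W Z + D^{-1},$$
where $\hat u$ is the mode of the joint density and $W$ the (observed)
negative curvature of the beta log-likelihood in the linear predictor.
Numerical design choices:

* **Inner problem.** The mode is found by Newton ascent with
  observed-Hessian steps, floored against indefiniteness and safeguarded
  by step halving; observed information gives quadratic convergence where
  Fisher scoring is only linear. Convergence at gradient ∞-norm < 1e-8.
* **Sparse algebra.** $A$'s sparsity pattern is fixed, so it is analysed
  once (CHOLMOD) and every iteration only refills the numeric slots via a
  precomputed observation-to-slot map, then updates the factorisation.
* **Outer problem.** Quasi-Newton (`nlminb`) over
  $(\beta, \log\sigma, \log\phi)$, started from a fast profile stage that
  solves for $(\beta, u)$ jointly in the inner Newton iteration so the
  initial outer search runs over the 5 variance parameters only. The full
  Laplace objective is always the final estimator; the profile stage only
  supplies start values. Starts: logit-scale least squares for $\beta$,
  $\sigma^2 = 0.1$, method-of-moments $\phi$.
* **Convergence reporting.** `nlminb`'s occasional "false convergence" at
  a flat endpoint (typically a variance collapsing to its lower bound,
  1e-3) is accepted only if a projected KKT gradient check passes;
  otherwise the fit carries a warning and `converged = FALSE`.
* **Inference.** Wald 95% CIs from the observed information (numerical
  Hessian of the Laplace objective at the optimum). P-values are reported
  but the intended basis for interpretation is effect sizes and intervals.
* **Degenerate cases.** A formula without random terms drops to plain ML
  beta regression (verified against an independent ML fit to 1e-4). A
  response touching 0 or 1 is an error that points to the boundary
  squeeze. Rank-deficient fixed designs are an error.

`validate()` computes the probability integral transform of each
observation under its fitted conditional beta distribution (randomized
quantile residuals on the normal scale), a Kolmogorov–Smirnov uniformity
test, residual-vs-fitted quintile summaries, and optional per-group (e.g.
per-order) residual summaries.

## The synthetic world

The generators state one emulated world; their defaults are fixed and are
not tuned against test outcomes.

* **Taxonomy**: configurable counts per level; a `dichromatic_fraction`
  of species yields male and female records, the rest a single
  "undefined" record. Genus and species labels are globally unique.
* **Images**: each unit's foreground pixels are split across named colour
  keys by largest-remainder apportionment (realised counts within one
  pixel of the target mix) using representative colours located at cell
  centroids and verified to survive the Lab → 8-bit sRGB → Lab round trip
  inside their own cell. The exact expected histogram is stored with the
  image, so colour quantification has an exact oracle. Layouts are flat
  colour bands ("stripe") or an elliptical bird-ish blob on transparent
  background; real photographic variation (lighting, pose, texture) is
  deliberately out of scope, so a green colour-pipeline test establishes
  binning/aggregation correctness, not robustness to photography.
* **Ratings**: photo counts per unit are truncated-Poisson on 1..15 with
  mean 5 (the observed per-species photo counts of the emulated archive
  average ≈5 in the range 1–15); each photo has a quality score 1–5 and a
  Gaussian photo effect; raters carry language offsets. The emitted
  rating is an affine map of the truth plus these effects and noise,
  rounded and clipped to 1..10. How real raters map perception to the
  1–10 scale is unknown; this affine-plus-noise mechanism is a stand-in,
  which is why consensus recovery is asserted on rank correlation rather
  than calibration.
* **Attractiveness**: drawn from the same beta-GLMM structure the fitting
  module assumes, with default precision $\phi = 30$ and taxonomic SDs
  (0.3, 0.2, 0.2, 0.3) — moderate clustering, response SD ≈ 0.09 around a
  mid-scale mean, matching the granularity of crowd-rated scores. Default
  coefficients are signed like typical aesthetic preferences (positive
  for red, blue, elaboration, crest, tail; negative for black, white,
  mass).
* **Streams**: every generator draws from a sub-seed derived from the
  base seed and the stream name, so adding photos does not perturb the
  taxonomy and all outputs are byte-identical under a fixed seed.

## Worked example

```{r example, eval = FALSE}
library(plumagescore)

res <- run_pipeline(list(
  scenario = list(taxonomy = list(n_orders = 3, families_per_order = 2,
                                  genera_per_family = 2,
                                  species_per_genus = 4,
                                  dichromatic_fraction = 0.3)),
  output_dir = "pipeline_out", seed = 42, models = "main"))

res$fits$main          # fixed effects, random-intercept SDs, precision
validate(res$fits$main)  # quantile-residual diagnostics
res$summaries$order    # order-level score summaries
```

## Known limitations

* The consensus model is a Gaussian approximation of an unpublished
  model; ordinal likelihoods and rater demographics are out of scope.
* The category map is a rule-based stand-in for an unpublished cell
  table; analyses that hinge on fine category boundaries should treat the
  map as a tunable input (it is a plain CSV).
* Two of the original twelve colour categories are not recoverable from
  the published description; the map implements the ten named ones.
* Taxonomic random intercepts approximate phylogeny only coarsely;
  phylogenetic covariance matrices are out of scope.
* The Laplace approximation can bias variance components slightly
  downward at few levels per factor (e.g. 10 orders); fixed-effect
  recovery is verified by simulation, variance components are reported
  as-is.
* For the same reason, Wald intervals for baseline-level parameters —
  above all the intercept — can under-cover when a top grouping factor
  has few levels: the grand mean's sampling variance is dominated by a
  handful of order effects whose variance is itself estimated
  imprecisely. Standardised slope effects, the quantities of scientific
  interest here, are much less sensitive.
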