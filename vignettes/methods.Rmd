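---
title: "Methods: presence-only habitat modelling and river-length population estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only habitat modelling and river-length population estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverSDM)
```

## The estimation problem

riverSDM estimates the wintering population of a riverine waterbird from
three ingredients that are individually weak but jointly informative:
presence-only sighting records, environmental raster layers, and
line-transect counts on a handful of surveyed river sections. The chain
is:

1. derive bioclimatic predictors from monthly climate grids;
2. fit a presence-background maximum-entropy model and evaluate it by
   replicated train/test AUC;
3. threshold the averaged suitability map at the mean predicted
   probability of the presence sites;
4. intersect the suitable area with the river network, keeping only
   large rivers (high Strahler order), to obtain a suitable river
   length L in km;
5. extrapolate the surveyed densities: N = D x L.

Each stage is an exported function; `runPipeline()` composes them and
records every seed, threshold and intermediate quantity.

## The maximum-entropy model

Let B be a background sample of cells representing available
conditions, and f(x) a vector of features derived from the predictor
layers at cell x, each min-max scaled to [0, 1] on B. The model is the
Gibbs distribution over B

$$q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z(\lambda)},\qquad
Z(\lambda) = \sum_{x \in B}\exp(\lambda \cdot f(x)),$$

fitted by maximising the L1-penalised mean presence log-likelihood

$$\ell(\lambda) = \bar f \cdot \lambda - \log Z(\lambda)
  - \sum_j \beta_j |\lambda_j|,$$

where $\bar f$ is the empirical feature mean over the presence cells.
This is the standard presence-background maximum-entropy formulation:
among all distributions whose feature expectations match the presence
means to within the $\beta_j$, it is the one of maximum entropy. At the
optimum the KKT conditions give $|\bar f_j - E_q f_j| \le \beta_j$ for
every feature, with equality whenever $\lambda_j \neq 0$;
`maxentCertificate()` checks exactly this, and the test suite asserts
it on every fitted model.

**Features.** Continuous layers contribute linear, quadratic,
pairwise-product, hinge and threshold features; categorical layers
contribute one indicator per observed code. Hinge and threshold knots
sit at equally spaced background quantiles (50 per layer by default). A
forward hinge with knot k has value $\max(0, (x-k)/(x_{max}-k))$ capped
at 1, so hinge features are already in [0, 1] by construction.

**Penalties.** $\beta_j = \mu\, s_j\, c/\sqrt{m}$, with $s_j$ the
feature's background standard deviation, m the presence count, c = 0.5
for hinge features and 1 otherwise, and $\mu$ the user's
`betaMultiplier` (default 1). This follows the published default
philosophy — penalties shrink with presence sample size and scale with
feature variability — without reproducing any version-specific lookup
table.

**Optimiser.** Cyclic coordinate descent with soft-thresholding. For
feature j the Newton proposal $z = \lambda_j + g_j/h_j$ (gradient
$g_j = \bar f_j - E_q f_j$, curvature $h_j = \mathrm{Var}_q f_j$) is
soft-thresholded at $\beta_j/h_j$; steps are capped at 4 and the cap is
halved whenever a full pass fails to improve the penalised objective,
which guarantees monotone progress. Convergence is declared when a pass
improves the objective by less than `tol` (1e-5 by default, 500 pass
limit). On small instances the attained optimum is verified in the
tests against dense lattice search over $\lambda$.

**Outputs.** The raw output is q renormalised over the prediction
region. The logistic output is
$p = q e^H/(1 + q e^H)$ with H the entropy of the fitted q and
prevalence parameter $\tau = 0.5$; it is a monotone transform of q
(rank-identical maps) interpretable as a relative occurrence
probability. The uniform model has $q = 1/|B|$, $H = \log |B|$ and
p = 0.5 everywhere, which is the fixed point reached when presences
carry no signal.

## Evaluation

Replicate runs split the presences 75%/25% (background shared), fit on
the training split, and score training and test AUC with the rank-based
(Mann-Whitney) estimator, ties counting one half. The suitability maps
of the replicates are averaged cell-wise and that averaged map drives
all downstream steps. Variable importance is reported two ways:
jackknife AUC (each variable alone / withheld, one fixed split) and
permutation importance (shuffle one layer's raw values across the
combined presence-plus-background evaluation points, re-extract
features, record the AUC drop, floor at zero, renormalise to 100%).
Permuting the raw layer rather than single features makes the score a
property of the variable, not of one basis function. Variables under
1% permutation importance are pruned and the model refitted.

## Thresholding, overlay and extrapolation

The binary habitat map uses the mean predicted probability at the
presence sites as threshold, inclusive (p >= t is suitable), so the
threshold-defining average site is itself suitable. The presence-site
reading of "average predicted probability" is the standard one in the
thresholding literature; the map-wide mean is available via
`rule = "map"`. Suitable regions are traced as polygon rings on cell
edges (4-connected, so diagonally touching corridors stay separate;
outer rings counter-clockwise, holes clockwise, even-odd containment),
and the round trip polygonise-then-rasterise reproduces the mask
exactly because cell centres never lie on cell edges.

Rivers of Strahler order 5 and below are excluded by default (the
species avoids small rivers). Polylines are clipped against the ring
set by planar segment-edge intersection in lon/lat; clipped pieces are
measured with haversine lengths on a sphere of radius 6371.0088 km.
Planar clipping followed by spherical measurement is accurate to well
below the raster resolution at mid-latitudes and mirrors how a desktop
GIS overlay does it. Pieces lying exactly on a polygon edge count as
inside, consistent with the inclusive threshold.

The population estimate defaults to the unweighted mean of per-section
densities, N = mean(D) x L, with spread SD(D) x L; the length-weighted
pooled estimator (total count over total surveyed length, with a
pooled Poisson standard error) is always co-reported. The two coincide
when all sections have equal length. Densities are presented rounded
half-up to 2 decimals; all propagation uses unrounded values. The
spread is labelled with its definition because section-to-section
density variation is only one source of uncertainty (it ignores the
error in L).

## The synthetic landscape and what it does (not) show

`syntheticLandscape()` generates a complete input set with known truth
on a 100 x 100 grid of 0.01-degree cells (roughly a 110 km square):

- **Climate.** Monthly tmin/tmax/precipitation as a latitudinal
  gradient (8 degrees C per degree latitude) plus a shared smooth
  Gaussian random field (SD 2 degrees C, correlation range 8 cells)
  plus a seasonal sinusoid (half-amplitude 12 degrees C, January
  coldest); precipitation additionally carries an east-wetter gradient
  (60 mm per degree longitude) emulating continentality, and a dry
  winter (half-amplitude 50 mm). These magnitudes are of the order of
  a subtropical river basin in winter.
- **Rivers.** Steepest-descent walks from 150 random high-ground
  sources on an east-sloping synthetic elevation field, so trunk
  rivers run broadly west to east — along, not across, the climatic
  gradient, as large rivers in the study system do. Strahler orders
  follow from the junction topology. On a 110 km square the network
  rarely exceeds order 3-4, so synthetic runs use an order cutoff of 2
  in place of the real-data cutoff of 6; the cutoff is a parameter,
  not a constant.
- **Niche.** True suitability is
  $s(x) = \mathrm{logistic}(a_0 - \sum_i ((x_i - o_i)/w_i)^2)$ on
  annual mean temperature (bio_1) and coldest-quarter mean temperature
  (bio_11), with optima at the 75th background percentile, widths
  1/52 of the layer range and $a_0 = 6$. These defaults were fixed by
  calibrating the *generator* so that the best achievable
  (Bayes-optimal) presence-background AUC of the true field is about
  0.95 — the regime the method is reported to operate in on real
  winter waterbird data — while the suitable area (about 5-10% of the
  landscape) still intersects the trunk-river network on every seed.
  A niche much broader makes high AUC impossible for any model (the
  ceiling is set by the overlap between presence and background score
  distributions, not by model quality); much sharper, and the habitat
  degenerates to slivers that miss the rivers.
- **Occurrences and survey.** Records are drawn with probability
  proportional to s (optionally times a bias field, off by default so
  estimator checks are unconfounded), jittered within cells. Survey
  sections are the longest in-habitat river pieces and their counts
  are Poisson with mean 0.5 birds/km x length, the density magnitude
  of the real surveys.

The truth analogue of the pipeline estimand is defined by applying the
pipeline's own thresholding rule to the true field: t_true is the mean
true suitability at the occurrence cells, L_true the order-filtered
river length inside {s >= t_true}, and N_true = 0.5 x L_true. This
makes the recovery experiment a test of estimation error, not of a
definitional mismatch.

Passing recovery tests show the chain is consistent when the model
family contains the truth, sampling is unbiased, and detection is
perfect. They do not show robustness to spatial sampling bias,
imperfect detection, non-equilibrium distributions, or predictor
collinearity patterns of real remote-sensing stacks — all of which
affect real applications.

## Numerical choices and degenerate inputs

- Quarters are the 12 circular 3-month windows; ties among windows
  break to the earliest start month. BIO4 uses the population standard
  deviation (x100); BIO3 is undefined (NA) where the annual
  temperature range is zero.
- Bilinear resampling clamps at the source border; categorical
  resampling takes the majority of contributing source cells, ties to
  the lowest code, nearest neighbour when upsampling.
- Constant layers are dropped from the feature expansion with a
  warning; a fit with no usable features is an error, as are fewer
  than two presence cells.
- Feature values outside the training range are clamped to [0, 1]
  after scaling at prediction time.
- Cell lookup snaps near-integer cell offsets (within 1e-9 of an edge)
  to the half-open convention [west, east) x (south, north], so
  boundary coordinates are assigned deterministically despite floating
  point.
- Problem sizes in the tests (100 x 100 grids, 2,000 background cells,
  200 presences, 5 replicates, 8 hinge knots) are chosen so the whole
  recovery experiment runs in seconds per seed; they are smaller than
  the package defaults (10,000 background, 50 knots, 30 replicates),
  which match the real-data design.

## Known limitations

- The spread of the population estimate reflects only density
  variation between sections; the uncertainty in L (model and
  threshold error) is not propagated. The recovery experiment shows
  the 2-spread interval still covers the truth in >= 90% of seeds
  under the generator's conditions, but that is an empirical property
  of those conditions.
- Permutation importance is an AUC-drop stand-in for the original
  software's internal definition, which is not published in print.
- The overlay treats "suitable river" as polygon containment of
  clipped pieces; cell-wise tagging of river cells would differ
  slightly at region boundaries.
- Everything stays in geographic WGS84 coordinates; there is no
  reprojection support, matching the source datasets of the intended
  application.
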