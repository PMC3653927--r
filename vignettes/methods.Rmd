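---
title: "Models and methods: willow thicket configuration and tundra bird communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thicketbirds` packages the statistical pipeline for asking how the areal
extent and spatial configuration of riparian willow thickets shape an arctic
bird community surveyed by repeated point counts. This vignette is the
package's own account of the models, the choices behind them, and what the
test suite does and does not establish.

## The data and the design

The design the package assumes (and its generator emulates) is a repeated
point-count survey: 37 sampling points in three river-valley regions
(12 + 13 + 12), each visited 3 times per year in each of 4 breeding seasons.
Counts per species × point × year × visit are reduced to binary
detection/nondetection histories for occupancy modelling
(`counts_to_detection()`), while the raw counts feed the abundance models.
Seventeen species, classified a priori into three assemblages — willow
canopy-breeders (WCB, 4 species), willow ground-breeders (WGB, 5) and
open-tundra species (OT, 8) — form the observed community; the bundled
habitat-use table carries the classification. Gulls and shoreline species
are assumed already removed from the table; an `excluded` flag column is
honoured if present.

Four point-level covariates enter all models: willow **area** (% of a 4 ha
quadrat), **edge density** (metres of willow/non-willow interface in the
quadrat), **willow height** (cm, mean of 4 field measures) and **willow
density** (point-frequency hits, mean of 4). Patch density is computed but
dropped before modelling when its correlation with edge density exceeds 0.7
(`drop_collinear()`), as the two fragmentation measures are strongly
collinear in this system and edge density better captures the browsing
"shredding" effect. All covariates are standardized to mean 0, SD 1
(**sample** SD, n − 1 denominator — the conventional choice, and the one that
makes slopes read "per SD"), pooled over regions, with centres and scales
retained for back-transforming predictions. The landscape was measured once
(2006 aerial photography), so covariates are constant across years even
though occupancy is indexed by year; the design matrix simply repeats point
values.

Two behaviours the source design leaves open are settable, not asserted:
"flying over" detections are retained by default (the habitat-use table
includes them in its totals), and region enters no model term by default
(covariate ranges overlap strongly between regions); both can be switched
for sensitivity runs.

## Landscape metrics

Willow cover arrives as a binary raster at 0.2 m resolution. Within a
200 × 200 m quadrat centred on the sampling point (snapped to the nearest
pixel centre; snap distance ≤ half a pixel is recorded):

* **area_pct** — 100 × willow pixels / total pixels;
* **patch_density** — connected components under the 8-neighbour rule, with
  components whose minimum pixel-centre separation is ≤ 2 m merged: the
  "distinct patches are > 2 m apart" rule is implemented as exact pairwise
  distance on pixel centres (transitively, via union–find), not as a
  dilation approximation;
* **edge_density** — 0.2 m × the number of 4-adjacent pixel pairs with
  differing values **inside** the quadrat. The quadrat border contributes no
  edge: edge is a habitat-interface quantity, and a clipped window border is
  an artefact of measurement, not an interface (a flag enables border
  counting). Whether the original analysis normalized edge to m/ha is not
  recoverable; since covariates are standardized, any linear rescaling is
  irrelevant to the models, and raw metres are reported.

Both the labeling (with merging) and the edge count are verified against
independent brute-force oracles — flood fill plus exhaustive pairwise pixel
distances, and exhaustive boundary enumeration — on batches of random masks.

## The community occupancy model

For species $i$, point $l$, year $j$, visit $k$:

$$z_{ilj} \mid w_i \sim \mathrm{Bern}(w_i\,\psi_{il}), \qquad
  \mathrm{logit}(\psi_{il}) = u_i + \textstyle\sum_c \beta_{ic} x_{lc}$$
$$x_{iljk} \mid z_{ilj} \sim \mathrm{Bern}(z_{ilj}\, p_{il}), \qquad
  \mathrm{logit}(p_{il}) = v_i + \textstyle\sum_c \beta^p_{ic} x_{lc}$$

Detection uses the *same* four willow covariates as occupancy and no
visit-level terms — implemented as the equations are written. Occupancy is
redrawn each year (no year trend term); visits are exchangeable given $p$.
Species parameters are draws from community distributions:
$(u_i, v_i)$ bivariate normal with correlation $\rho_{uv}$ (abundant,
easily-detected species tend to be widespread — the model lets occupancy and
detection intercepts covary), and each slope
$\beta_{ic} \sim N(\mu_{\beta c}, \sigma_{\beta c})$ independently per
covariate. Data augmentation adds $M - n$ all-zero pseudo-species (default
32 on top of the 17 observed) with inclusion indicators
$w_i \sim \mathrm{Bern}(\Omega)$, so the posterior of
$N_\mathrm{tot} = \sum_i w_i$ estimates total community size including
never-detected species.

**Priors.** The source analysis defers to its cited model family without
restating constants, so the constants here are documented as this package's
choice, not asserted as the original's: $\Omega \sim U(0,1)$; community
means $\sim N(0, 10^2)$; community SDs $\sim U(0, 10)$;
$\rho_{uv} \sim U(-1, 1)$.

**Sampler.** A purpose-built Metropolis-within-Gibbs sampler (C++ core)
replaces the original general-purpose Gibbs software, so every update is
explicit and testable:

* $w_i$ for never-detected species: exact Bernoulli full conditional with
  the latent $z$ *marginalized out* (avoids the sticky joint update);
* $z_{ilj}$: exact Bernoulli full conditional; forced to 1 at observed
  detections;
* $\Omega$: conjugate Beta; community means: conjugate normal
  (conditionally, through the bivariate-normal residual decomposition for
  $\mu_u, \mu_v$);
* species intercepts/slopes and the community SDs and $\rho_{uv}$: Gaussian
  random-walk Metropolis, with Robbins–Monro adaptation towards 0.44
  acceptance during burn-in **only** (so retained draws come from a fixed
  kernel);
* species with $w_i = 0$ and no detections have no likelihood term and are
  refreshed by exact draws from the community distribution.

Default chain settings mirror the original analysis: 2 chains × 30 000
iterations, 3 000 burn-in, thin 10 → exactly 2 700 retained draws per chain.
Initialization: $z$ at the observed detections, $w = 1$ for observed species
and Bernoulli(0.5) for augmented ones. The stated design decision "parameters
from priors" is implemented as: initial *hyperparameters* from moderate
distributions, species parameters from the community distribution given
them. Literal draws from the $N(0,10^2)$/$U(0,10)$ hyperpriors would
routinely start chains at $|logit| > 20$, where the likelihood is flat and
burn-in is wasted; starting from the hierarchical prior conditioned on
sensible hypers is still an overdispersed random start (per-chain seeds
derive from the master seed) without the pathology. Convergence is
monitored by the classic Gelman–Rubin $\hat R$ (between/within-chain
variance, non-split), attached per hyperparameter.

**Derived quantities.** Richness at point $l$ is
$R_l = \sum_i w_i \psi_{il}$ per draw, summarized by posterior median and
95% credible interval per point-year (psi is year-constant because
covariates are; the sum runs over the whole superpopulation or any species
group, e.g. an assemblage). The richness surface over (area, edge density)
holds the other covariates at their means (0 standardized) — the
conditional-effect surface — and flags extrapolation beyond the observed
covariate range with a warning rather than an error.

**Calibration, honestly stated.** Simulation at the design size (37 × 4 × 3,
17 species, community-mean area slope 1.0, reduced chains 2 × 3000) gives
95% credible intervals covering the true community-mean area slope in 18/20
replicates. Under the same stated world the posterior *median* sits about
+0.15 logit above the truth on average: with per-visit detection around 30%
and detection itself increasing with area, the community-mean slope is
weakly identified and its posterior right-skewed. In a high-detection probe
(mean detection logit 2, no detection slopes) the bias is −0.05 ± 0.05,
i.e. the sampler itself is calibrated; the skew is a property of the
posterior at this design size, worth remembering when reading real-data
medians. The unbiasedness property test therefore runs in the informative
regime.

## The N-mixture abundance model

Per species, sample units are point-years ("stacked", one fit per species —
the reading consistent with "years as a detection covariate"):
$N_s \sim \mathrm{Pois}(\lambda_s)$ with
$\log \lambda_s = \alpha + \sum_c \beta_c x_{sc}$, and visit counts
$y_{sk} \sim \mathrm{Bin}(N_s, p_{\mathrm{year}(s)})$. The marginal
likelihood sums the binomial over $N$ up to a truncation bound $K$ (log-space
throughout). $K$ starts at max(count) + 100 and doubles until the maximized
log-likelihood moves < 1e−6 — the bound is a numerical device, never a model
assumption. Maximization is BFGS from documented starting values (intercept
log(mean of unit maxima + 0.1), slopes 0, detection logits 0); standard
errors come from the inverse numerical Hessian. Fits on the classic
non-identifiable ridge ($\hat p \to 0$, $\hat\lambda \to \infty$, or an
all-zero species, or a non-positive-definite Hessian) are *flagged*, refused
by `predict_abundance()`, and dropped from pooling with a message — never
silently returned.

## Meta-analytic pooling

Species-level slopes (estimate, SE) are pooled per assemblage group
(willow-dependent WCB + WGB together, OT separately — the layout of the
published response table). Fixed effects: weights $1/\mathrm{se}^2$, pooled
SE $(\sum w)^{-1/2}$. Random effects: DerSimonian–Laird
$\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w)\big)$,
then inverse-variance with $1/(\mathrm{se}^2 + \tau^2)$. The heterogeneity
estimator is labeled DL because the original does not name one. Intervals
are normal (±1.96 se), matching the defaults of the function family the
original used and the log/logit scales involved; "significant" means the
95% CI excludes 0.

## What the generator emulates — and what it does not

The synthetic world reproduces the *stated* features of the study:
design sizes; the covariate correlation skeleton (patch–edge r ≈ 0.8 as the
one strong pair, everything else < 0.43; magnitudes of each variable chosen
once as field-plausible: cover ~5–50%, edge ~1–3 km per 4 ha at 0.2 m
pixels, heights ~30–150 cm); assemblage-structured effects (occupancy-scale
area slope 0.99 for willow-dependent assemblages, abundance-scale 0.27 and
height 0.16; OT means 0 with nonzero between-species spread so individual OT
species can respond while the assemblage mean is null); intercept spreads
placed so occupancy spans ~7–95%, detection ~12–71%, with
occupancy–detection correlation 0.75. Landscapes are random overlapping
elliptical clumps with per-point cover targets spanning 5–50%. Sub-seeds for
each artifact derive from the master seed by a fixed scheme
(`sub_seed()`), so artifacts regenerate independently and bit-exactly.

It does **not** emulate: observer behaviour (time of day, song rates —
detection is constant per species × point), spatial autocorrelation between
points, year trends in occupancy, or the true joint distribution of willow
height/density with area (only the printed correlation constraint is
matched). A green recovery test therefore establishes that the estimators
work *when the model's assumptions hold at the study's design size* — not
that the published numbers are reproducible; the raw survey data were never
deposited, and the published posterior summaries serve here as generator
defaults, not as targets.

## Numerical notes

* Logit probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the
  sampler; likelihoods use `log1p` where it matters.
* Patch labels are deterministic (row-major order of each patch's first
  pixel); ties in quadrat snapping resolve to the nearest pixel centre and
  the snap distance is recorded.
* `marginal_detection_loglik()` and the N-mixture likelihood are each
  checked against independent enumeration oracles to 1e−12 / 1e−10; the
  all-zero N-mixture history has a closed form
  $\exp(\lambda((1-p)^K - 1))$ used as a third, analytic check.
* Degenerate inputs error loudly and specifically: zero-variance columns in
  standardization, non-positive-definite target correlations before
  sampling, counts below zero, non-standardized covariates passed to the
  sampler, missing augmentation.

## Known limitations

* The occupancy sampler is single-threaded; the full 2 × 30 000 default run
  takes a couple of minutes at the study's size.
* Richness summaries are derived from year-constant covariates; with
  time-varying covariates the psi computation would need a year index.
* No negative-binomial or zero-inflated N-mixture variants, no multispecies
  N-mixture, no spatial model terms, and no model-selection machinery — all
  outside this pipeline's scope.
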