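# thicketbirds

Hierarchical community models for riparian tundra bird surveys: how does the
areal extent and spatial configuration of willow (*Salix* spp.) thickets shape
bird occupancy, abundance and species richness?

Arctic riparian plains hold mosaics of tall willow thickets embedded in
meadows and heaths. Thickets are labile — climate warming expands them while
heavy reindeer browsing shreds them into smaller, edgier fragments — and a
large share of the tundra bird community depends on them. `thicketbirds`
implements, as a tested and reusable pipeline, the statistical machinery
needed to quantify these effects from repeated point-count surveys with
imperfect detection:

* **Landscape metrics** from binary willow rasters (0.2 m pixels): percent
  willow cover, patch density (8-neighbour connected components, patches
  ≤ 2 m apart merged) and edge density within a 200 × 200 m (4 ha) quadrat
  centred on each sampling point.
* **A data-augmented multispecies multiyear occupancy model**. For species
  *i*, point *l*, year *j*:

  ```
  z_ilj | w_i      ~ Bernoulli(w_i · psi_il),   logit(psi_il) = u_i + Σ_c β_ic x_lc
  x_iljk | z_ilj   ~ Bernoulli(z_ilj · p_il),   logit(p_il)   = v_i + Σ_c βp_ic x_lc
  (u_i, v_i)       ~ BVN((μ_u, μ_v), Σ),        β_ic ~ N(μ_βc, σ_βc)
  w_i              ~ Bernoulli(Ω)
  ```

  with covariates x = (willow area, edge density, willow height, willow
  density), standardized. Adding M − n all-zero pseudo-species (default 32)
  with inclusion indicators `w` makes total community size `N_tot = Σ w_i`
  estimable. Fitting is by an explicit Metropolis-within-Gibbs sampler
  (C++ core), convergence checked by the Gelman–Rubin Rhat. Richness at a
  point is the posterior of `Σ_i w_i · psi_il`.
* **Single-species N-mixture models** for relative abundance from the raw
  counts: latent `N_s ~ Poisson(λ_s)` with `log λ_s` linear in the willow
  covariates, visit counts `y_sk ~ Binomial(N_s, p_year)`; maximum-likelihood
  fit of the marginal likelihood (sum over N up to a stability-checked
  truncation bound K).
* **Meta-analytic pooling** of species-level slopes into assemblage-level
  estimates: fixed-effects inverse-variance weighting, with a
  DerSimonian–Laird random-effects robustness variant. Assemblages follow the
  a-priori classification: willow canopy-breeders (WCB), willow
  ground-breeders (WGB) and open-tundra species (OT).
* **A synthetic-data generator** reproducing the study design — 3 regions,
  37 points (12 KO, 13 VJ, 12 IF), 4 years, 3 visits/year, 17 species
  (4 WCB / 5 WGB / 8 OT) — including raster landscapes, a covariate field
  with the observed correlation structure (patch vs edge density r ≈ 0.8,
  all other pairs < 0.43) and assemblage-structured effect sizes, so every
  stage of the pipeline is testable without any field data.

The species habitat-use table (17 species × 5 habitat categories) ships in
`inst/extdata/species_table1.csv`.

## Worked example

```r
library(thicketbirds)

tab  <- read_species_table(system.file("extdata", "species_table1.csv",
                                       package = "thicketbirds"))
attr(assemblage_partition(tab), "sizes")
#> WCB WGB  OT
#>   4   5   8

## synthetic survey in the study's design
config <- sim_config(seed = 42)
covs   <- standardize_covariates(simulate_covariates(config))
print(thicket_metrics(simulate_landscape(config, 5)))
#>   area_pct patch_density edge_density
#> 1  10.2144            21       1541.6

## community occupancy model (reduced chains for the example)
x     <- simulate_community(config, covs)
draws <- run_mcmc(x, covs, community_spec(chains = 2, iterations = 3000,
                                          burn_in = 500, thin = 5, seed = 42))
posterior_summary(draws, c("mu_u", "mu_beta_area", "Omega", "Ntot"))
#>      parameter median   q2.5  q97.5  Rhat
#> 1         mu_u  0.546 -0.264  1.229 1.078
#> 2 mu_beta_area  0.326 -0.129  0.779 1.002
#> 3        Omega  0.336  0.213  0.458 0.999
#> 4         Ntot 16.000 16.000 17.000 0.999

rich <- derive_richness(draws, covs)
attr(rich, "Ntot")
#> median   q2.5  q97.5   mean
#> 16.000 16.000 17.000 16.124
```

`mu_beta_area` is the community-mean logit-scale response of occupancy to a
1 SD increase in willow area; `Ntot` is the estimated total community size
(16 of the 17 simulated species were ever detected at seed 42, and the model
finds little evidence for additional never-detected species). The richest
point (`IF12`, posterior median 12.2 species per year) combines
well-above-average willow area (40%, upper quartile) with the tallest
willows of the sample — mirroring the field result that richness climbs
with thicket extent and height.

```r
## abundance: N-mixture fit for one willow ground-breeder
y   <- simulate_counts(config, covs)
fit <- fit_nmixture(nmix_data(y, covs, "sp05_WGB"))
nmix_coef_table(fit)[2, ]
#>   term estimate     se    q2.5  q97.5
#> 2 area   0.2234 0.0358  0.1532 0.2937   # truth drawn around 0.27

## assemblage-level pooling of all species' area slopes
eff <- nmix_effect_table(fit_nmixture_all(y, covs),
                         records = data.frame(
                           latin_name = dimnames(y)[[1]],
                           assemblage = rep(c("WCB", "WGB", "OT"), c(4, 5, 8))))
pool_by_assemblage(eff[eff$covariate == "area", ])
#>     group covariate estimate     se   q2.5   q97.5 k significant
#> 1 WCB&WGB      area   0.3170 0.0196  0.279  0.3554 7        TRUE
#> 2      OT      area  -0.0717 0.0253 -0.121 -0.0221 8        TRUE
```

The willow-dependent assemblage shows a clearly positive pooled abundance
response to willow area while the open-tundra assemblage does not — the
pattern the generator encodes and the pipeline recovers. (Two rare species
with non-identifiable fits are dropped from pooling with a message.)

## Command line

```sh
Rscript inst/cli/thicketbirds simulate --seed 1 --out-dir fixture
Rscript inst/cli/thicketbirds metrics --masks fixture --out-dir out
Rscript inst/cli/thicketbirds fit-occupancy --detections fixture/detections.csv \
    --covariates fixture/covariates.csv --config settings.cfg --out-dir out
Rscript inst/cli/thicketbirds fit-nmixture --counts fixture/counts.csv \
    --covariates fixture/covariates.csv --out-dir out
Rscript inst/cli/thicketbirds pool --effects out/nmixture_effects.csv --out-dir out
```

Global flags: `--seed`, `--config` (plain `key = value` file mirroring the
model settings), `--out-dir`, `--log-level`. Every run writes a JSON manifest
(settings, seed, versions).

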