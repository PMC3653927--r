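test_that("simulated covariates hit the target correlation structure", {
  config <- sim_config(seed = 10)
  big <- simulate_covariates(config, n_points = 2000)
  r <- cor(big[, c("area", "patch_density", "edge_density", "willow_height",
                   "willow_density")])
  # patch density vs edge density strongly correlated (target 0.8)
  expect_lt(abs(r["patch_density", "edge_density"] - 0.8), 0.05)
  expect_gt(r["patch_density", "edge_density"], 0.7)
  # every other pair below 0.43
  mask <- upper.tri(r)
  dimnames(mask) <- dimnames(r)
  mask["patch_density", "edge_density"] <- FALSE
  expect_true(all(abs(r[mask]) < 0.43))

  # determinism and valid ranges
  expect_identical(simulate_covariates(config), simulate_covariates(config))
  expect_true(all(big$area >= 0 & big$area <= 100))
  expect_true(all(big$patch_density >= 0 &
                    big$patch_density == round(big$patch_density)))

  std <- standardize_covariates(simulate_covariates(config))
  for (cl in c("area", "edge_density", "willow_height", "willow_density")) {
    expect_lt(abs(mean(std[[cl]])), 1e-9)
    expect_lt(abs(sd(std[[cl]]) - 1), 1e-9)
  }
})

test_that("an infeasible correlation matrix is rejected before sampling", {
  bad <- diag(5)
  bad[1, 2] <- bad[2, 1] <- 0.95
  bad[1, 3] <- bad[3, 1] <- 0.95
  bad[2, 3] <- bad[3, 2] <- -0.95
  config <- sim_config(cov_cor = bad)
  expect_error(simulate_covariates(config), "positive definite")
})

test_that("simulated landscapes span the observed willow-cover gradient", {
  config <- sim_config(seed = 12)
  # empty target -> empty mask and zero metrics
  m0 <- simulate_landscape(config, 1, n_pixels = 100, target_area_pct = 0)
  expect_equal(sum(m0$grid), 0)
  expect_equal(unlist(thicket_metrics(m0)),
               c(area_pct = 0, patch_density = 0, edge_density = 0))

  # determinism under the master seed
  m1 <- simulate_landscape(config, 3, n_pixels = 150)
  m2 <- simulate_landscape(config, 3, n_pixels = 150)
  expect_identical(m1$grid, m2$grid)
  expect_equal(m1$pixel_size, 0.2)

  # per-point targets span ~5-50%: realized covers include <10% and >40%
  covers <- sapply(c(1, 10, 24, 37), function(i)
    100 * mean(simulate_landscape(config, i)$grid))
  expect_true(any(covers < 10))
  expect_true(any(covers > 40))
})

test_that("community detections follow the occupancy/detection equations", {
  des <- survey_design(points_per_region = c(4, 4, 4))
  zero4 <- matrix(0, 3, 4, dimnames = list(c("WCB", "WGB", "OT"), NULL))
  # degenerate limit psi = p = 1: every species detected everywhere
  config1 <- sim_config(design = des, seed = 14,
                        occ = list(mu_u = 40, sigma_u = 1e-12, mu_v = 40,
                                   sigma_v = 1e-12, rho_uv = 0,
                                   beta_mean = zero4, beta_sd = 1e-12,
                                   betap_mean = zero4, betap_sd = 1e-12))
  covs <- standardize_covariates(simulate_covariates(config1))
  x1 <- simulate_community(config1, covs)
  expect_true(all(x1 == 1))

  # psi = 0: all-zero array
  config0 <- sim_config(design = des, seed = 14,
                        occ = list(mu_u = -40, sigma_u = 1e-12))
  x0 <- simulate_community(config0, covs)
  expect_true(all(x0 == 0))

  # detection frequency among occupied point-years matches generating p
  config <- sim_config(design = des, seed = 15)
  x <- simulate_community(config, covs)
  tr <- attr(x, "truth")
  K <- des$visits_per_year
  occ_cells <- which(tr$z == 1, arr.ind = TRUE)    # (species, point, year)
  p_cell <- tr$p[cbind(occ_cells[, 1], occ_cells[, 2])]
  ndet <- sum(x)  # detections only occur in occupied cells
  expected <- K * sum(p_cell)
  se <- sqrt(K * sum(p_cell * (1 - p_cell)))
  expect_lt(abs(ndet - expected), 3 * se)

  # determinism
  expect_identical(unclass(simulate_community(config, covs)),
                   unclass(simulate_community(config, covs)))
})

test_that("count simulation follows the N-mixture generative model", {
  des <- survey_design(points_per_region = c(4, 4, 4))
  # p = 1: counts equal latent N on every visit
  config1 <- sim_config(design = des, seed = 16,
                        abund = list(p_year_logit_mean = 40,
                                     p_year_logit_sd = 1e-12))
  covs <- standardize_covariates(simulate_covariates(config1))
  y1 <- simulate_counts(config1, covs)
  N <- attr(y1, "truth")$N
  for (k in seq_len(des$visits_per_year))
    expect_equal(unname(y1[, , , k]), N)

  # log lambda = 0 with zero slopes: mean N ~ 1 by the law of large numbers
  config2 <- sim_config(design = des, seed = 17,
                        abund = list(mu_loglam = 0, sigma_loglam = 1e-12,
                                     beta_mean = matrix(0, 3, 4,
                                       dimnames = list(c("WCB", "WGB", "OT"),
                                                       NULL)),
                                     beta_sd = 1e-12))
  y2 <- simulate_counts(config2, covs)
  N2 <- attr(y2, "truth")$N
  expect_lt(abs(mean(N2) - 1), 3 / sqrt(length(N2)))

  # determinism
  expect_identical(unclass(simulate_counts(config2, covs)),
                   unclass(simulate_counts(config2, covs)))
})

test_that("count-derived detections match community detections as psi -> 1", {
  des <- survey_design(points_per_region = c(5, 5, 5))
  zero4 <- matrix(0, 3, 4, dimnames = list(c("WCB", "WGB", "OT"), NULL))
  # counts with lambda = e^2 and p_year = 1: detection iff N > 0,
  # i.e. occupancy-like with psi = 1 - exp(-lambda) ~ 0.9994, p = 1
  configc <- sim_config(design = des, seed = 18,
                        abund = list(mu_loglam = 2, sigma_loglam = 1e-12,
                                     beta_mean = zero4, beta_sd = 1e-12,
                                     p_year_logit_mean = 40,
                                     p_year_logit_sd = 1e-12))
  covs <- standardize_covariates(simulate_covariates(configc))
  xc <- counts_to_detection(simulate_counts(configc, covs))
  configo <- sim_config(design = des, seed = 18,
                        occ = list(mu_u = 40, sigma_u = 1e-12, mu_v = 40,
                                   sigma_v = 1e-12, rho_uv = 0,
                                   beta_mean = zero4, beta_sd = 1e-12,
                                   betap_mean = zero4, betap_sd = 1e-12))
  xo <- simulate_community(configo, covs)
  expect_gt(mean(xc), 0.99)       # psi -> 1 limit
  expect_equal(mean(xo), 1)
  expect_lt(abs(mean(xc) - mean(xo)), 0.01)
})

test_that("fixture directories are complete and reproducible", {
  dir1 <- file.path(tempdir(), "fix1")
  config <- sim_config(seed = 20,
                       design = survey_design(points_per_region = c(3, 3, 3),
                                              years = 2005:2006))
  simulate_fixture(config, dir1)
  expect_true(all(file.exists(file.path(
    dir1, c("covariates.csv", "counts.csv", "detections.csv", "truth.json",
            "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(man$seed, 20)
  # counts round-trip through the written CSV (all-zero species restored
  # from the explicit species axis)
  y <- read_counts(file.path(dir1, "counts.csv"), config$design,
                   species = sprintf("sp%02d_%s", 1:17,
                                     rep(c("WCB", "WGB", "OT"), c(4, 5, 8))))
  covs <- standardize_covariates(
    read_covariates(file.path(dir1, "covariates.csv")))
  y2 <- simulate_counts(config, covs)
  attr(y2, "truth") <- NULL
  expect_equal(unname(unclass(y)), unname(unclass(y2)))
})

test_that("estimation error shrinks as the design grows (consistency smoke)", {
  # N-mixture area slope at 1x and 4x the point count, averaged over seeds
  err_at <- function(mult, seed) {
    des <- survey_design(points_per_region = c(12, 13, 12) * mult)
    config <- sim_config(
      design = des, seed = seed,
      abund = list(mu_loglam = 0.5, sigma_loglam = 1e-12,
                   beta_mean = rbind(WCB = c(0.27, 0, 0, 0),
                                     WGB = c(0.27, 0, 0, 0),
                                     OT = c(0.27, 0, 0, 0)),
                   beta_sd = 1e-12, p_year_logit_sd = 0))
    covs <- standardize_covariates(simulate_covariates(config))
    y <- simulate_counts(config, covs)
    fit <- fit_nmixture(nmix_data(y, covs, dimnames(y)[[1]][1]))
    abs(unname(fit$coef["area"]) - 0.27)
  }
  e1 <- mean(sapply(1:3, function(s) err_at(1, 7000 + s)))
  e4 <- mean(sapply(1:3, function(s) err_at(4, 7000 + s)))
  expect_lt(e4, e1)
})
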