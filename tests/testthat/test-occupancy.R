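test_that("marginal detection likelihood sums the latent state out", {
  # all-zero history: psi * (1-p)^K + (1 - psi)
  expect_equal(marginal_detection_loglik(c(0, 0, 0), 0.5, 0.5), log(0.5625))
  # a detection forces z = 1
  expect_equal(marginal_detection_loglik(c(1, 0, 0), 1, 0.5), log(0.125))
  # oracle equivalence on random inputs
  set.seed(19)
  for (rep in 1:50) {
    K <- sample(1:6, 1)
    psi <- runif(1); p <- runif(1)
    x <- rbinom(K, 1, runif(1))
    expect_equal(marginal_detection_loglik(x, psi, p),
                 oracle_marginal(x, psi, p), tolerance = 1e-12)
  }
  expect_error(marginal_detection_loglik(c(0, 2), 0.5, 0.5), "0/1")
  expect_error(marginal_detection_loglik(c(0, 1), 1.5, 0.5), "\\[0, 1\\]")
})

test_that("Gelman-Rubin diagnostic behaves at its limits and by formula", {
  set.seed(29)
  ch <- rnorm(1000)
  # two identical chains: no excess between-chain variance
  expect_lt(abs(gelman_rubin(list(ch, ch)) - 1), 0.01)
  # grossly separated chains
  expect_gt(gelman_rubin(list(rnorm(200), rnorm(200, 10))), 3)
  # two 50-draw chains against the between/within variance formula
  c1 <- rnorm(50); c2 <- rnorm(50, 0.3)
  n <- 50
  W <- mean(c(var(c1), var(c2)))
  B_over_n <- var(c(mean(c1), mean(c2)))
  want <- sqrt(((n - 1) / n * W + B_over_n) / W)
  expect_equal(unname(gelman_rubin(list(c1, c2))), want, tolerance = 1e-12)

  expect_error(gelman_rubin(list(c1)), "2 chains")
  expect_error(gelman_rubin(list(c1[1:5], c2[1:5])), ">= 10")
})

test_that("retained-draw bookkeeping follows the chain settings", {
  expect_equal(retained_draws(community_spec()), 2700L)
  expect_equal(retained_draws(community_spec(), per_chain = FALSE), 5400L)
  expect_equal(retained_draws(community_spec(iterations = 3000, burn_in = 500,
                                             thin = 5)), 500L)
  expect_error(community_spec(iterations = 100, burn_in = 200), "exceed")
})

test_that("run_mcmc validates inputs and is reproducible", {
  config <- sim_config(seed = 4, design = survey_design(
    points_per_region = c(4, 4, 4), years = 2005:2006))
  covs <- standardize_covariates(simulate_covariates(config))
  x <- simulate_community(config, covs)
  spec <- community_spec(n_aug = 5, chains = 2, iterations = 300,
                         burn_in = 100, thin = 2, seed = 77)

  raw <- unstandardize_covariates(covs)
  expect_error(run_mcmc(x, raw, spec), "standardized")
  expect_error(run_mcmc(x, covs, community_spec(n_aug = 0, iterations = 300,
                                                burn_in = 100)),
               "augmentation")

  d1 <- run_mcmc(x, covs, spec)
  d2 <- run_mcmc(x, covs, spec)
  expect_identical(d1$chains[[1]]$hypers, d2$chains[[1]]$hypers)
  expect_identical(d1$chains[[2]]$u, d2$chains[[2]]$u)
  expect_equal(nrow(d1$chains[[1]]$hypers), retained_draws(spec))

  # invariants across every retained draw: species actually detected in the
  # data always have w = 1, so detected richness bounds Ntot from below
  h <- do.call(rbind, lapply(d1$chains, `[[`, "hypers"))
  everdet <- apply(x, 1, function(a) any(a > 0))
  expect_true(all(h[, "Ntot"] >= sum(everdet) & h[, "Ntot"] <= d1$M))
  w <- do.call(rbind, lapply(d1$chains, `[[`, "w"))
  expect_true(all(w[, which(everdet)] == 1))
  # z respects the data in every retained draw
  expect_true(all(unlist(lapply(d1$chains, `[[`, "z_respects_data")) == 1))
})

test_that("derived richness sums inclusion-weighted occupancy", {
  # two species at two points with psi ~ (1,1) and (0,1): richness (1, 2)
  big <- 40 # logit scale: plogis(40) == 1, plogis(-40) == 0 numerically
  X <- matrix(c(-1, 1), 2, 1)
  d <- make_fake_draws(u = c(big, 0), beta = rbind(0, big / 1), X = X)
  # species 1: psi = 1 at both points; species 2: psi ~ 0 then ~ 1
  r <- derive_richness(d)
  expect_equal(r$median, rep(c(1, 2), each = 1), tolerance = 1e-10)

  # 10 species all at psi 0.5, w = 1 -> richness 5
  d2 <- make_fake_draws(u = rep(0, 10), beta = matrix(0, 10, 1),
                        X = matrix(0, 3, 1))
  r2 <- derive_richness(d2)
  expect_equal(r2$median, rep(5, 3), tolerance = 1e-12)

  # excluded species (w = 0) do not count
  d3 <- make_fake_draws(u = rep(big, 4), beta = matrix(0, 4, 1),
                        w = c(1, 1, 0, 0), X = matrix(0, 2, 1))
  expect_equal(derive_richness(d3)$median, rep(2, 2), tolerance = 1e-10)
  expect_equal(unname(attr(derive_richness(d3), "Ntot")["median"]), 2)

  expect_error(derive_richness(d3, grouping = list(g = "nope")), "unknown")
})

test_that("richness is linear in species: mean of sum equals sum of means", {
  set.seed(57)
  M <- 6; C <- 2; npts <- 4; ndraw <- 50
  X <- matrix(rnorm(npts * C), npts, C)
  chains <- lapply(1:2, function(ch) {
    u <- matrix(rnorm(ndraw * M), ndraw, M)
    beta <- matrix(rnorm(ndraw * M * C, 0, 0.5), ndraw, M * C)
    hy <- matrix(0, ndraw, 5 + 4 * C + 2)
    colnames(hy) <- c("mu_u", "sigma_u", "mu_v", "sigma_v", "rho_uv",
                      paste0("mu_beta_c", 1:C), paste0("sigma_beta_c", 1:C),
                      paste0("mu_betap_c", 1:C), paste0("sigma_betap_c", 1:C),
                      "Omega", "Ntot")
    list(u = u, v = u, beta = beta, betap = beta,
         w = matrix(1L, ndraw, M), hypers = hy, n_keep = ndraw)
  })
  d <- make_fake_draws(u = rep(0, M), beta = matrix(0, M, C), X = X)
  d$chains <- chains
  # per-point posterior mean richness via the package
  sp <- thicketbirds:::.species_draws(d)
  R <- apply(thicketbirds:::.psi_draws(sp, X, 1:M), c(1, 3), sum)
  # independent: sum over species of per-species mean occupancy
  bymean <- sapply(seq_len(npts), function(l) {
    s <- 0
    for (i in 1:M) {
      b <- matrix(sp$beta[, i, ], ncol = C)
      s <- s + mean(plogis(sp$u[, i] + drop(b %*% X[l, ])))
    }
    s
  })
  expect_equal(colMeans(R), bymean, tolerance = 1e-10)
})

test_that("richness surface matches pointwise derivation and is monotone", {
  set.seed(61)
  M <- 5
  beta <- cbind(area = runif(M, 0.3, 1.2), edge_density = rnorm(M, 0, 0.3),
                willow_height = 0, willow_density = 0)
  u <- rnorm(M)
  X <- matrix(rnorm(8), 2, 4,
              dimnames = list(NULL, colnames(beta)))
  d <- make_fake_draws(u = u, beta = beta, X = X)

  a <- c(-1, 0, 1); e <- c(-1, 0, 1)
  surf <- suppressWarnings(predict_richness_surface(d, a, e))
  expect_equal(nrow(surf), 9)

  # pointwise re-evaluation through derive_richness at the same covariates
  grid <- expand.grid(area = a, edge_density = e)
  covtab <- data.frame(point = sprintf("g%d", 1:9), area = grid$area,
                       edge_density = grid$edge_density, willow_height = 0,
                       willow_density = 0)
  r <- derive_richness(d, covtab)
  expect_equal(surf$median, r$median[seq_len(9)], tolerance = 1e-10)

  # all area slopes positive -> nondecreasing along the area axis
  for (ee in e) {
    s <- surf[surf$edge_density == ee, ]
    expect_true(all(diff(s$median[order(s$area)]) >= -1e-12))
  }

  # node at all-zero covariates equals mean-covariate richness
  zero <- surf[surf$area == 0 & surf$edge_density == 0, ]
  r0 <- derive_richness(d, data.frame(point = "z", area = 0,
                                      edge_density = 0, willow_height = 0,
                                      willow_density = 0))
  expect_equal(zero$median, r0$median[1], tolerance = 1e-12)

  # extrapolation beyond the data is flagged with a warning, not an error
  expect_warning(predict_richness_surface(d, c(0, 50), 0), "extrapolation")
})

test_that("with all slopes fixed at zero richness is identical across points", {
  set.seed(71)
  X <- matrix(rnorm(12), 6, 2)  # heterogeneous covariates
  d <- make_fake_draws(u = rnorm(5), beta = matrix(0, 5, 2), X = X)
  r <- derive_richness(d)
  expect_equal(r$median, rep(r$median[1], nrow(r)), tolerance = 1e-12)
})

test_that("community-mean slope recovery is unbiased where data are informative", {
  # high detection, no detection-covariate confounding: the posterior
  # concentrates and the estimator must be calibrated (see methods vignette
  # for behaviour under weak detection)
  zero4 <- matrix(0, 3, 4, dimnames = list(c("WCB", "WGB", "OT"), NULL))
  meds <- numeric(20)
  for (rep in 1:20) {
    bm <- rbind(WCB = c(1, 0, 0, 0), WGB = c(1, 0, 0, 0), OT = c(1, 0, 0, 0))
    config <- sim_config(seed = 3000 + rep,
                         occ = list(beta_mean = bm, mu_v = 2, sigma_v = 0.3,
                                    rho_uv = 0, betap_mean = zero4,
                                    betap_sd = 1e-6))
    covs <- standardize_covariates(simulate_covariates(config))
    x <- simulate_community(config, covs)
    spec <- community_spec(chains = 2, iterations = 3000, burn_in = 500,
                           thin = 5, seed = 3000 + rep)
    d <- run_mcmc(x, covs, spec)
    h <- do.call(rbind, lapply(d$chains, `[[`, "hypers"))
    meds[rep] <- median(h[, "mu_beta_area"])
  }
  expect_lt(abs(mean(meds) - 1), 0.1)
})
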