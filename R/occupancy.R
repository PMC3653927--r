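#' Settings for the community occupancy model
#'
#' Defaults follow the analysis the package emulates: a superpopulation built
#' by adding `n_aug = 32` all-zero species to the n detected species, two
#' parallel chains of 30000 iterations, 3000 discarded as burn-in and 1 in 10
#' retained.
#'
#' @param n_aug Number of all-zero augmented species (M = n + n_aug).
#' @param covariate_names Ordered covariate columns entering both the
#'   occupancy and detection linear predictors.
#' @param chains,iterations,burn_in,thin MCMC settings.
#' @param prior_mean_sd SD of the Normal(0, .) hyperprior on community means.
#' @param prior_sd_max Upper bound of the Uniform(0, .) hyperprior on
#'   community SDs.
#' @param seed Master seed; per-chain seeds are `seed + chain - 1`.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(n_aug = 32L,
                           covariate_names = c("area", "edge_density",
                                               "willow_height",
                                               "willow_density"),
                           chains = 2L, iterations = 30000L, burn_in = 3000L,
                           thin = 10L, prior_mean_sd = 10, prior_sd_max = 10,
                           seed = 1L) {
  if (n_aug < 0) stop("n_aug must be >= 0", call. = FALSE)
  if (iterations <= burn_in) stop("iterations must exceed burn_in", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if (chains < 1) stop("need at least one chain", call. = FALSE)
  structure(list(n_aug = as.integer(n_aug),
                 covariate_names = covariate_names,
                 chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_mean_sd = prior_mean_sd, prior_sd_max = prior_sd_max,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Retained draws implied by MCMC settings
#'
#' @param spec A [community_spec()].
#' @param per_chain Return the per-chain count (default) or the total over
#'   chains.
#' @return Integer number of retained posterior draws.
#' @export
retained_draws <- function(spec, per_chain = TRUE) {
  k <- (spec$iterations - spec$burn_in) %/% spec$thin
  if (per_chain) k else k * spec$chains
}

#' Marginal log-likelihood of one detection history
#'
#' Likelihood of a binary visit history for one species x point x year with
#' the latent occupancy state summed out:
#' `log(psi * p^d * (1-p)^(K-d) + (1-psi) * I(d == 0))`
#' for `d` detections in `K` visits. Distinguishes true absence from
#' nondetection.
#'
#' @param x_history Binary vector of per-visit detections.
#' @param psi Occupancy probability.
#' @param p Per-visit detection probability.
#' @return Log-probability of the history.
#' @export
#' @examples
#' marginal_detection_loglik(c(0, 0, 0), 0.5, 0.5)  # log(0.5625)
marginal_detection_loglik <- function(x_history, psi, p) {
  if (any(is.na(x_history)) || !all(x_history %in% c(0, 1)))
    stop("validation error: history entries must be 0/1", call. = FALSE)
  if (psi < 0 || psi > 1 || p < 0 || p > 1)
    stop("psi and p must lie in [0, 1]", call. = FALSE)
  d <- sum(x_history)
  K <- length(x_history)
  log(psi * p^d * (1 - p)^(K - d) + (1 - psi) * (d == 0))
}

# detection array (species x point x year x visit) -> detections per
# species x point x year, plus axis checks
.collapse_detections <- function(x) {
  if (length(dim(x)) != 4)
    stop("detection array must be species x point x year x visit", call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop("validation error: detection entries must be 0/1", call. = FALSE)
  apply(x, c(1, 2, 3), sum)
}

#' Fit the data-augmented multispecies occupancy model
#'
#' Runs a Metropolis-within-Gibbs sampler for the hierarchical community
#' occupancy model: species-level occupancy and detection intercepts drawn
#' from a bivariate normal community distribution, per-covariate slopes from
#' normal community distributions, and `n_aug` all-zero augmented species with
#' inclusion indicators `w` so that total community size is estimable.
#' Occupancy is redrawn each year; covariates are point-level and constant
#' across years.
#'
#' @param x Binary `detection_array` (species x point x year x visit).
#' @param covariates Standardized covariate table (see
#'   [standardize_covariates()]) with one row per point in the array's point
#'   order.
#' @param spec A [community_spec()].
#' @param verbose Print progress.
#' @return Object of class `occ_draws`: per-chain posterior draws of species
#'   parameters (`u`, `v`, `beta`, `betap`), inclusion indicators `w`,
#'   hyperparameters, total richness `Ntot`, plus Rhat per hyperparameter and
#'   bookkeeping (`species`, covariate centres/scales, the settings used).
#' @export
run_mcmc <- function(x, covariates, spec = community_spec(), verbose = FALSE) {
  d <- .collapse_detections(x)
  n <- dim(x)[1]; L <- dim(x)[2]; J <- dim(x)[3]; K <- dim(x)[4]
  if (spec$n_aug <= 0)
    stop(paste0("augmentation must be applied: spec$n_aug must be > 0 so the",
                " superpopulation exceeds the observed species"), call. = FALSE)
  cn <- spec$covariate_names
  missing <- setdiff(cn, names(covariates))
  if (length(missing))
    stop("format error: missing covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(covariates) != L)
    stop("covariate table has ", nrow(covariates), " rows but the detection",
         " array has ", L, " points", call. = FALSE)
  X <- as.matrix(covariates[, cn, drop = FALSE])
  mu <- colMeans(X); sdev <- apply(X, 2, stats::sd)
  if (any(abs(mu) > 1e-6) || any(abs(sdev - 1) > 1e-6))
    stop("covariates must be standardized (mean 0, SD 1); call ",
         "standardize_covariates() first", call. = FALSE)

  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch - 1L)
    if (verbose) message("chain ", ch, "/", spec$chains)
    chains[[ch]] <- .occ_mcmc_chain(as.integer(d), n, L, J, K, X,
                                    spec$n_aug, spec$iterations, spec$burn_in,
                                    spec$thin, spec$prior_mean_sd,
                                    spec$prior_sd_max)
  }
  C <- length(cn)
  hyper_names <- c("mu_u", "sigma_u", "mu_v", "sigma_v", "rho_uv",
                   paste0("mu_beta_", cn), paste0("sigma_beta_", cn),
                   paste0("mu_betap_", cn), paste0("sigma_betap_", cn),
                   "Omega", "Ntot")
  for (ch in seq_along(chains)) colnames(chains[[ch]]$hypers) <- hyper_names

  out <- structure(list(
    chains = chains,
    species = dimnames(x)[[1]],
    n_obs = n, M = n + spec$n_aug, n_points = L, n_years = J, n_visits = K,
    covariate_names = cn,
    X = X,
    center = attr(covariates, "center"), scale = attr(covariates, "scale"),
    point_ids = if (!is.null(covariates$point)) covariates$point
                else dimnames(x)[[2]],
    years = dimnames(x)[[3]],
    spec = spec
  ), class = "occ_draws")
  out$rhat <- gelman_rubin(lapply(chains, `[[`, "hypers"))
  out
}

#' @export
print.occ_draws <- function(x, ...) {
  cat(sprintf(paste0("Community occupancy fit: %d observed + %d augmented",
                     " species, %d points x %d years x %d visits\n"),
              x$n_obs, x$M - x$n_obs, x$n_points, x$n_years, x$n_visits))
  cat(sprintf("%d chains x %d retained draws; max hyperparameter Rhat %.3f\n",
              length(x$chains), x$chains[[1]]$n_keep, max(x$rhat)))
  print(posterior_summary(x))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) Rhat from between- and within-chain variances:
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` for m chains of n draws. Values
#' close to 1 indicate convergence.
#'
#' @param chain_draws List (one element per chain) of numeric vectors or of
#'   draws-by-parameter matrices with matching columns.
#' @return Named numeric vector of Rhat values, one per parameter.
#' @export
gelman_rubin <- function(chain_draws) {
  if (!is.list(chain_draws) || length(chain_draws) < 2)
    stop("need at least 2 chains", call. = FALSE)
  mats <- lapply(chain_draws, function(m) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    as.matrix(m)
  })
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) != 1 || ns[1] < 10)
    stop("chains must have equal length >= 10", call. = FALSE)
  n <- ns[1]
  vapply(seq_len(ncol(mats[[1]])), function(jj) {
    draws <- vapply(mats, function(m) m[, jj], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    B_over_n <- stats::var(colMeans(draws))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1), USE.NAMES = FALSE) -> rh
  names(rh) <- colnames(mats[[1]])
  rh
}

# combined hyperparameter draw matrix (all chains stacked)
.hyper_draws <- function(draws) do.call(rbind, lapply(draws$chains, `[[`, "hypers"))

# combined species-parameter draws: list of u, v (draws x M), beta, betap
# (draws x M x C arrays), w (draws x M)
.species_draws <- function(draws) {
  M <- draws$M; C <- length(draws$covariate_names)
  comb <- function(name) do.call(rbind, lapply(draws$chains, `[[`, name))
  b <- comb("beta"); bp <- comb("betap")
  list(u = comb("u"), v = comb("v"),
       beta = array(b, dim = c(nrow(b), M, C)),
       betap = array(bp, dim = c(nrow(bp), M, C)),
       w = comb("w"))
}

#' Posterior summary table
#'
#' @param draws An `occ_draws` object.
#' @param params Which hyperparameters to summarize (default all).
#' @return Data frame (parameter, median, q2.5, q97.5, Rhat).
#' @export
posterior_summary <- function(draws, params = NULL) {
  h <- .hyper_draws(draws)
  if (!is.null(params)) h <- h[, params, drop = FALSE]
  qs <- t(apply(h, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  data.frame(parameter = colnames(h), median = qs[, 1], q2.5 = qs[, 2],
             q97.5 = qs[, 3],
             Rhat = unname(draws$rhat[colnames(h)]), row.names = NULL)
}

# per-draw psi for the requested species set at covariate matrix Xnew
# returns draws x nspecies x npoints array of w_i * psi_il
.psi_draws <- function(sp, Xnew, species_idx) {
  ndraw <- nrow(sp$u)
  npt <- nrow(Xnew)
  out <- array(0, dim = c(ndraw, length(species_idx), npt))
  for (s in seq_along(species_idx)) {
    i <- species_idx[s]
    eta <- sp$u[, i] %o% rep(1, npt) +
      matrix(sp$beta[, i, ], nrow = ndraw) %*% t(Xnew)
    out[, s, ] <- sp$w[, i] * stats::plogis(eta)
  }
  out
}

#' Derived richness summaries
#'
#' Per retained draw, richness at point l in year j is the sum over the
#' selected species group of `w_i * psi_il` (occupancy is redrawn each year
#' but covariates are constant, so expected richness is shared across years).
#' Summed over the whole superpopulation this yields community richness; the
#' total community size `Ntot = sum(w)` is summarized alongside.
#'
#' @param draws An `occ_draws` object.
#' @param covariates Standardized covariate table matching the fit (defaults
#'   to the table used in fitting).
#' @param grouping `"all"` (whole community including augmented species), or a
#'   named list of species groups (e.g. [assemblage_partition()] output) whose
#'   names are looked up among observed species.
#' @return Data frame (point, year, group, median, q2.5, q97.5) of posterior
#'   richness, with attribute `Ntot` summarizing total community size.
#' @export
derive_richness <- function(draws, covariates = NULL, grouping = "all") {
  Xnew <- if (is.null(covariates)) draws$X
          else as.matrix(covariates[, draws$covariate_names, drop = FALSE])
  sp <- .species_draws(draws)
  groups <- if (identical(grouping, "all")) list(all = seq_len(draws$M))
  else {
    lapply(grouping, function(g) {
      idx <- match(g, draws$species)
      if (anyNA(idx))
        stop("unknown species in grouping: ",
             paste(g[is.na(idx)], collapse = ", "), call. = FALSE)
      idx
    })
  }
  pts <- if (!is.null(covariates) && !is.null(covariates$point))
    covariates$point else draws$point_ids[seq_len(nrow(Xnew))]
  res <- list()
  for (gname in names(groups)) {
    R <- apply(.psi_draws(sp, Xnew, groups[[gname]]), c(1, 3), sum) # draws x pts
    qs <- apply(R, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
    for (j in seq_len(draws$n_years)) {
      res[[length(res) + 1]] <- data.frame(
        point = pts, year = draws$years[j], group = gname,
        median = qs[1, ], q2.5 = qs[2, ], q97.5 = qs[3, ], row.names = NULL)
    }
  }
  out <- do.call(rbind, res)
  ntot <- rowSums(sp$w)
  attr(out, "Ntot") <- c(median = stats::median(ntot),
                         q2.5 = unname(stats::quantile(ntot, 0.025)),
                         q97.5 = unname(stats::quantile(ntot, 0.975)),
                         mean = mean(ntot))
  out
}

#' Expected richness over a willow area x edge density grid
#'
#' Evaluates expected community richness on a grid of (area, edge density)
#' values with the remaining covariates held at their means (0 on the
#' standardized scale) — the conditional-effect surface behind the
#' area-by-fragmentation richness contour plot.
#'
#' @param draws An `occ_draws` object.
#' @param area,edge_density Grid values. Interpreted on the standardized scale
#'   unless `raw_scale = TRUE`, in which case they are converted using the
#'   centres/scales stored at fit time.
#' @param raw_scale Are the grid values on the raw covariate scale?
#' @param grouping As in [derive_richness()].
#' @return Data frame (area, edge_density, median, q2.5, q97.5) over the full
#'   grid. Grid nodes outside the range of the fitted covariate values are
#'   flagged in the `extrapolated` column (with a warning).
#' @export
predict_richness_surface <- function(draws, area, edge_density,
                                     raw_scale = FALSE, grouping = "all") {
  cn <- draws$covariate_names
  if (raw_scale) {
    if (is.null(draws$center))
      stop("fit carries no center/scale; supply standardized values",
           call. = FALSE)
    area <- (area - draws$center["area"]) / draws$scale["area"]
    edge_density <- (edge_density - draws$center["edge_density"]) /
      draws$scale["edge_density"]
  }
  grid <- expand.grid(area = area, edge_density = edge_density,
                      KEEP.OUT.ATTRS = FALSE)
  Xnew <- matrix(0, nrow(grid), length(cn), dimnames = list(NULL, cn))
  Xnew[, "area"] <- grid$area
  Xnew[, "edge_density"] <- grid$edge_density
  sp <- .species_draws(draws)
  idx <- if (identical(grouping, "all")) seq_len(draws$M)
         else match(unlist(grouping), draws$species)
  R <- apply(.psi_draws(sp, Xnew, idx), c(1, 3), sum)
  qs <- apply(R, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  rng_a <- range(draws$X[, "area"]); rng_e <- range(draws$X[, "edge_density"])
  extra <- grid$area < rng_a[1] | grid$area > rng_a[2] |
    grid$edge_density < rng_e[1] | grid$edge_density > rng_e[2]
  if (any(extra))
    warning(sum(extra), " grid node(s) outside the observed covariate range",
            " (extrapolation)", call. = FALSE)
  data.frame(grid, median = qs[1, ], q2.5 = qs[2, ], q97.5 = qs[3, ],
             extrapolated = extra, row.names = NULL)
}

#' Species-level posterior effect estimates
#'
#' Posterior mean and SD of each observed species' occupancy slopes, in the
#' (estimate, se) form consumed by [pool_fixed()] / [pool_random()].
#'
#' @param draws An `occ_draws` object.
#' @return Data frame (species, covariate, estimate, se, q2.5, q97.5).
#' @export
species_effects <- function(draws) {
  sp <- .species_draws(draws)
  cn <- draws$covariate_names
  res <- list()
  for (i in seq_len(draws$n_obs)) {
    for (c in seq_along(cn)) {
      b <- sp$beta[, i, c]
      res[[length(res) + 1]] <- data.frame(
        species = draws$species[i], covariate = cn[c],
        estimate = mean(b), se = stats::sd(b),
        q2.5 = unname(stats::quantile(b, 0.025)),
        q97.5 = unname(stats::quantile(b, 0.975)))
    }
  }
  do.call(rbind, res)
}
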