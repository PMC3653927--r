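#' Configuration of the synthetic study
#'
#' Describes the "stated world" the generator emulates: the survey design
#' (3 regions, 37 points, 4 years, 3 visits), 17 species in three assemblages
#' (4 WCB, 5 WGB, 8 OT), covariate correlation structure (patch vs edge
#' density r ~ 0.8, all other pairs < 0.43), and assemblage-structured effect
#' sizes. Occupancy-scale defaults: willow-dependent assemblages respond to
#' area with community-mean logit slope 0.99; open-tundra species have zero
#' mean slopes but nonzero between-species spread. Abundance-scale defaults:
#' area 0.27 and willow height 0.16 (log scale) for willow-dependent species.
#' Intercept spreads are chosen so occupancy spans roughly 7--95% and
#' detection 12--71% across species, with occupancy-detection correlation
#' 0.75.
#'
#' @param design A [survey_design()].
#' @param assemblage_sizes Named integer vector (WCB, WGB, OT).
#' @param occ Occupancy-model truth: list with `mu_u`, `sigma_u`, `mu_v`,
#'   `sigma_v`, `rho_uv`, `beta_mean` (assemblage x covariate matrix),
#'   `beta_sd`, `betap_mean`, `betap_sd`.
#' @param abund Abundance-model truth: `mu_loglam`, `sigma_loglam`,
#'   `beta_mean` (assemblage x covariate), `beta_sd`, `p_year_logit_mean`,
#'   `p_year_logit_sd`.
#' @param cov_cor Target correlation of the latent covariate field
#'   (5 x 5: area, patch_density, edge_density, willow_height,
#'   willow_density).
#' @param seed Master seed; artifact sub-seeds are derived from it (see
#'   [sub_seed()]).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(design = survey_design(),
                       assemblage_sizes = c(WCB = 4L, WGB = 5L, OT = 8L),
                       occ = NULL, abund = NULL, cov_cor = NULL, seed = 1L) {
  covs <- c("area", "edge_density", "willow_height", "willow_density")
  if (is.null(occ)) occ <- list()
  occ <- utils::modifyList(list(
    mu_u = 0, sigma_u = 1.5,
    mu_v = stats::qlogis(0.3), sigma_v = 0.8, rho_uv = 0.75,
    beta_mean = rbind(WCB = c(0.99, -0.13, 0.30, 0.09),
                      WGB = c(0.99, -0.13, 0.30, 0.09),
                      OT = c(0, 0, 0, 0)),
    beta_sd = 0.5,
    betap_mean = rbind(WCB = c(0.3, 0, 0, 0), WGB = c(0.3, 0, 0, 0),
                       OT = c(0.3, 0, 0, 0)),
    betap_sd = 0.3), occ)
  if (is.null(abund)) abund <- list()
  abund <- utils::modifyList(list(
    mu_loglam = 0, sigma_loglam = 1.8,
    beta_mean = rbind(WCB = c(0.27, 0.02, 0.16, 0.01),
                      WGB = c(0.27, 0.02, 0.16, 0.01),
                      OT = c(0, 0, 0, 0)),
    beta_sd = 0.1,
    p_year_logit_mean = 0, p_year_logit_sd = 0.3), abund)
  colnames(occ$beta_mean) <- colnames(occ$betap_mean) <- covs
  colnames(abund$beta_mean) <- covs
  if (is.null(cov_cor)) {
    cov_cor <- diag(5)
    vars <- c("area", "patch_density", "edge_density", "willow_height",
              "willow_density")
    dimnames(cov_cor) <- list(vars, vars)
    cov_cor["patch_density", "edge_density"] <- 0.8
    cov_cor["area", "patch_density"] <- 0.25
    cov_cor["area", "edge_density"] <- 0.30
    cov_cor["area", "willow_height"] <- 0.30
    cov_cor["area", "willow_density"] <- 0.20
    cov_cor["willow_height", "willow_density"] <- 0.30
    cov_cor[lower.tri(cov_cor)] <- t(cov_cor)[lower.tri(cov_cor)]
  }
  sizes <- assemblage_sizes[c("WCB", "WGB", "OT")]
  if (anyNA(sizes)) stop("assemblage_sizes needs WCB, WGB, OT", call. = FALSE)
  if (any(c(occ$sigma_u, occ$sigma_v, occ$beta_sd, occ$betap_sd,
            abund$sigma_loglam) <= 0))
    stop("all SDs must be > 0", call. = FALSE)
  structure(list(design = design, assemblage_sizes = sizes,
                 n_species = sum(sizes), occ = occ, abund = abund,
                 cov_cor = cov_cor, seed = as.integer(seed)),
            class = "sim_config")
}

#' Derive an artifact sub-seed from the master seed
#'
#' Fixed scheme so each artifact (covariates, landscapes, detection
#' histories, counts) can be regenerated independently and reproducibly:
#' `(seed * 1009 + offset) mod (2^31 - 1)` with documented per-artifact
#' offsets (covariates 1, community 2, counts 3, landscape 100 + point).
#'
#' @param seed Master seed.
#' @param offset Artifact offset.
#' @return Integer seed below 2^31.
#' @export
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% (2^31 - 1))
}

# species names + assemblage labels for a config
.sim_species <- function(config) {
  a <- rep(names(config$assemblage_sizes), config$assemblage_sizes)
  data.frame(species = sprintf("sp%02d_%s", seq_along(a), a), assemblage = a,
             stringsAsFactors = FALSE)
}

#' Simulate point-level covariates
#'
#' Draws the five willow variables from a multivariate normal latent field
#' with the target correlation structure, then back-transforms each margin to
#' its natural scale and range: area as % of the 4-ha quadrat clipped to
#' [0, 100], patch density rounded to a nonnegative count, edge density in
#' metres, willow height in cm, willow density in point-frequency hits.
#'
#' @param config A [sim_config()].
#' @param n_points Override the design's point count (useful for large-n
#'   correlation checks).
#' @return Data frame (point, region, area, patch_density, edge_density,
#'   willow_height, willow_density); attribute `truth` holds the latent draws.
#' @export
simulate_covariates <- function(config, n_points = NULL) {
  R <- config$cov_cor
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("covariate correlation matrix is not positive definite", call. = FALSE)
  set.seed(sub_seed(config$seed, 1))
  n <- if (is.null(n_points)) sum(config$design$points_per_region) else n_points
  Z <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(R)
  raw <- data.frame(
    area = pmin(100, pmax(0, 27 + 13 * Z[, 1])),
    patch_density = pmax(0, round(15 + 5 * Z[, 2])),
    edge_density = pmax(0, 1600 + 500 * Z[, 3]),
    willow_height = pmax(5, 80 + 25 * Z[, 4]),
    willow_density = pmax(0, 9 + 4 * Z[, 5]))
  pts <- if (is.null(n_points)) point_ids(config$design)
         else sprintf("P%04d", seq_len(n))
  regs <- if (is.null(n_points)) point_regions(config$design)
          else rep(config$design$regions, length.out = n)
  out <- cbind(data.frame(point = pts, region = regs,
                          stringsAsFactors = FALSE), raw)
  attr(out, "truth") <- list(latent = Z)
  out
}

# fill an ellipse into a binary matrix (pixel units); returns the updated
# grid and the number of newly covered pixels so callers can track coverage
# without rescanning the whole mask
.fill_ellipse <- function(g, cr, cc, a, b, theta) {
  nr <- nrow(g); nc <- ncol(g)
  ext <- ceiling(max(a, b))
  r1 <- max(1, floor(cr - ext)); r2 <- min(nr, ceiling(cr + ext))
  c1 <- max(1, floor(cc - ext)); c2 <- min(nc, ceiling(cc + ext))
  if (r1 > r2 || c1 > c2) return(list(g = g, added = 0L))
  dr <- (r1:r2) - cr
  dc <- (c1:c2) - cc
  ct <- cos(theta); st <- sin(theta)
  xr <- outer(dr, dc, function(y, x) ((x * ct + y * st) / a)^2 +
                ((-x * st + y * ct) / b)^2)
  sub <- g[r1:r2, c1:c2, drop = FALSE]
  inside <- xr <= 1
  added <- sum(inside & sub == 0L)
  sub[inside] <- 1L
  g[r1:r2, c1:c2] <- sub
  list(g = g, added = added)
}

#' Simulate a willow landscape for one sampling point
#'
#' Builds a 1000 x 1000 binary mask at 0.2 m (a 200 x 200 m quadrat) from
#' randomly placed, partially overlapping elliptical thicket clumps. Per-point
#' target cover spans 5--50% across the design's points (matching the sampled
#' gradient of willow areal extent), achieved by adding clumps until the
#' realized cover reaches the target.
#'
#' @param config A [sim_config()].
#' @param point Point index (1-based) or point id.
#' @param n_pixels Mask side in pixels (default 1000).
#' @param target_area_pct Override the per-point target cover (%); 0 gives an
#'   empty mask.
#' @return A [willow_mask()]; attribute `truth` records clump geometry and the
#'   target.
#' @export
simulate_landscape <- function(config, point, n_pixels = 1000,
                               target_area_pct = NULL) {
  pts <- point_ids(config$design)
  pi_ <- if (is.character(point)) match(point, pts) else as.integer(point)
  if (is.na(pi_) || pi_ < 1)
    stop("unknown point: ", point, call. = FALSE)
  if (is.null(target_area_pct)) {
    targets <- seq(5, 50, length.out = length(pts))
    target_area_pct <- targets[((pi_ - 1) %% length(pts)) + 1]
  }
  set.seed(sub_seed(config$seed, 100 + pi_))
  g <- matrix(0L, n_pixels, n_pixels)
  clumps <- list()
  covered <- 0L
  # clump semi-axes scale with the quadrat (4-12 m x 2-8 m at the default
  # 200 m side) so cover accrues in realistic increments
  ax <- n_pixels * c(0.02, 0.06)
  bx <- n_pixels * c(0.01, 0.04)
  while (covered / n_pixels^2 < target_area_pct / 100) {
    cl <- list(cr = stats::runif(1, 1, n_pixels),
               cc = stats::runif(1, 1, n_pixels),
               a = stats::runif(1, ax[1], ax[2]),
               b = stats::runif(1, bx[1], bx[2]),
               theta = stats::runif(1, 0, pi))
    fe <- .fill_ellipse(g, cl$cr, cl$cc, cl$a, cl$b, cl$theta)
    g <- fe$g
    covered <- covered + fe$added
    clumps[[length(clumps) + 1]] <- cl
  }
  m <- willow_mask(g, pixel_size = 0.2)
  attr(m, "truth") <- list(point = pts[pi_], target_area_pct = target_area_pct,
                           clumps = clumps)
  m
}

# draw species-level parameters from assemblage-structured communities
.draw_species_params <- function(config, covs) {
  spp <- .sim_species(config)
  n <- nrow(spp)
  occ <- config$occ
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  u <- occ$mu_u + occ$sigma_u * z1
  v <- occ$mu_v + occ$sigma_v * (occ$rho_uv * z1 +
                                   sqrt(1 - occ$rho_uv^2) * z2)
  beta <- occ$beta_mean[spp$assemblage, , drop = FALSE] +
    matrix(stats::rnorm(n * 4, 0, occ$beta_sd), n, 4)
  betap <- occ$betap_mean[spp$assemblage, , drop = FALSE] +
    matrix(stats::rnorm(n * 4, 0, occ$betap_sd), n, 4)
  rownames(beta) <- rownames(betap) <- spp$species
  list(species = spp, u = u, v = v, beta = beta, betap = betap)
}

#' Simulate community detection histories
#'
#' Draws species-level occupancy/detection parameters from the
#' assemblage-structured community distributions, occupancy states z per
#' point-year from psi, and per-visit binary detections from p among occupied
#' point-years.
#'
#' @param config A [sim_config()].
#' @param covariates Standardized covariate table (columns area,
#'   edge_density, willow_height, willow_density), one row per point.
#' @return A `detection_array` (species x point x year x visit); attribute
#'   `truth` holds all latent quantities (species parameters, psi, p, z).
#' @export
simulate_community <- function(config, covariates) {
  cn <- c("area", "edge_density", "willow_height", "willow_density")
  missing <- setdiff(cn, names(covariates))
  if (length(missing))
    stop("format error: missing covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  des <- config$design
  L <- sum(des$points_per_region)
  if (nrow(covariates) != L)
    stop("covariate table has ", nrow(covariates), " rows; design has ", L,
         " points", call. = FALSE)
  X <- as.matrix(covariates[, cn])
  J <- length(des$years); K <- des$visits_per_year
  set.seed(sub_seed(config$seed, 2))
  par <- .draw_species_params(config, cn)
  n <- nrow(par$species)
  psi <- stats::plogis(par$u + par$beta %*% t(X))     # n x L
  p <- stats::plogis(par$v + par$betap %*% t(X))      # n x L
  z <- array(stats::rbinom(n * L * J, 1, rep(psi, J)), dim = c(n, L, J))
  x <- array(0L, dim = c(n, L, J, K),
             dimnames = list(species = par$species$species,
                             point = point_ids(des),
                             year = as.character(des$years),
                             visit = as.character(seq_len(K))))
  pz <- rep(as.vector(z) * rep(as.vector(p), J), K)
  x[] <- stats::rbinom(n * L * J * K, 1, pz)
  class(x) <- c("detection_array", class(x))
  attr(x, "truth") <- list(params = par, psi = psi, p = p, z = z)
  x
}

#' Simulate repeated counts (N-mixture generative model)
#'
#' Per species, latent abundance N at each point-year is Poisson with a
#' log-linear covariate model; visit counts are Binomial(N, p_year) with a
#' detection probability per study year.
#'
#' @inheritParams simulate_community
#' @return A `count_array`; attribute `truth` holds species parameters,
#'   lambda, the per-year detection probabilities and the latent N.
#' @export
simulate_counts <- function(config, covariates) {
  cn <- c("area", "edge_density", "willow_height", "willow_density")
  missing <- setdiff(cn, names(covariates))
  if (length(missing))
    stop("format error: missing covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  des <- config$design
  L <- sum(des$points_per_region)
  if (nrow(covariates) != L)
    stop("covariate table has ", nrow(covariates), " rows; design has ", L,
         " points", call. = FALSE)
  X <- as.matrix(covariates[, cn])
  J <- length(des$years); K <- des$visits_per_year
  set.seed(sub_seed(config$seed, 3))
  spp <- .sim_species(config)
  n <- nrow(spp)
  ab <- config$abund
  loglam0 <- stats::rnorm(n, ab$mu_loglam, ab$sigma_loglam)
  beta <- ab$beta_mean[spp$assemblage, , drop = FALSE] +
    matrix(stats::rnorm(n * 4, 0, ab$beta_sd), n, 4)
  p_year <- stats::plogis(stats::rnorm(J, ab$p_year_logit_mean,
                                       ab$p_year_logit_sd))
  lam <- exp(loglam0 + beta %*% t(X))                 # n x L
  N <- array(stats::rpois(n * L * J, rep(lam, J)), dim = c(n, L, J))
  y <- array(0L, dim = c(n, L, J, K),
             dimnames = list(species = spp$species, point = point_ids(des),
                             year = as.character(des$years),
                             visit = as.character(seq_len(K))))
  pj <- rep(rep(p_year, each = n * L), K)
  y[] <- stats::rbinom(n * L * J * K, rep(as.vector(N), K), pj)
  class(y) <- c("count_array", class(y))
  attr(y, "truth") <- list(species = spp, loglam0 = loglam0, beta = beta,
                           p_year = p_year, lambda = lam, N = N)
  y
}

#' Write a complete synthetic fixture directory
#'
#' Generates covariates, per-point landscape rasters (optional), detection
#' histories and counts under the master seed, and writes them as plain-text
#' artifacts (CSV, text grids) plus a JSON truth file and run manifest.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param rasters Also write per-point text rasters (slower; default FALSE).
#' @return Invisibly, the directory path.
#' @export
simulate_fixture <- function(config, dir, rasters = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  covs <- simulate_covariates(config)
  write_covariates(covs, file.path(dir, "covariates.csv"))
  std <- standardize_covariates(covs)
  x <- simulate_community(config, std)
  y <- simulate_counts(config, std)
  write_counts(y, file.path(dir, "counts.csv"), keep_zeros = FALSE)
  dn <- dimnames(x)
  dx <- expand.grid(species = dn$species, point = dn$point, year = dn$year,
                    visit = dn$visit, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  dx$detected <- as.vector(x)
  utils::write.csv(dx[dx$detected > 0, ], file.path(dir, "detections.csv"),
                   row.names = FALSE)
  if (rasters) {
    for (i in seq_len(sum(config$design$points_per_region))) {
      m <- simulate_landscape(config, i)
      write_mask_text(m, file.path(dir, sprintf("mask_%s.txt",
                                                point_ids(config$design)[i])))
    }
  }
  tr_comm <- attr(x, "truth"); tr_cnt <- attr(y, "truth")
  truth <- list(
    occupancy = list(u = tr_comm$params$u, v = tr_comm$params$v,
                     beta = tr_comm$params$beta,
                     betap = tr_comm$params$betap),
    abundance = list(loglam0 = tr_cnt$loglam0, beta = tr_cnt$beta,
                     p_year = tr_cnt$p_year))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  manifest <- list(seed = config$seed,
                   design = unclass(config$design),
                   assemblage_sizes = as.list(config$assemblage_sizes),
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("thicketbirds")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
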