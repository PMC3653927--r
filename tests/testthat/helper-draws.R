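# forge a minimal occ_draws object with known species parameters, so the
# derived-quantity code paths can be tested deterministically
make_fake_draws <- function(u, beta, w = NULL, X = NULL, ndraw = 12,
                            n_obs = NULL, years = "2005") {
  M <- length(u)
  C <- ncol(beta)
  if (is.null(w)) w <- rep(1L, M)
  if (is.null(X)) X <- matrix(0, 2, C)
  cn <- paste0("c", seq_len(C))
  if (!is.null(colnames(beta))) cn <- colnames(beta)
  colnames(X) <- cn
  mk <- function() {
    hy <- matrix(0, ndraw, 5 + 4 * C + 2)
    colnames(hy) <- c("mu_u", "sigma_u", "mu_v", "sigma_v", "rho_uv",
                      paste0("mu_beta_", cn), paste0("sigma_beta_", cn),
                      paste0("mu_betap_", cn), paste0("sigma_betap_", cn),
                      "Omega", "Ntot")
    hy[, "Ntot"] <- sum(w)
    list(u = matrix(rep(u, each = ndraw), ndraw, M),
         v = matrix(0, ndraw, M),
         beta = matrix(rep(as.vector(beta), each = ndraw), ndraw, M * C),
         betap = matrix(0, ndraw, M * C),
         w = matrix(rep(w, each = ndraw), ndraw, M),
         hypers = hy, n_keep = ndraw)
  }
  chains <- list(mk(), mk())
  d <- structure(list(
    chains = chains,
    species = sprintf("sp%02d", seq_len(M)),
    n_obs = if (is.null(n_obs)) M else n_obs,
    M = M, n_points = nrow(X), n_years = length(years), n_visits = 3,
    covariate_names = cn, X = X, center = NULL, scale = NULL,
    point_ids = sprintf("P%02d", seq_len(nrow(X))), years = years,
    spec = community_spec(seed = 1)
  ), class = "occ_draws")
  d$rhat <- gelman_rubin(lapply(chains, `[[`, "hypers"))
  d
}
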