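#' Fixed-effects (inverse-variance) pooling of species effects
#'
#' Pools per-species effect estimates for one covariate into an
#' assemblage-level estimate with weights `w_i = 1/se_i^2`:
#' pooled estimate `sum(w * theta) / sum(w)`, pooled SE `1/sqrt(sum(w))`,
#' normal 95% CI `estimate +/- 1.96 * se`.
#'
#' @param estimate Numeric vector of effect sizes (log or logit scale).
#' @param se Positive standard errors, same length.
#' @return List of class `pooled_effect`: `estimate`, `se`, `ci95`, `k`,
#'   `method = "fixed"`, `Q` (heterogeneity statistic) and `significant`
#'   (CI excludes 0).
#' @export
#' @examples
#' pool_fixed(c(0.2, 0.4), c(0.1, 0.1))  # estimate 0.3, se 0.1/sqrt(2)
pool_fixed <- function(estimate, se) {
  if (length(estimate) != length(se) || length(estimate) < 1)
    stop("estimate and se must be equal-length, nonempty", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("validation error: all se must be positive", call. = FALSE)
  w <- 1 / se^2
  est <- sum(w * estimate) / sum(w)
  pse <- 1 / sqrt(sum(w))
  Q <- sum(w * (estimate - est)^2)
  ci <- est + c(-1.96, 1.96) * pse
  structure(list(estimate = est, se = pse, ci95 = ci, k = length(estimate),
                 method = "fixed", tau2 = 0, Q = Q,
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "pooled_effect")
}

#' Random-effects (DerSimonian-Laird) pooling
#'
#' Robustness variant of [pool_fixed()] accounting for between-species
#' heterogeneity. The DerSimonian-Laird moment estimator is
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with `Q` the
#' fixed-effects heterogeneity statistic; pooling then uses weights
#' `1/(se^2 + tau2)`.
#'
#' @inheritParams pool_fixed
#' @return List of class `pooled_effect` with `method = "random"` and the
#'   `tau2` estimate.
#' @export
pool_random <- function(estimate, se) {
  if (length(estimate) < 2)
    stop("random-effects pooling needs k >= 2 (tau2 undefined)", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("validation error: all se must be positive", call. = FALSE)
  fx <- pool_fixed(estimate, se)
  w <- 1 / se^2
  k <- length(estimate)
  tau2 <- max(0, (fx$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  est <- sum(wr * estimate) / sum(wr)
  pse <- 1 / sqrt(sum(wr))
  ci <- est + c(-1.96, 1.96) * pse
  structure(list(estimate = est, se = pse, ci95 = ci, k = k,
                 method = "random", tau2 = tau2, Q = fx$Q,
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("%s-effects pooled estimate: %.4f (se %.4f), 95%% CI [%.4f, %.4f], k = %d%s%s\n",
              x$method, x$estimate, x$se, x$ci95[1], x$ci95[2], x$k,
              if (x$method == "random") sprintf(", tau2 = %.4f", x$tau2) else "",
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Assemblage-level pooled effect table
#'
#' Pools a species x covariate effect table (columns `species`, `assemblage`,
#' `covariate`, `estimate`, `se`) into one row per assemblage-group x
#' covariate — the layout of an assemblage response table, with willow
#' dependent species (WCB & WGB) pooled together and open-tundra species (OT)
#' separately by default.
#'
#' @param effects Data frame of species-level effects.
#' @param groups Named list mapping output group labels to assemblage codes.
#' @param method "fixed" or "random".
#' @return Data frame (group, covariate, estimate, se, q2.5, q97.5, k,
#'   significant).
#' @export
pool_by_assemblage <- function(effects,
                               groups = list(`WCB&WGB` = c("WCB", "WGB"),
                                             OT = "OT"),
                               method = c("fixed", "random")) {
  method <- match.arg(method)
  need <- c("species", "assemblage", "covariate", "estimate", "se")
  missing <- setdiff(need, names(effects))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pooler <- if (method == "fixed") pool_fixed else pool_random
  res <- list()
  for (g in names(groups)) {
    sub <- effects[effects$assemblage %in% groups[[g]], ]
    for (cv in unique(sub$covariate)) {
      e <- sub[sub$covariate == cv, ]
      p <- pooler(e$estimate, e$se)
      res[[length(res) + 1]] <- data.frame(
        group = g, covariate = cv, estimate = p$estimate, se = p$se,
        q2.5 = p$ci95[1], q97.5 = p$ci95[2], k = p$k,
        significant = p$significant)
    }
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
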