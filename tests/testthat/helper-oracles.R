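# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# flood-fill labeling (8-connectivity) + exhaustive pairwise-distance merge
oracle_label <- function(grid, pixel_size, merge_gap) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (grid[r, cc] == 1 && lab[r, cc] == 0) {
      cur <- cur + 1L
      queue <- list(c(r, cc)); lab[r, cc] <- cur
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- q[1] + dr; c2 <- q[2] + dc
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              grid[r2, c2] == 1 && lab[r2, c2] == 0) {
            lab[r2, c2] <- cur
            queue <- c(queue, list(c(r2, c2)))
          }
        }
      }
    }
  }
  if (cur > 1 && merge_gap > 0) {
    # explicit pairwise pixel-centre distances between every component pair
    pix <- which(lab > 0, arr.ind = TRUE)
    comp <- lab[lab > 0]
    adj <- diag(cur) == 1
    for (a in seq_len(cur - 1)) for (b in (a + 1):cur) {
      pa <- pix[comp == a, , drop = FALSE]
      pb <- pix[comp == b, , drop = FALSE]
      d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
      if (min(d2) * pixel_size^2 <= merge_gap^2 + 1e-12)
        adj[a, b] <- adj[b, a] <- TRUE
    }
    # transitive closure -> merged groups
    repeat {
      adj2 <- (adj %*% adj) > 0
      if (identical(adj2, adj)) break
      adj <- adj2
    }
    group <- integer(cur)
    g <- 0L
    for (a in seq_len(cur)) if (group[a] == 0) {
      g <- g + 1L
      group[which(adj[a, ])] <- g
    }
    lab[lab > 0] <- group[lab[lab > 0]]
    # relabel by row-major first pixel (scan rows, then columns)
    relab <- integer(max(lab))
    nxt <- 0L
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      v <- lab[r, cc]
      if (v > 0 && relab[v] == 0) { nxt <- nxt + 1L; relab[v] <- nxt }
    }
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

# exhaustive enumeration of interior pixel boundaries
oracle_edge <- function(grid, pixel_size) {
  nr <- nrow(grid); nc <- ncol(grid)
  n <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (cc < nc && grid[r, cc] != grid[r, cc + 1]) n <- n + 1L
    if (r < nr && grid[r, cc] != grid[r + 1, cc]) n <- n + 1L
  }
  n * pixel_size
}

# two-term enumeration over the latent occupancy state z
oracle_marginal <- function(x, psi, p) {
  pr_z1 <- psi * prod(ifelse(x == 1, p, 1 - p))
  pr_z0 <- (1 - psi) * as.numeric(all(x == 0))
  log(pr_z1 + pr_z0)
}

# exhaustive N-mixture likelihood with explicit factorials (valid for K <= 30)
oracle_nmix_unit <- function(y, lambda, p, K) {
  total <- 0
  for (N in 0:K) {
    pois <- exp(-lambda) * lambda^N / factorial(N)
    bin <- prod(choose(N, y) * p^y * (1 - p)^(N - y))
    if (any(y > N)) bin <- 0
    total <- total + pois * bin
  }
  log(total)
}

random_mask <- function(nr = 50, nc = 50, p = 0.2, pixel_size = 0.2) {
  willow_mask(matrix(rbinom(nr * nc, 1, p), nr, nc), pixel_size = pixel_size)
}

# minimal single-unit nmix_data constructor for likelihood tests
tiny_nmix_data <- function(y, X = NULL, year = NULL) {
  y <- matrix(y, nrow = if (is.matrix(y)) nrow(y) else 1)
  S <- nrow(y)
  if (is.null(X)) X <- matrix(1, S, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(year)) year <- factor(rep("y1", S))
  structure(list(y = y, X = X, year = year,
                 unit = as.character(seq_len(S)), species = "test",
                 covariate_names = setdiff(colnames(X), "(Intercept)")),
            class = "nmix_data")
}

table1_path <- function() {
  system.file("extdata", "species_table1.csv", package = "thicketbirds")
}
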