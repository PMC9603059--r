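# Shared fixtures and independent geometric oracles, all built in code.

# 7-cell "flower": one centre hexagon with its 6 neighbours, width 2.
flower_grid <- function(width = 2) {
  region <- generate_region(rings = 1, width = width)
  filter_cells(build_hex_grid(region, width = width), min_fraction = 0.8)
}

# Brute-force O(K^2) shared-edge adjacency: two cells are neighbours iff
# their hexagon polygons share a segment of positive length (matching
# vertex pairs up to tolerance). Independent of the lattice bookkeeping.
brute_force_adjacency <- function(grid) {
  verts <- hex_vertices(grid)
  R <- attr(grid, "circumradius")
  K <- nrow(grid)
  W <- matrix(0L, K, K, dimnames = list(grid$cell_id, grid$cell_id))
  vkey <- lapply(verts, function(v) round(v / R, 6))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      shared <- 0L
      for (a in seq_len(6)) {
        d <- abs(sweep(vkey[[j]], 2, vkey[[i]][a, ]))
        if (any(rowSums(d) < 1e-4)) shared <- shared + 1L
      }
      if (shared >= 2) {  # two shared vertices = a shared edge
        W[i, j] <- W[j, i] <- 1L
      }
    }
  }
  W
}

# Brute-force Moran's I (double loop over all pairs).
brute_force_morans_i <- function(x, W) {
  K <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (k in seq_len(K)) for (j in seq_len(K)) num <- num + W[k, j] * xc[k] * xc[j]
  (K / sum(W)) * num / sum(xc^2)
}

# Random connected-ish symmetric binary adjacency on K nodes.
random_adjacency <- function(K, p = 0.4) {
  W <- matrix(0L, K, K)
  W[upper.tri(W)] <- rbinom(K * (K - 1) / 2, 1, p)
  W <- W + t(W)
  # ensure no isolated node (give it one neighbour)
  for (k in which(rowSums(W) == 0)) {
    j <- if (k == 1) 2 else k - 1
    W[k, j] <- W[j, k] <- 1L
  }
  W
}

# Minimal hand-built panel: arbitrary design matrix and adjacency, used for
# model-level tests that do not need the full coding pipeline.
make_panel <- function(Y, X, W) {
  K <- nrow(Y); N <- ncol(Y)
  storage.mode(Y) <- "integer"
  structure(list(
    Y = Y, X = X, offset = matrix(0, K, N),
    cells = seq_len(K), quarters = seq_len(N),
    columns = tibble::tibble(name = colnames(X),
                             role = NA_character_,
                             parents = vector("list", ncol(X))),
    W = W
  ), class = "hex_panel")
}

# K-node path graph adjacency.
path_adjacency <- function(K) {
  W <- matrix(0L, K, K)
  for (k in seq_len(K - 1)) W[k, k + 1] <- W[k + 1, k] <- 1L
  W
}

# Simulate a compact Poisson CAR-AR panel (intercept + covariates) directly
# from the model equations; independent of generate_panel's full coding.
simulate_compact_panel <- function(K_W, N, beta, rho_s, rho_t, tau2,
                                   X = NULL) {
  W <- K_W; K <- nrow(W)
  p <- length(beta)
  if (is.null(X)) {
    X <- matrix(1, K * N, 1)
    if (p > 1) X <- cbind(X, matrix(rnorm(K * N * (p - 1)), K * N, p - 1))
    colnames(X) <- c("(Intercept)",
                     if (p > 1) paste0("x", seq_len(p - 1)))
  }
  Q <- leroux_precision(W, rho_s)
  U <- chol(Q)
  phi <- matrix(0, K, N)
  phi[, 1] <- sqrt(tau2) * backsolve(U, rnorm(K))
  if (N > 1) for (t in 2:N) {
    phi[, t] <- rho_t * phi[, t - 1] + sqrt(tau2) * backsolve(U, rnorm(K))
  }
  eta <- matrix(X %*% beta, K, N) + phi
  Y <- matrix(rpois(K * N, exp(eta)), K, N)
  list(panel = make_panel(Y, X, W), phi = phi)
}

# Gaussian log density with generic linear algebra (independent oracle).
ref_dmvnorm_log <- function(x, mean, sigma) {
  K <- length(x)
  ev <- eigen(sigma, symmetric = TRUE)
  ld <- sum(log(ev$values))
  xc <- x - mean
  quad <- drop(t(xc) %*% ev$vectors %*% diag(1 / ev$values, K) %*%
                 t(ev$vectors) %*% xc)
  -0.5 * (K * log(2 * pi) + ld + quad)
}
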