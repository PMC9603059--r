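test_that("Leroux precision has its limiting and algebraic properties", {
  W <- attr(flower_grid(), "W")
  K <- nrow(W)
  expect_equal(unname(leroux_precision(W, 0)), diag(K))
  for (rho in c(0.2, 0.5, 0.9, 0.99)) {
    Q <- leroux_precision(W, rho)
    expect_true(isSymmetric(Q))
    expect_true(all(eigen(Q, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  # Q 1 = (1 - rho) 1 on a regular graph (row degree constant): here a cycle
  Wc <- matrix(0L, 6, 6)
  for (k in 1:6) {
    Wc[k, k %% 6 + 1] <- 1L
    Wc[k %% 6 + 1, k] <- 1L
  }
  for (rho in c(0.3, 0.8)) {
    expect_equal(drop(leroux_precision(Wc, rho) %*% rep(1, 6)),
                 rep(1 - rho, 6), tolerance = 1e-12)
  }
})

test_that("log joint matches closed forms and a term-by-term oracle", {
  # K = 1 hexagon would have an empty W; use the smallest instance with
  # closed-form terms: Y = 0, beta = 0, phi = 0 gives Poisson term -1 per obs
  W2 <- rbind(c(0L, 1L), c(1L, 0L))
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  panel <- make_panel(matrix(0L, 2, 1), X, W2)
  cfg <- car_config()
  lj <- log_joint(panel, beta = 0, phi = matrix(0, 2, 1), tau2 = 0.5,
                  rho_s = 0.4, rho_t = 0.3, config = cfg)
  # Poisson contribution is exactly -1 per observation here
  pois <- -2
  Q <- leroux_precision(W2, 0.4)
  prior_phi <- ref_dmvnorm_log(c(0, 0), c(0, 0), 0.5 * solve(Q))
  prior_beta <- dnorm(0, 0, sqrt(1e5), log = TRUE)
  prior_tau2 <- log(0.01) - lgamma(1) - 2 * log(0.5) - 0.01 / 0.5
  expect_equal(lj, pois + prior_phi + prior_beta + prior_tau2,
               tolerance = 1e-10)

  # K = 3, N = 2: brute-force term-by-term evaluation
  set.seed(21)
  W3 <- path_adjacency(3)
  X3 <- cbind(1, rnorm(6)); colnames(X3) <- c("(Intercept)", "x1")
  Y3 <- matrix(rpois(6, 2), 3, 2)
  panel3 <- make_panel(Y3, X3, W3)
  beta <- c(0.3, -0.2); phi <- matrix(rnorm(6, sd = 0.4), 3, 2)
  tau2 <- 0.7; rho_s <- 0.6; rho_t <- 0.5
  lj3 <- log_joint(panel3, beta, phi, tau2, rho_s, rho_t, cfg)
  eta <- matrix(X3 %*% beta, 3, 2) + phi
  oracle <- sum(dpois(Y3, exp(eta), log = TRUE))
  Q3 <- leroux_precision(W3, rho_s)
  oracle <- oracle + ref_dmvnorm_log(phi[, 1], rep(0, 3), tau2 * solve(Q3))
  oracle <- oracle + ref_dmvnorm_log(phi[, 2], rho_t * phi[, 1],
                                     tau2 * solve(Q3))
  oracle <- oracle + sum(dnorm(beta, 0, sqrt(1e5), log = TRUE))
  oracle <- oracle + (cfg$a * log(cfg$b) - lgamma(cfg$a) -
                        (cfg$a + 1) * log(tau2) - cfg$b / tau2)
  expect_equal(lj3, oracle, tolerance = 1e-8)

  expect_error(log_joint(panel3, c(NA, 1), phi, tau2, rho_s, rho_t, cfg),
               "finite")
})

test_that("tau2 full conditional is the documented inverse gamma", {
  W <- attr(flower_grid(), "W")
  K <- nrow(W); N <- 3
  # phi = 0: the quadratic form vanishes, draw is IG(a + KN/2, b)
  d0 <- sample_tau2(matrix(0, K, N), 0.5, 0.5, W, a = 2, b = 1, n = 1)
  expect_equal(attr(d0, "shape"), 2 + K * N / 2)
  expect_equal(attr(d0, "rate"), 1)

  set.seed(31)
  phi <- matrix(rnorm(K * N, sd = 0.6), K, N)
  # rho_t = 0 specialisation: quad reduces to sum_t phi_t' Q phi_t
  Q <- leroux_precision(W, 0.7)
  quad_direct <- sum(vapply(1:N, function(t) {
    drop(t(phi[, t]) %*% Q %*% phi[, t])
  }, numeric(1)))
  d1 <- sample_tau2(phi, 0.7, 0, W, a = 1, b = 0.01)
  expect_equal(attr(d1, "rate"), 0.01 + quad_direct / 2, tolerance = 1e-12)

  # conjugacy: log-joint differences in tau2 equal IG density differences
  X <- matrix(1, K * N, 1, dimnames = list(NULL, "(Intercept)"))
  panel <- make_panel(matrix(rpois(K * N, 2), K, N), X, W)
  d2 <- sample_tau2(phi, 0.4, 0.6, W, a = 1, b = 0.01)
  sh <- attr(d2, "shape"); rt <- attr(d2, "rate")
  dig <- function(x) sh * log(rt) - lgamma(sh) - (sh + 1) * log(x) - rt / x
  for (pair in list(c(0.2, 0.9), c(0.5, 1.7))) {
    dlj <- log_joint(panel, 0, phi, pair[1], 0.4, 0.6) -
      log_joint(panel, 0, phi, pair[2], 0.4, 0.6)
    expect_equal(dlj, dig(pair[1]) - dig(pair[2]), tolerance = 1e-8)
  }

  # moments of repeated draws match the closed form
  set.seed(32)
  draws <- sample_tau2(phi, 0.4, 0.6, W, a = 1, b = 0.01, n = 20000)
  m_true <- rt / (sh - 1)
  expect_lt(abs(mean(draws) - m_true) / m_true, 0.03)
})

test_that("fixed seeds give bit-identical chains and distinct sub-seeds", {
  set.seed(41)
  sim <- simulate_compact_panel(path_adjacency(4), 3, c(0.2, 0.1),
                                0.5, 0.5, 0.2)
  cfg <- car_config(n_chains = 2, n_iter = 400, burn_in = 100, thin = 2,
                    seed = 9)
  f1 <- suppressWarnings(fit_car_ar(sim$panel, cfg))
  f2 <- suppressWarnings(fit_car_ar(sim$panel, cfg))
  expect_identical(f1$chains[[1]]$beta, f2$chains[[1]]$beta)
  expect_identical(f1$chains[[1]]$tau2, f2$chains[[1]]$tau2)
  expect_false(identical(f1$chains[[1]]$beta, f1$chains[[2]]$beta))
  # retained count per chain
  expect_equal(nrow(f1$chains[[1]]$beta), floor((400 - 100) / 2))
  expect_true(all(unlist(lapply(f1$chains, `[[`, "tau2")) > 0))
  rhos <- unlist(lapply(f1$chains, `[[`, "rho_s"))
  expect_true(all(rhos >= 0 & rhos <= 1))
})

test_that("prior-only sampling recovers the prior distributions", {
  set.seed(51)
  W <- attr(flower_grid(), "W")
  K <- nrow(W); N <- 2
  X <- matrix(1, K * N, 1, dimnames = list(NULL, "(Intercept)"))
  panel <- make_panel(matrix(0L, K, N), X, W)
  cfg <- car_config(n_chains = 1, n_iter = 30000, burn_in = 2000, thin = 5,
                    seed = 3, a = 3, b = 2, likelihood = FALSE,
                    update = list(beta = FALSE))
  fit <- suppressWarnings(fit_car_ar(panel, cfg))
  ch <- fit$chains[[1]]
  # rho_s, rho_t ~ U(0,1): mean 1/2, var 1/12
  for (r in list(ch$rho_s, ch$rho_t)) {
    expect_lt(abs(mean(r) - 0.5), 0.05)
    expect_lt(abs(var(r) - 1 / 12), 0.02)
  }
  # tau2 ~ IG(3, 2): mean b/(a-1) = 1, var b^2/((a-1)^2 (a-2)) = 1
  expect_lt(abs(mean(ch$tau2) - 1), 0.15)
})

test_that("with the latent field disabled the fit matches the Poisson GLM", {
  set.seed(61)
  sim <- simulate_compact_panel(path_adjacency(8), 10,
                                c(0.5, 0.3, -0.2), 0, 0, 1e-12)
  cfg <- car_config(n_chains = 1, n_iter = 6000, burn_in = 1000, thin = 1,
                    seed = 5)
  fit <- fit_car_ar(sim$panel, cfg, latent = FALSE)
  draws <- combine_chains(fit)
  mle <- coef(glm(as.vector(sim$panel$Y) ~ sim$panel$X - 1,
                  family = poisson()))
  post_mean <- colMeans(draws)
  mcse <- apply(draws, 2, function(v) {
    m <- 50
    bm <- colMeans(matrix(v[seq_len((length(v) %/% m) * m)], nrow = m))
    sd(bm) / sqrt(length(bm))
  })
  expect_true(all(abs(post_mean - mle) < 4 * pmax(mcse, 0.005)))
})

test_that("gelman_rubin behaves at its limits", {
  set.seed(71)
  sim <- simulate_compact_panel(path_adjacency(4), 3, c(0.2), 0.5, 0.5, 0.2)
  cfg <- car_config(n_chains = 2, n_iter = 300, burn_in = 100, thin = 1,
                    seed = 11)
  fit <- suppressWarnings(fit_car_ar(sim$panel, cfg))
  # exact copies -> PSRF = 1
  fit_same <- fit
  fit_same$chains[[2]] <- fit_same$chains[[1]]
  expect_equal(gelman_rubin(fit_same, "(Intercept)"), 1, tolerance = 1e-12)
  # disjoint supports -> PSRF >> 1
  fit_apart <- fit
  fit_apart$chains[[2]]$beta <- fit_apart$chains[[2]]$beta + 100
  expect_gt(gelman_rubin(fit_apart, "(Intercept)"), 10)
  fit1 <- fit
  fit1$chains <- fit1$chains[1]
  expect_error(gelman_rubin(fit1, "(Intercept)"), "2 chains")
  # well-mixed long run stays near 1
  cfg2 <- car_config(n_chains = 2, n_iter = 4000, burn_in = 1000, thin = 2,
                     seed = 13)
  fit2 <- suppressWarnings(fit_car_ar(sim$panel, cfg2))
  expect_lt(gelman_rubin(fit2, "(Intercept)"), 1.1)
})

test_that("tidy and glance summarise a fit", {
  set.seed(81)
  sim <- simulate_compact_panel(path_adjacency(5), 4, c(0.4, 0.2), 0.5, 0.5,
                                0.2)
  cfg <- car_config(n_chains = 2, n_iter = 800, burn_in = 200, thin = 2,
                    seed = 15)
  fit <- suppressWarnings(fit_car_ar(sim$panel, cfg))
  td <- tidy(fit)
  expect_equal(td$term,
               c("(Intercept)", "x1", "tau2", "rho_s", "rho_t"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_retained, 2 * 300)
  expect_s3_class(autoplot(fit), "ggplot")
})
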