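# Bayesian Poisson spatio-temporal model:
#   Y[k,t] ~ Poisson(mu[k,t]),  log mu[k,t] = x[k,t]' beta + O[k,t] + phi[k,t]
# with a Leroux CAR spatial precision and AR(1) temporal evolution of the
# latent field phi, fitted by Metropolis-within-Gibbs MCMC (C++ core).

#' Model configuration: priors and chain settings
#'
#' @param n_chains Number of independent chains (default 3). Chain `i` is
#'   seeded with `seed + (i - 1) * 1e6`.
#' @param n_iter Iterations per chain.
#' @param burn_in Discarded initial iterations (must be `< n_iter`).
#'   Proposal-scale adaptation happens during burn-in only and is frozen
#'   afterwards so the retained chain satisfies detailed balance.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer base seed; fixed-seed runs are bit-identical.
#' @param mu_beta,sigma2_beta Normal prior mean and (diagonal) variance for
#'   the regression coefficients; scalars are recycled over columns. The
#'   default variance 1e5 is effectively flat.
#' @param a,b Inverse-gamma shape and scale for the latent-field conditional
#'   variance `tau2` (defaults 1 and 0.01).
#' @param center_phi If `TRUE`, re-centre the latent field to mean zero
#'   within each quarter after every sweep (an identifiability device useful
#'   when the spatial dependence is close to intrinsic). Default `FALSE`:
#'   the Leroux prior is proper for `rho_s < 1`, so the exact posterior is
#'   well defined and is what the sampler targets.
#' @param keep_phi Store latent-field draws (memory-heavy); otherwise only
#'   the posterior mean of `phi` is kept.
#' @param likelihood If `FALSE` the Poisson likelihood is switched off and
#'   the sampler explores the joint prior — used to verify that prior-only
#'   sampling recovers the prior distributions.
#' @param init Optional named list of initial values (`beta`, `phi`, `tau2`,
#'   `rho_s`, `rho_t`).
#' @param update Optional named list of logicals switching individual update
#'   blocks on/off (`beta`, `phi`, `tau2`, `rho_s`, `rho_t`); a switched-off
#'   block keeps its initial value fixed.
#' @return A `car_config` list.
#' @export
car_config <- function(n_chains = 3, n_iter = 42000, burn_in = 2000,
                       thin = 10, seed = 1,
                       mu_beta = 0, sigma2_beta = 1e5,
                       a = 1, b = 0.01,
                       center_phi = FALSE, keep_phi = FALSE,
                       likelihood = TRUE, init = list(), update = list()) {
  stopifnot(n_iter > 0, burn_in >= 0, burn_in < n_iter, thin >= 1,
            n_chains >= 1, all(sigma2_beta > 0), a > 0, b > 0)
  structure(list(
    n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
    burn_in = as.integer(burn_in), thin = as.integer(thin),
    seed = as.integer(seed), mu_beta = mu_beta, sigma2_beta = sigma2_beta,
    a = a, b = b, center_phi = isTRUE(center_phi),
    keep_phi = isTRUE(keep_phi), likelihood = isTRUE(likelihood),
    init = init, update = update
  ), class = "car_config")
}

#' Leroux conditional-autoregressive precision matrix
#'
#' `Q(W, rho) = rho * (diag(W 1) - W) + (1 - rho) * I`, interpolating
#' between independence (`rho = 0`, where `Q = I`) and the intrinsic CAR
#' (`rho = 1`). Symmetric and positive definite for `rho` in `[0, 1)`.
#'
#' @param W Binary symmetric adjacency matrix.
#' @param rho Spatial dependence parameter in `[0, 1]`.
#' @return The K x K precision matrix.
#' @export
leroux_precision <- function(W, rho) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), rho >= 0, rho <= 1)
  rho * (diag(rowSums(W)) - W) + (1 - rho) * diag(nrow(W))
}

#' Log joint density of the model
#'
#' Sum of the Poisson log-likelihood, the Gaussian log-densities of the
#' latent AR(1)-CAR field, and the log-priors of `beta`, `tau2`, `rho_s`,
#' `rho_t`. Used as an independent check of the sampler's kernels.
#'
#' @param panel A [hex_panel][build_design_matrix] with adjacency `W`.
#' @param beta Coefficient vector (length `ncol(panel$X)`).
#' @param phi Latent field, K x N matrix.
#' @param tau2 Latent conditional variance (> 0).
#' @param rho_s,rho_t Spatial and temporal dependence in `[0, 1)`.
#' @param config A [car_config()] providing the prior hyperparameters.
#' @return A finite scalar log density.
#' @export
log_joint <- function(panel, beta, phi, tau2, rho_s, rho_t,
                      config = car_config()) {
  stopifnot(inherits(panel, "hex_panel"), tau2 > 0,
            rho_s >= 0, rho_s < 1, rho_t >= 0, rho_t < 1)
  K <- nrow(panel$Y); N <- ncol(panel$Y)
  if (!all(is.finite(beta)) || !all(is.finite(phi))) {
    abort("Non-finite parameter values.")
  }
  eta <- matrix(panel$X %*% beta, K, N) + panel$offset + phi
  ll_pois <- sum(panel$Y * eta - exp(eta) - lfactorial(panel$Y))

  W <- panel$W
  if (is.null(W)) abort("Panel has no adjacency matrix `W`.")
  Q <- leroux_precision(W, rho_s)
  ld <- as.numeric(determinant(Q, logarithm = TRUE)$modulus)
  quad <- drop(t(phi[, 1]) %*% Q %*% phi[, 1])
  if (N > 1) {
    for (t in 2:N) {
      e <- phi[, t] - rho_t * phi[, t - 1]
      quad <- quad + drop(t(e) %*% Q %*% e)
    }
  }
  ll_phi <- N * (-K / 2 * log(2 * pi * tau2) + ld / 2) - quad / (2 * tau2)

  p <- length(beta)
  mu_b <- rep_len(config$mu_beta, p)
  s2_b <- rep_len(config$sigma2_beta, p)
  lp_beta <- sum(-0.5 * log(2 * pi * s2_b) - (beta - mu_b)^2 / (2 * s2_b))
  lp_tau2 <- config$a * log(config$b) - lgamma(config$a) -
    (config$a + 1) * log(tau2) - config$b / tau2
  # rho_s, rho_t ~ Uniform(0,1): log density 0
  ll_pois + ll_phi + lp_beta + lp_tau2
}

#' Conjugate Gibbs draw for the latent-field variance
#'
#' Given the latent field and dependence parameters, `tau2` has an
#' inverse-gamma full conditional `IG(a + KN/2, b + quad/2)` where `quad` is
#' the AR(1)-CAR quadratic form
#' `phi_1' Q phi_1 + sum_t (phi_t - rho_t phi_{t-1})' Q (phi_t - rho_t phi_{t-1})`.
#'
#' @param phi K x N latent field matrix.
#' @param rho_s,rho_t Dependence parameters.
#' @param W Adjacency matrix.
#' @param a,b Inverse-gamma prior shape and scale.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws. The attribute `"shape"`/`"rate"`
#'   record the full-conditional parameters.
#' @export
sample_tau2 <- function(phi, rho_s, rho_t, W, a = 1, b = 0.01, n = 1) {
  phi <- as.matrix(phi)
  K <- nrow(phi); N <- ncol(phi)
  Q <- leroux_precision(W, rho_s)
  quad <- drop(t(phi[, 1]) %*% Q %*% phi[, 1])
  if (N > 1) {
    for (t in 2:N) {
      e <- phi[, t] - rho_t * phi[, t - 1]
      quad <- quad + drop(t(e) %*% Q %*% e)
    }
  }
  shape <- a + K * N / 2
  rate <- b + quad / 2
  out <- 1 / rgamma(n, shape = shape, rate = rate)
  attr(out, "shape") <- shape
  attr(out, "rate") <- rate
  out
}

#' Fit the Poisson CAR-AR model by MCMC
#'
#' Runs `config$n_chains` independent Metropolis-within-Gibbs chains:
#' componentwise adaptive random-walk Metropolis for `beta`, single-site
#' Metropolis for the latent field using the Gaussian full-conditional
#' structure, a conjugate inverse-gamma Gibbs step for `tau2`, and
#' logit-scale random-walk Metropolis with Jacobian correction for `rho_s`
#' and `rho_t`. Adaptation is restricted to burn-in. Identical seeds give
#' bit-identical chains.
#'
#' @param panel A [hex_panel][build_design_matrix]; must carry the adjacency
#'   matrix `W` (attach via `build_design_matrix(..., W = )`).
#' @param config A [car_config()].
#' @param latent If `FALSE` the latent field is disabled (held at zero, no
#'   `tau2`/`rho` updates), reducing the model to a Bayesian Poisson GLM.
#' @return A `carar_fit`: list with per-chain retained draws (`beta`,
#'   `tau2`, `rho_s`, `rho_t`, posterior-mean `phi`), acceptance rates,
#'   the config, and the panel's column metadata.
#' @export
fit_car_ar <- function(panel, config = car_config(), latent = TRUE) {
  stopifnot(inherits(panel, "hex_panel"), inherits(config, "car_config"))
  W <- panel$W
  if (is.null(W)) abort("Panel has no adjacency matrix `W`.")
  K <- nrow(panel$Y); N <- ncol(panel$Y); p <- ncol(panel$X)
  if (nrow(W) != K) abort("Adjacency dimension does not match cell count.")
  if (anyNA(panel$Y) || anyNA(panel$X)) abort("Panel has missing values.")

  nbr <- lapply(seq_len(K), function(k) which(W[k, ] != 0))
  lap_eig <- eigen(diag(rowSums(W)) - W, symmetric = TRUE,
                   only.values = TRUE)$values

  upd <- utils::modifyList(
    list(beta = TRUE, phi = latent, tau2 = latent,
         rho_s = latent, rho_t = latent),
    config$update)
  init <- config$init
  beta0 <- init$beta %||% init_beta_glm(panel)
  phi0 <- init$phi %||% matrix(0, K, N)
  tau20 <- init$tau2 %||% 0.1
  rhoS0 <- init$rho_s %||% 0.5
  rhoT0 <- init$rho_t %||% 0.5

  chains <- vector("list", config$n_chains)
  for (i in seq_len(config$n_chains)) {
    set.seed(config$seed + (i - 1L) * 1000000L)
    res <- carar_chain(
      panel$Y, panel$X, panel$offset, nbr, lap_eig,
      as.numeric(rep_len(beta0, p)), phi0, tau20, rhoS0, rhoT0,
      rep_len(config$mu_beta, p), rep_len(config$sigma2_beta, p),
      config$a, config$b,
      config$n_iter, config$burn_in, config$thin,
      upd$beta, upd$phi, upd$tau2, upd$rho_s, upd$rho_t,
      config$center_phi, config$keep_phi, config$likelihood,
      intercept_column(panel$X))
    colnames(res$beta) <- colnames(panel$X)
    chains[[i]] <- res
    rates <- unlist(res$accept)
    rates <- rates[is.finite(rates)]
    if (length(rates) && (any(rates < 0.1) || any(rates > 0.6))) {
      warn(sprintf(
        "Chain %d: acceptance rate(s) outside [0.1, 0.6] after adaptation: %s",
        i, paste(sprintf("%s=%.2f", names(rates), rates), collapse = ", ")))
    }
  }
  structure(list(
    chains = chains, config = config, latent = latent,
    columns = panel$columns, cells = panel$cells, quarters = panel$quarters,
    W = W
  ), class = "carar_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based index of an all-ones intercept column (enables the joint
# beta0/phi translation move), or -1 when absent
intercept_column <- function(X) {
  j <- which(colnames(X) == "(Intercept)")
  if (length(j) == 1 && all(X[, j] == 1)) j - 1L else -1L
}

init_beta_glm <- function(panel) {
  y <- as.vector(panel$Y)
  fit <- suppressWarnings(
    glm.fit(panel$X, y, family = poisson(), offset = as.vector(panel$offset)))
  b <- coef(fit)
  b[!is.finite(b)] <- 0
  unname(b)
}

#' Potential scale reduction factor (Gelman-Rubin diagnostic)
#'
#' Between/within-chain variance ratio for one scalar parameter; values
#' near 1 indicate the chains have mixed.
#'
#' @param fit A `carar_fit` with at least 2 chains.
#' @param parameter Parameter name: a design-column name (or `"beta[j]"`),
#'   `"tau2"`, `"rho_s"`, or `"rho_t"`.
#' @return Scalar PSRF (>= 1 up to Monte-Carlo noise).
#' @export
gelman_rubin <- function(fit, parameter) {
  stopifnot(inherits(fit, "carar_fit"))
  if (length(fit$chains) < 2) abort("Gelman-Rubin needs at least 2 chains.")
  draws <- lapply(fit$chains, extract_param, parameter = parameter)
  n <- unique(vapply(draws, length, integer(1)))
  if (length(n) != 1 || n < 10) abort("Need >= 10 retained draws per chain.")
  m <- length(draws)
  means <- vapply(draws, mean, numeric(1))
  vars <- vapply(draws, var, numeric(1))
  Wv <- mean(vars)
  B_over_n <- var(means)
  var_plus <- (n - 1) / n * Wv + B_over_n
  # clamped at 1: the (n-1)/n deflation can push the raw ratio just below 1
  max(1, sqrt(var_plus / Wv))
}

extract_param <- function(chain, parameter) {
  if (parameter %in% c("tau2", "rho_s", "rho_t")) return(chain[[parameter]])
  nm <- colnames(chain$beta)
  if (parameter %in% nm) return(chain$beta[, parameter])
  j <- suppressWarnings(as.integer(sub("^beta\\[(\\d+)\\]$", "\\1", parameter)))
  if (!is.na(j) && j >= 1 && j <= ncol(chain$beta)) return(chain$beta[, j])
  abort(paste0("Unknown parameter: ", parameter))
}

#' @export
print.carar_fit <- function(x, ...) {
  m <- nrow(x$chains[[1]]$beta)
  cat("<carar_fit> ", length(x$chains), " chain(s) x ", m,
      " retained draws, ", ncol(x$chains[[1]]$beta), " coefficients",
      if (x$latent) ", CAR-AR latent field" else ", latent field disabled",
      "\n", sep = "")
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `carar_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, posterior `estimate`
#'   (median), `conf.low`/`conf.high` (central 95% credible interval), and
#'   `rhat` when multiple chains are available.
#' @export
tidy.carar_fit <- function(x, ...) {
  params <- c(colnames(x$chains[[1]]$beta),
              if (x$latent) c("tau2", "rho_s", "rho_t"))
  rows <- lapply(params, function(pp) {
    pooled <- unlist(lapply(x$chains, extract_param, parameter = pp))
    qs <- quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(term = pp, estimate = qs[2], conf.low = qs[1],
                   conf.high = qs[3],
                   rhat = if (length(x$chains) >= 2) gelman_rubin(x, pp) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted model
#'
#' @param x A `carar_fit`.
#' @param ... Unused.
#' @return Tibble with chain bookkeeping, worst-case `rhat`, and mean
#'   acceptance rates.
#' @export
glance.carar_fit <- function(x, ...) {
  td <- tidy(x)
  acc <- colMeans(do.call(rbind, lapply(x$chains, function(ch) {
    v <- unlist(ch$accept)
    v[!is.finite(v)] <- NA
    v
  })), na.rm = TRUE)
  tibble::tibble(
    n_chains = length(x$chains),
    n_retained = sum(vapply(x$chains, function(ch) nrow(ch$beta), integer(1))),
    n_iter = x$config$n_iter, burn_in = x$config$burn_in,
    thin = x$config$thin,
    max_rhat = suppressWarnings(max(td$rhat, na.rm = TRUE)),
    accept_beta = unname(acc["beta"]),
    accept_phi = unname(acc["phi"])
  )
}

#' Trace plots for a fitted model
#'
#' @param object A `carar_fit`.
#' @param parameters Parameters to plot (default: first coefficient plus
#'   `tau2`, `rho_s`, `rho_t` when the latent field is on).
#' @param ... Unused.
#' @return A ggplot object (facetted trace plot, one colour per chain).
#' @export
autoplot.carar_fit <- function(object, parameters = NULL, ...) {
  if (is.null(parameters)) {
    parameters <- c(colnames(object$chains[[1]]$beta)[1],
                    if (object$latent) c("tau2", "rho_s", "rho_t"))
  }
  df <- purrr::map_dfr(seq_along(object$chains), function(i) {
    purrr::map_dfr(parameters, function(pp) {
      v <- extract_param(object$chains[[i]], pp)
      tibble::tibble(chain = factor(i), parameter = pp,
                     iteration = seq_along(v), value = v)
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL) +
    ggplot2::theme_minimal()
}
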