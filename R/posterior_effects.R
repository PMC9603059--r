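# Posterior relative-risk contrasts: pool chains, form linear combinations
# of the regression coefficients, exponentiate quantiles.

#' Pool retained MCMC draws across chains
#'
#' Applies a burn-in/thinning retention pass to each chain and stacks the
#' retained draws chain-major (all of chain 1, then chain 2, ...). For a
#' fitted model the stored draws are already post-burn-in and thinned, so
#' the defaults pool them as-is; raw per-chain draw matrices can be pooled
#' with explicit `burn_in` and `thin`.
#'
#' @param chains A `carar_fit`, or a list of numeric matrices (iterations x
#'   parameters) sharing their column dimension.
#' @param burn_in Number of leading iterations to drop from each chain.
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @param parameter For a `carar_fit`: which parameter block to pool
#'   (`"beta"`, `"tau2"`, `"rho_s"`, `"rho_t"`).
#' @return A matrix of pooled draws with
#'   `n_chains * floor((n_iter - burn_in) / thin)` rows (possibly 0).
#' @examples
#' chains <- list(matrix(rnorm(1005), ncol = 1), matrix(rnorm(1005), ncol = 1))
#' nrow(combine_chains(chains, burn_in = 5, thin = 10))  # 200
#' @export
combine_chains <- function(chains, burn_in = 0, thin = 1, parameter = "beta") {
  if (inherits(chains, "carar_fit")) {
    chains <- lapply(chains$chains, function(ch) {
      v <- extract_param_matrix(ch, parameter)
      v
    })
  }
  stopifnot(is.list(chains), length(chains) >= 1, thin >= 1, burn_in >= 0)
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1) else as.matrix(ch)
  })
  pdim <- unique(vapply(chains, ncol, integer(1)))
  if (length(pdim) != 1) abort("Chains disagree on parameter dimension.")
  kept <- lapply(chains, function(ch) {
    n <- nrow(ch)
    if (n < burn_in + thin) return(ch[0, , drop = FALSE])
    idx <- seq.int(burn_in + thin, n, by = thin)
    ch[idx, , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  attr(out, "n_per_chain") <- vapply(kept, nrow, integer(1))
  out
}

extract_param_matrix <- function(chain, parameter) {
  if (parameter == "beta") chain$beta else matrix(chain[[parameter]], ncol = 1)
}

#' Posterior relative risk for a linear contrast of coefficients
#'
#' Computes `s_i = c' beta_i` for every pooled draw and returns the
#' exponential of the 2.5%, 50%, and 97.5% empirical quantiles of `{s_i}`
#' (quantiles by linear interpolation of order statistics; exponentiating
#' quantiles equals taking quantiles of the exponentials by monotonicity).
#'
#' @param draws Pooled coefficient draw matrix (>= 100 rows), columns named
#'   by design column.
#' @param contrast Numeric contrast: either a full-length vector over the
#'   columns of `draws`, or a named vector whose names are design columns
#'   (all other weights zero).
#' @param name Label for the contrast.
#' @return One-row tibble: `name`, `rr` (posterior median relative risk),
#'   `lower`, `upper` (95% credible interval), `significant` (interval
#'   excludes 1).
#' @export
relative_risk <- function(draws, contrast, name = "contrast") {
  draws <- as.matrix(draws)
  if (nrow(draws) < 100) {
    abort("Need at least 100 pooled draws for a stable 2.5% quantile.")
  }
  if (!is.null(names(contrast)) && length(contrast) != ncol(draws)) {
    full <- setNames(numeric(ncol(draws)), colnames(draws))
    bad <- setdiff(names(contrast), colnames(draws))
    if (length(bad)) abort(paste0("Unknown design column(s): ",
                                  paste(bad, collapse = ", ")))
    full[names(contrast)] <- contrast
    contrast <- full
  }
  if (length(contrast) != ncol(draws)) {
    abort("Contrast length does not match the number of coefficients.")
  }
  if (!all(is.finite(contrast))) abort("Contrast weights must be finite.")
  s <- drop(draws %*% contrast)
  qs <- quantile(s, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  tibble::tibble(name = name, rr = exp(qs[2]), lower = exp(qs[1]),
                 upper = exp(qs[3]),
                 significant = exp(qs[1]) > 1 | exp(qs[3]) < 1)
}

#' Dose- and stratum-specific relative-risk table
#'
#' Emits the standard table layout: for each demolition dose level (low,
#' med, high; reference = zero demolitions within the stratum) by vacancy
#' stratum (low, medium, high), and for the rehabilitation indicator within
#' each vacancy stratum, the posterior median relative risk and 95%
#' credible interval. With reference-cell coding each contrast is the unit
#' vector on the corresponding interaction column, because the stratum main
#' effects cancel in the within-stratum comparison; the contrast is built
#' from the column metadata so an equivalent alternative coding yields the
#' same risks.
#'
#' @param fit A `carar_fit`, or a pooled coefficient draw matrix.
#' @param columns Column metadata (needed only when `fit` is a matrix).
#' @param outcome Outcome label carried into the table.
#' @return An `rr_table` tibble: `outcome`, `exposure`, `dose`, `vacancy`,
#'   `rr`, `lower`, `upper`, `significant` — 9 demolition rows then 3
#'   rehabilitation rows.
#' @export
rr_table <- function(fit, columns = NULL, outcome = "crime") {
  if (inherits(fit, "carar_fit")) {
    draws <- combine_chains(fit)
    columns <- fit$columns
  } else {
    draws <- as.matrix(fit)
    if (is.null(columns)) {
      columns <- tibble::tibble(name = colnames(draws),
                                role = NA_character_, parents = list(NULL))
    }
  }
  vac_levels <- c("low", "medium", "high")
  demo_levels <- c("low", "med", "high")
  rows <- list()
  for (dl in demo_levels) for (vl in vac_levels) {
    col <- paste0("demo_", dl, ":vac_", vl)
    if (!col %in% columns$name) abort(paste0("Missing design column: ", col))
    res <- relative_risk(draws, setNames(1, col), name = col)
    rows[[length(rows) + 1]] <- tibble::tibble(
      outcome = outcome, exposure = "demolition", dose = dl, vacancy = vl,
      rr = res$rr, lower = res$lower, upper = res$upper,
      significant = res$significant)
  }
  for (vl in vac_levels) {
    col <- paste0("rehab:vac_", vl)
    if (!col %in% columns$name) abort(paste0("Missing design column: ", col))
    res <- relative_risk(draws, setNames(1, col), name = col)
    rows[[length(rows) + 1]] <- tibble::tibble(
      outcome = outcome, exposure = "rehabilitation", dose = "present",
      vacancy = vl, rr = res$rr, lower = res$lower, upper = res$upper,
      significant = res$significant)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rr_table", class(out))
  out
}

#' Forest plot of a relative-risk table
#'
#' @param object An `rr_table`.
#' @param ... Unused.
#' @return A ggplot object: point = posterior median RR, bar = 95% credible
#'   interval, facetted by vacancy stratum, reference line at RR = 1.
#' @export
autoplot.rr_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      label = paste(.data$exposure, .data$dose),
                      vacancy = factor(.data$vacancy,
                                       c("low", "medium", "high")))
  ggplot2::ggplot(df, ggplot2::aes(.data$rr, .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper,
                                          colour = .data$significant)) +
    ggplot2::facet_wrap(~vacancy, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative risk (95% credible interval)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a relative-risk table as CSV and JSON
#'
#' @param x An `rr_table`.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_rr_table <- function(x, stem) {
  utils::write.csv(x, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(x, paste0(stem, ".json"), digits = NA)
  invisible(stem)
}
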