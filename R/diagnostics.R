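# Spatial autocorrelation testing and event-window descriptive trends.

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (K / S0) * sum_kj w_kj (x_k - xbar)(x_j - xbar) / sum_k (x_k -
#' xbar)^2` with `S0 = sum_kj w_kj`.
#'
#' @param values Numeric vector over the K cells (non-constant).
#' @param W Symmetric binary adjacency matrix.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(values, W) {
  K <- length(values)
  stopifnot(is.matrix(W), nrow(W) == K, ncol(W) == K)
  x <- values - mean(values)
  den <- sum(x^2)
  if (den == 0) abort("Moran's I is undefined for constant values.")
  s0 <- sum(W)
  (K / s0) * drop(t(x) %*% W %*% x) / den
}

#' Permutation test for positive spatial autocorrelation
#'
#' Permutes the cell labels of `values` uniformly at random `n_perm` times
#' and compares the observed Moran's I with the permutation distribution.
#' The p-value uses the add-one correction
#' `p = (1 + #permutations with I >= I_obs) / (1 + n_perm)`, so the minimum
#' attainable p is `1 / (1 + n_perm)`. One-sided (upper tail) by default,
#' matching a test for positive autocorrelation; `"two.sided"` doubles the
#' smaller tail around the permutation null expectation `-1 / (K - 1)`.
#'
#' @param values Numeric vector over cells.
#' @param W Adjacency matrix.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Optional integer seed; the test is deterministic given it.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `moran_test`: list with `I`, `n_perm`, `p_value`, `seed`,
#'   `alternative`.
#' @export
morans_i_permutation_test <- function(values, W, n_perm = 9999, seed = NULL,
                                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) abort("Use at least 99 permutations.")
  i_obs <- morans_i(values, W)
  if (!is.null(seed)) set.seed(seed)
  i_perm <- vapply(seq_len(n_perm),
                   function(i) morans_i(sample(values), W), numeric(1))
  if (alternative == "greater") {
    p <- (1 + sum(i_perm >= i_obs)) / (1 + n_perm)
  } else {
    e0 <- -1 / (length(values) - 1)
    p <- (1 + sum(abs(i_perm - e0) >= abs(i_obs - e0))) / (1 + n_perm)
  }
  structure(list(I = i_obs, n_perm = as.integer(n_perm), p_value = p,
                 seed = seed, alternative = alternative),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat("Moran's I permutation test (", x$alternative, ")\n",
      "I = ", format(x$I, digits = 4), ", n_perm = ", x$n_perm,
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.moran_test <- function(x, ...) {
  tibble::tibble(statistic = x$I, p.value = x$p_value, n_perm = x$n_perm,
                 alternative = x$alternative)
}

#' Mean outcome counts in event-aligned windows
#'
#' For every treated cell-quarter (treatment count >= 1), aligns the
#' outcome series at relative quarters `-window .. +window` around the
#' event and averages within dose group (the group is the categorised
#' treatment count at the event quarter). Windows crossing the panel
#' boundary are dropped (complete-window rule); a cell treated in several
#' quarters contributes one window per event. With
#' `include_untreated = TRUE` an `"untreated"` comparison series is added,
#' built from all complete windows around untreated cell-quarters.
#'
#' @param outcome Tibble `cell_id`, `quarter`, `y` (outcome counts).
#' @param treatment Tibble `cell_id`, `quarter`, `count` (treatment counts).
#' @param categorize Function mapping counts to group labels
#'   (default [categorize_demolition()]); for a presence/absence treatment
#'   use [rehab_indicator()] or supply labels directly.
#' @param window Half-width of the window in quarters (default 3).
#' @param include_untreated Add the untreated comparison series.
#' @return An `event_window` tibble: `group`, `rel_quarter`, `mean_count`,
#'   `n_windows`. Empty (with a warning) when there are no treated events.
#' @export
event_window_means <- function(outcome, treatment,
                               categorize = categorize_demolition,
                               window = 3, include_untreated = FALSE) {
  quarters <- sort(unique(outcome$quarter))
  if (length(quarters) < 2 * window + 1) {
    abort("Panel must span at least 2*window + 1 quarters.")
  }
  ymat <- outcome |>
    dplyr::arrange(.data$cell_id, .data$quarter)
  ywide <- tidyr::pivot_wider(ymat, names_from = "quarter", values_from = "y")
  cells <- ywide$cell_id
  Y <- as.matrix(ywide[, -1])

  collect <- function(events, label_fun) {
    rows <- list()
    for (i in seq_len(nrow(events))) {
      tq <- match(events$quarter[i], quarters)
      kk <- match(events$cell_id[i], cells)
      if (is.na(tq) || is.na(kk)) next
      if (tq - window < 1 || tq + window > length(quarters)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = label_fun(events$count[i]),
        rel_quarter = -window:window,
        count = as.numeric(Y[kk, (tq - window):(tq + window)]))
    }
    dplyr::bind_rows(rows)
  }

  treated <- dplyr::filter(treatment, .data$count >= 1)
  if (nrow(treated) == 0) {
    warn("No treated cell-quarters; returning an empty series.")
    out <- tibble::tibble(group = character(0), rel_quarter = integer(0),
                          mean_count = numeric(0), n_windows = integer(0))
    class(out) <- c("event_window", class(out))
    return(out)
  }
  empty_series <- function() {
    out <- tibble::tibble(group = character(0), rel_quarter = integer(0),
                          mean_count = numeric(0), n_windows = integer(0))
    class(out) <- c("event_window", class(out))
    out
  }
  long <- collect(treated, function(cnt) as.character(categorize(cnt)))
  if (nrow(long) == 0 && !include_untreated) {
    warn("All event windows cross the panel boundary; returning an empty series.")
    return(empty_series())
  }
  if (include_untreated) {
    untreated <- dplyr::filter(treatment, .data$count == 0)
    long <- dplyr::bind_rows(long,
                             collect(untreated, function(cnt) "untreated"))
    if (nrow(long) == 0) {
      warn("All event windows cross the panel boundary; returning an empty series.")
      return(empty_series())
    }
  }
  out <- long |>
    dplyr::group_by(.data$group, .data$rel_quarter) |>
    dplyr::summarise(mean_count = mean(.data$count),
                     n_windows = dplyr::n(), .groups = "drop")
  class(out) <- c("event_window", class(out))
  out
}

#' Plot event-window mean series
#'
#' @param object An `event_window` tibble.
#' @param ... Unused.
#' @return A ggplot object: one line per group, vertical reference at the
#'   event quarter.
#' @export
autoplot.event_window <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rel_quarter, .data$mean_count,
                                       colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "quarters relative to event", y = "mean count",
                  colour = "group") +
    ggplot2::theme_minimal()
}
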