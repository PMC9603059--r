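# Synthetic study generator: region, grid, exposures, covariates, and
# outcomes drawn from the exact Poisson CAR-AR model with known parameters,
# so every pipeline stage can be validated against ground truth.

#' Ground-truth parameters for the synthetic generator
#'
#' Defaults emulate the marginal features of a mid-sized post-industrial
#' city panel: demolition counts are zero-inflated and right-skewed
#' (roughly a quarter of cell-quarters treated, treated mean near 2,
#' occasional double-digit counts), rehabilitation is a sparse indicator
#' (marginal probability 0.069), vacancy counts span all three strata with
#' per-cell persistence, and covariates come in correlated blocks so the
#' first principal component of each block is meaningful by construction.
#'
#' @param rho_s,rho_t,tau2 Latent-field truth: spatial and temporal
#'   dependence and conditional variance.
#' @param beta Named numeric vector of non-zero true coefficients over
#'   design-column names; unnamed columns default to 0 and the entries
#'   below default as documented. The default injects an elevated risk for
#'   high demolition dose in high-vacancy cells (log 1.5) and for
#'   rehabilitation in medium-vacancy cells (log 1.3), with all other dose
#'   effects null.
#' @param demolition List: zero-inflation weight `pi0`, negative-binomial
#'   `mu` and `size` for the non-inflated component.
#' @param vacancy List: negative-binomial `mu`, `size`, and shape `cell_shape`
#'   of the per-cell gamma multiplier (persistent spatial heterogeneity).
#' @param rehab_prob Marginal probability of any rehabilitation in a
#'   cell-quarter.
#' @param covariates List: number of variables per block (`property`,
#'   `community`, `crime`) and the intra-block correlation `rho` induced by
#'   a shared latent factor.
#' @return A `truth_params` list.
#' @export
truth_params <- function(rho_s = 0.8, rho_t = 0.7, tau2 = 0.3,
                         beta = NULL,
                         demolition = list(pi0 = 0.45, mu = 0.9, size = 0.7),
                         vacancy = list(mu = 5, size = 1, cell_shape = 2),
                         rehab_prob = 0.069,
                         covariates = list(property = 8, community = 6,
                                           crime = 4, rho = 0.7)) {
  stopifnot(rho_s >= 0, rho_s < 1, rho_t >= 0, rho_t < 1, tau2 > 0,
            rehab_prob >= 0, rehab_prob <= 1)
  base_beta <- c(
    "(Intercept)" = 0.5,
    "demo_high:vac_high" = log(1.5),
    "rehab:vac_medium" = log(1.3),
    "vac_medium" = 0.3, "vac_high" = 0.5,
    "pc_property" = 0.10, "pc_community" = 0.10, "pc_crime" = 0.05,
    "qtr_2" = 0.10, "qtr_3" = 0.15, "qtr_4" = 0.05
  )
  if (!is.null(beta)) {
    if (is.null(names(beta))) abort("`beta` overrides must be named.")
    base_beta[names(beta)] <- beta
  }
  structure(list(rho_s = rho_s, rho_t = rho_t, tau2 = tau2,
                 beta = base_beta, demolition = demolition,
                 vacancy = vacancy, rehab_prob = rehab_prob,
                 covariates = covariates),
            class = "truth_params")
}

#' Generate a study region as a disc of hexagonal rings
#'
#' The region polygon is the exact union of a hexagonal lattice disc with
#' the given number of rings around a central cell, so tessellating it
#' reproduces `1 + 3 * rings * (rings + 1)` cells with
#' `fraction_inside = 1`. The region carries its generating-lattice anchor
#' so [build_hex_grid()] reproduces the generating cells exactly.
#' Optionally the polygon is clipped by the half-plane `x <= clip_x`, which
#' creates boundary-crossing cells and exercises the area-fraction
#' inclusion rule.
#'
#' @param rings Number of rings (>= 1); 1 gives 7 cells, 4 gives 61.
#' @param width Cell corner-to-corner width in region units.
#' @param clip_x Optional x-limit clipping the region.
#' @param unit Linear unit label.
#' @return A [hex_region()].
#' @export
generate_region <- function(rings, width = 2000, clip_x = NULL,
                            unit = "feet") {
  stopifnot(rings >= 1)
  R <- width / 2
  ax <- hex_disc_axial(rings)
  centers <- hex_center(ax[, 1], ax[, 2], R, c(0, 0))
  outline <- hex_union_outline(centers, R)
  if (!is.null(clip_x)) {
    bb_y <- range(outline[, 2]); bb_x <- range(outline[, 1])
    rect <- cbind(c(bb_x[1] - R, clip_x, clip_x, bb_x[1] - R),
                  c(bb_y[1] - R, bb_y[1] - R, bb_y[2] + R, bb_y[2] + R))
    outline <- clip_polygon_convex(outline, rect)
  }
  region <- hex_region(outline, unit = unit)
  attr(region, "origin") <- c(0, 0)
  attr(region, "lattice_width") <- width
  region
}

hex_disc_axial <- function(rings) {
  qq <- rr <- integer(0)
  for (q in -rings:rings) {
    for (r in max(-rings, -q - rings):min(rings, -q + rings)) {
      qq <- c(qq, q); rr <- c(rr, r)
    }
  }
  cbind(q = qq, r = rr)
}

# Exact union outline of a set of equal hexagons: collect all edges, cancel
# edges shared by two hexagons, chain the boundary edges into a ring.
hex_union_outline <- function(centers, R) {
  ang <- pi / 3 * (0:5)
  key <- function(x, y) paste(round(x / R, 6), round(y / R, 6))
  edges <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(centers))) {
    vx <- centers[i, 1] + R * cos(ang)
    vy <- centers[i, 2] + R * sin(ang)
    for (e in 1:6) {
      j <- if (e == 6) 1 else e + 1
      k1 <- key(vx[e], vy[e]); k2 <- key(vx[j], vy[j])
      ek <- paste(sort(c(k1, k2)), collapse = "|")
      cur <- edges[[ek]]
      if (is.null(cur)) {
        edges[[ek]] <- list(n = 1L, a = c(vx[e], vy[e]), b = c(vx[j], vy[j]),
                            ka = k1, kb = k2)
      } else {
        cur$n <- cur$n + 1L
        edges[[ek]] <- cur
      }
    }
  }
  boundary <- Filter(function(e) e$n == 1L,
                     mget(ls(edges), envir = edges))
  # chain edges: map from start-key to edge (boundary of a union of equal
  # hexagons has exactly one outgoing edge per vertex)
  nxt <- new.env(parent = emptyenv())
  for (e in boundary) nxt[[e$ka]] <- e
  start <- boundary[[1]]
  ring <- list(start$a)
  cur <- start
  repeat {
    nk <- cur$kb
    if (identical(nk, start$ka)) break
    cur <- nxt[[nk]]
    ring[[length(ring) + 1]] <- cur$a
  }
  do.call(rbind, ring)
}

#' Generate exposure event counts per cell-quarter
#'
#' Demolition counts follow a zero-inflated negative binomial;
#' rehabilitation is a sparse indicator-plus-small-count process; vacancy
#' counts are negative binomial with a persistent per-cell multiplier.
#' Quarters run from `1 - lead_in` to `n_quarters` so that one-quarter
#' lagging and 8 quarters of remediation history are available for every
#' modeled quarter.
#'
#' @param grid A [hex_grid][build_hex_grid].
#' @param n_quarters Number of modeled quarters.
#' @param truth A [truth_params()].
#' @param lead_in Lead-in quarters before quarter 1 (default 8).
#' @return Tibble `cell_id`, `quarter`, `demolitions`, `rehabs`,
#'   `vacancies`.
#' @export
generate_exposures <- function(grid, n_quarters, truth = truth_params(),
                               lead_in = 8) {
  cells <- grid$cell_id
  quarters <- seq(1 - lead_in, n_quarters)
  n <- length(cells) * length(quarters)
  dm <- truth$demolition
  demolitions <- ifelse(runif(n) < dm$pi0, 0L,
                        rnbinom(n, size = dm$size, mu = dm$mu))
  rehab_on <- rbinom(n, 1, truth$rehab_prob)
  rehabs <- rehab_on * (1L + rpois(n, 0.15))
  vc <- truth$vacancy
  cell_mult <- rgamma(length(cells), shape = vc$cell_shape,
                      rate = vc$cell_shape)
  mult <- rep(cell_mult, times = length(quarters))
  vacancies <- rnbinom(n, size = vc$size, mu = vc$mu * mult)
  tibble::tibble(
    cell_id = rep(cells, times = length(quarters)),
    quarter = rep(quarters, each = length(cells)),
    demolitions = as.integer(demolitions),
    rehabs = as.integer(rehabs),
    vacancies = as.integer(vacancies)
  )
}

#' Generate correlated covariate blocks
#'
#' Each block (property, community, crime) shares a latent standard-normal
#' factor per cell-quarter; variable `j` in a block is
#' `sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving intra-block
#' correlation `rho`.
#'
#' @inheritParams generate_exposures
#' @return Tibble `cell_id`, `quarter`, and columns
#'   `<block>_<j>`.
#' @export
generate_covariates <- function(grid, n_quarters, truth = truth_params()) {
  cells <- grid$cell_id
  quarters <- seq(0, n_quarters - 1)  # used lagged: quarter t-1 for model t
  n <- length(cells) * length(quarters)
  cv <- truth$covariates
  out <- tibble::tibble(
    cell_id = rep(cells, times = length(quarters)),
    quarter = rep(quarters, each = length(cells))
  )
  for (block in c("property", "community", "crime")) {
    nv <- cv[[block]]
    f <- rnorm(n)
    for (j in seq_len(nv)) {
      out[[paste0(block, "_", j)]] <-
        sqrt(cv$rho) * f + sqrt(1 - cv$rho) * rnorm(n)
    }
  }
  out
}

#' Simulate the latent AR(1)-CAR field
#'
#' `phi_1 ~ N(0, tau2 Q^-1)` and `phi_t | phi_{t-1} ~ N(rho_t phi_{t-1},
#' tau2 Q^-1)` with the Leroux precision `Q(W, rho_s)`, drawn via the
#' Cholesky factor of `Q`.
#'
#' @param W Adjacency matrix.
#' @param n_quarters Number of time points.
#' @param truth A [truth_params()].
#' @return K x N matrix.
#' @export
generate_latent_field <- function(W, n_quarters, truth = truth_params()) {
  K <- nrow(W)
  Q <- leroux_precision(W, truth$rho_s)
  U <- chol(Q)
  s <- sqrt(truth$tau2)
  phi <- matrix(0, K, n_quarters)
  phi[, 1] <- s * backsolve(U, rnorm(K))
  if (n_quarters > 1) {
    for (t in 2:n_quarters) {
      phi[, t] <- truth$rho_t * phi[, t - 1] + s * backsolve(U, rnorm(K))
    }
  }
  phi
}

#' Generate a complete synthetic hexagon-quarter panel
#'
#' Runs the full data-preparation pipeline on generated exposures and
#' covariates — ordinal dose coding, one-quarter lagging, history windows,
#' per-block first principal components, seasonal indicators — then draws
#' the latent field and outcome counts from the Poisson CAR-AR model with
#' the true parameters.
#'
#' @param grid A filtered [hex_grid][build_hex_grid] with adjacency.
#' @param n_quarters Number of modeled quarters (default 24).
#' @param truth A [truth_params()].
#' @return List: `panel` (a `hex_panel` with `W` attached), `phi` (true
#'   latent field), `beta` (true coefficient vector aligned to the design
#'   columns), `truth`, `exposures`, `coded` (the coded cell-quarter
#'   table).
#' @export
generate_panel <- function(grid, n_quarters = 24, truth = truth_params()) {
  W <- attr(grid, "W")
  if (is.null(W)) W <- adjacency_matrix(grid)
  exposures <- generate_exposures(grid, n_quarters, truth)
  covars <- generate_covariates(grid, n_quarters, truth)

  hist <- history_covariates(exposures, start_quarter = 1)
  lagged <- exposures |>
    dplyr::mutate(quarter = .data$quarter + 1L) |>
    dplyr::filter(.data$quarter >= 1, .data$quarter <= n_quarters) |>
    dplyr::transmute(.data$cell_id, .data$quarter,
                     demo_level = categorize_demolition(.data$demolitions),
                     vacancy_stratum = categorize_vacancy(.data$vacancies),
                     rehab = rehab_indicator(.data$rehabs))

  pcs <- lapply(c("property", "community", "crime"), function(block) {
    vars <- grep(paste0("^", block, "_"), names(covars), value = TRUE)
    pca_first_component(covars[vars], group = block)
  })
  pc_tbl <- covars |>
    dplyr::select("cell_id", "quarter") |>
    dplyr::mutate(quarter = .data$quarter + 1L)  # lag: scores at t from t-1
  for (pc in pcs) pc_tbl[[paste0("pc_", pc$group)]] <- pc$scores

  coded <- lagged |>
    dplyr::inner_join(hist, by = c("cell_id", "quarter")) |>
    dplyr::inner_join(pc_tbl, by = c("cell_id", "quarter")) |>
    dplyr::mutate(y = 0L)
  panel <- build_design_matrix(coded, W = W)

  beta <- setNames(numeric(ncol(panel$X)), colnames(panel$X))
  known <- intersect(names(truth$beta), names(beta))
  beta[known] <- truth$beta[known]

  phi <- generate_latent_field(W, n_quarters, truth)
  eta <- matrix(panel$X %*% beta, nrow(panel$Y), ncol(panel$Y)) +
    panel$offset + phi
  if (any(eta > 30)) {
    abort("Linear predictor exceeds 30 (expected counts overflow); use smaller coefficients.")
  }
  y <- rpois(length(eta), exp(eta))
  panel$Y <- matrix(as.integer(y), nrow(panel$Y), ncol(panel$Y),
                    dimnames = dimnames(panel$Y))

  list(panel = panel, phi = phi, beta = beta, truth = truth,
       exposures = exposures, coded = coded)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: region (disc of `rings` rings, optionally clipped),
#' grid at the 0.8 area-fraction threshold, and a full panel.
#'
#' @param rings Rings in the region disc (default 4: 61 cells).
#' @param n_quarters Modeled quarters (default 24).
#' @param truth A [truth_params()].
#' @param width Hexagon corner-to-corner width.
#' @param seed Optional seed set before generation.
#' @return List as [generate_panel()], plus `region` and `grid`.
#' @export
simulate_study <- function(rings = 4, n_quarters = 24,
                           truth = truth_params(), width = 2000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region <- generate_region(rings, width = width)
  grid <- build_hex_grid(region, width = width)
  grid <- filter_cells(grid, min_fraction = 0.8)
  out <- generate_panel(grid, n_quarters, truth)
  out$region <- region
  out$grid <- grid
  out
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the region as GeoJSON, the grid as GeoJSON plus the adjacency
#' triplet file, the exposures as CSV, the panel as tidy CSV with JSON
#' column metadata, and the truth parameters as JSON — exactly the formats
#' the pipeline reads.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  region_path <- file.path(dir, "region.geojson")
  ring <- rbind(study$region$parts[[1]], study$region$parts[[1]][1, ])
  jsonlite::write_json(list(
    type = "Feature", properties = list(unit = study$region$unit),
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(ring)),
                                              function(j) ring[j, ])))),
    region_path, auto_unbox = TRUE, digits = NA)
  write_grid_geojson(study$grid, file.path(dir, "grid.geojson"))
  write_adjacency_triplet(attr(study$grid, "W"), file.path(dir, "adjacency.txt"))
  utils::write.csv(study$exposures, file.path(dir, "exposures.csv"),
                   row.names = FALSE)
  write_panel_csv(study$panel, file.path(dir, "panel"))
  tp <- study$truth
  jsonlite::write_json(list(rho_s = tp$rho_s, rho_t = tp$rho_t,
                            tau2 = tp$tau2, beta = as.list(study$beta),
                            rehab_prob = tp$rehab_prob),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
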