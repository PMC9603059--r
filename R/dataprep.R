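# Panel assembly: point events -> hexagon-quarter counts -> ordinal dose
# coding -> lagged design matrix.

#' Ordinal coding of intervention counts
#'
#' `categorize_demolition()` maps a quarterly demolition count to the ordinal
#' dose scale: 0 is the reference, 1 is low, 2 is medium, and 3 or more is
#' high. `categorize_vacancy()` maps a vacant-property count to the stratum
#' scale low (0-1), medium (2-11), high (12 or more). `rehab_indicator()`
#' collapses a rehabilitation count to presence/absence.
#'
#' @param count Non-negative integer vector.
#' @return `categorize_demolition()`: factor with levels
#'   `ref < low < med < high`; `categorize_vacancy()`: factor with levels
#'   `low < medium < high`; `rehab_indicator()`: integer 0/1.
#' @examples
#' categorize_demolition(c(0, 1, 2, 13))
#' categorize_vacancy(c(1, 2, 11, 12))
#' rehab_indicator(c(0, 6))
#' @export
categorize_demolition <- function(count) {
  check_counts(count)
  factor(ifelse(count == 0, "ref",
         ifelse(count == 1, "low",
         ifelse(count == 2, "med", "high"))),
         levels = c("ref", "low", "med", "high"), ordered = TRUE)
}

#' @rdname categorize_demolition
#' @export
categorize_vacancy <- function(count) {
  check_counts(count)
  factor(ifelse(count <= 1, "low", ifelse(count <= 11, "medium", "high")),
         levels = c("low", "medium", "high"), ordered = TRUE)
}

#' @rdname categorize_demolition
#' @export
rehab_indicator <- function(count) {
  check_counts(count)
  as.integer(count >= 1)
}

check_counts <- function(count) {
  if (any(!is.finite(count)) || any(count < 0) || any(count != floor(count))) {
    abort("Counts must be finite non-negative integers.")
  }
  invisible(count)
}

#' Assign planar points to hexagonal grid cells
#'
#' Each point is assigned to the hexagon containing it, by axial-coordinate
#' rounding followed by a nearest-centre check against the candidate cell
#' and its six lattice neighbours. Points exactly equidistant from two
#' centres (on a shared edge) go to the cell with the smaller `cell_id`;
#' points in cells not present in `grid` get `NA`.
#'
#' @param points Data frame with numeric columns `x`, `y`.
#' @param grid A [hex_grid][build_hex_grid].
#' @return Integer vector of `cell_id`s (NA when no retained cell contains
#'   the point).
#' @export
assign_cells <- function(points, grid) {
  stopifnot(inherits(grid, "hex_grid"))
  R <- attr(grid, "circumradius")
  origin <- attr(grid, "origin")
  key <- paste(grid$q, grid$r)
  n <- nrow(points)
  out <- rep(NA_integer_, n)
  qf <- (points$x - origin[1]) / (1.5 * R)
  rf <- (points$y - origin[2]) / (sqrt(3) * R) - qf / 2
  # cube rounding
  xc <- qf; zc <- rf; yc <- -xc - zc
  rx <- round(xc); ry <- round(yc); rz <- round(zc)
  dx <- abs(rx - xc); dy <- abs(ry - yc); dz <- abs(rz - zc)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  q0 <- rx; r0 <- rz
  cand_off <- rbind(c(0, 0), AXIAL_NEIGHBORS)
  for (i in seq_len(n)) {
    cq <- q0[i] + cand_off[, 1]
    cr <- r0[i] + cand_off[, 2]
    ctr <- hex_center(cq, cr, R, origin)
    d2 <- (ctr[, 1] - points$x[i])^2 + (ctr[, 2] - points$y[i])^2
    # containing lattice cell(s): nearest centre over the full lattice;
    # ties (points on a shared edge) resolved toward the smaller cell_id
    # among retained cells
    tied <- which(d2 <= min(d2) + 1e-9 * R^2)
    hit <- match(paste(cq[tied], cr[tied]), key)
    hit <- hit[!is.na(hit)]
    if (length(hit)) out[i] <- min(grid$cell_id[hit])
  }
  out
}

#' Aggregate point events to hexagon-quarter counts
#'
#' @param events Data frame with columns `x`, `y`, `quarter` (integer), and
#'   `class` (character event class).
#' @param grid A [hex_grid][build_hex_grid].
#' @param quarters Integer vector of quarters the output should cover;
#'   defaults to the full consecutive range observed in `events`.
#' @return A tibble with one row per (cell_id, quarter, class) combination
#'   over all retained cells and requested quarters, column `count`. Events
#'   falling in no retained cell are tallied in the `"unassigned"` attribute
#'   (a tibble by quarter and class) and reported with a warning rather than
#'   silently dropped.
#' @export
aggregate_events <- function(events, grid, quarters = NULL) {
  stopifnot(all(c("x", "y", "quarter", "class") %in% names(events)))
  if (is.null(quarters)) {
    quarters <- if (nrow(events)) seq(min(events$quarter), max(events$quarter)) else integer(0)
  }
  classes <- sort(unique(events$class))
  full <- tidyr::expand_grid(cell_id = grid$cell_id, quarter = quarters,
                             class = classes)
  if (nrow(events) == 0) {
    out <- dplyr::mutate(full, count = 0L)
    attr(out, "unassigned") <- tibble::tibble(quarter = integer(0),
                                              class = character(0),
                                              count = integer(0))
    return(out)
  }
  events <- dplyr::mutate(events, cell_id = assign_cells(events, grid))
  unas <- events |>
    dplyr::filter(is.na(.data$cell_id)) |>
    dplyr::count(.data$quarter, .data$class, name = "count")
  if (nrow(unas) > 0) {
    warn(sprintf("%d event(s) fell outside every retained cell; see attr(x, 'unassigned').",
                 sum(unas$count)))
  }
  counts <- events |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::count(.data$cell_id, .data$quarter, .data$class, name = "count")
  out <- full |>
    dplyr::left_join(counts, by = c("cell_id", "quarter", "class")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  attr(out, "unassigned") <- unas
  out
}

#' Remediation-history covariates
#'
#' For each cell and modeled quarter `t`, computes the sum of demolitions
#' over quarters `t-4 .. t-1` and over `t-8 .. t-5`, and indicators of any
#' rehabilitation in the same two windows. The input series must start at
#' least 8 quarters before the first modeled quarter.
#'
#' @param exposures Tibble with columns `cell_id`, `quarter`, `demolitions`,
#'   `rehabs`, covering consecutive quarters.
#' @param start_quarter First modeled quarter (history is computed for
#'   `start_quarter` onward).
#' @return Tibble `cell_id`, `quarter`, `demo_prev4`, `demo_prev8`,
#'   `rehab_prev4`, `rehab_prev8`.
#' @export
history_covariates <- function(exposures, start_quarter) {
  stopifnot(all(c("cell_id", "quarter", "demolitions", "rehabs") %in%
                  names(exposures)))
  qmin <- min(exposures$quarter)
  if (start_quarter - qmin < 8) {
    abort(sprintf(
      "History covariates need 8 lead-in quarters before quarter %d; series starts at %d (only %d available).",
      start_quarter, qmin, start_quarter - qmin))
  }
  qs <- sort(unique(exposures$quarter))
  if (!identical(qs, seq(min(qs), max(qs)))) {
    abort("`exposures$quarter` must cover consecutive integer quarters.")
  }
  exposures |>
    dplyr::arrange(.data$cell_id, .data$quarter) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      demo_prev4 = slide_sum(.data$demolitions, 1, 4),
      demo_prev8 = slide_sum(.data$demolitions, 5, 8),
      rehab_prev4 = as.integer(slide_sum(.data$rehabs, 1, 4) > 0),
      rehab_prev8 = as.integer(slide_sum(.data$rehabs, 5, 8) > 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$quarter >= start_quarter) |>
    dplyr::select("cell_id", "quarter", "demo_prev4", "demo_prev8",
                  "rehab_prev4", "rehab_prev8")
}

# sum of x over lags `from..to` quarters back (NA when the window is
# incomplete); x ordered by quarter within a cell
slide_sum <- function(x, from, to) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - to >= 1) out[i] <- sum(x[(i - to):(i - from)])
  }
  out
}

#' First principal component of a standardized variable block
#'
#' Performs PCA on the correlation scale (columns centered and scaled to
#' unit variance) and returns the first component. The loading sign is
#' pinned so that the largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param x Numeric matrix or data frame (rows = hexagon-quarters, columns =
#'   variables); at least 2 columns and 3 rows, no missing values.
#' @param group Name of the variable group (e.g. `"property"`).
#' @return A `pca_composite`: list with `group`, unit-norm `loading`,
#'   `scores` (mean zero), `center`, `scale`, and `var_share` (share of
#'   variance explained by the first component).
#' @export
pca_first_component <- function(x, group = "composite") {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be numeric.")
  if (ncol(x) < 2) abort("PCA needs at least 2 variables.")
  if (nrow(x) < 3) abort("PCA needs at least 3 rows.")
  if (anyNA(x)) abort("PCA input must not contain missing values.")
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance column(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)
  sv <- svd(xs, nu = 0, nv = ncol(x))
  loading <- sv$v[, 1]
  names(loading) <- colnames(x)
  if (loading[which.max(abs(loading))] < 0) loading <- -loading
  scores <- drop(xs %*% loading)
  structure(list(group = group, loading = loading, scores = scores,
                 center = ctr, scale = sds,
                 var_share = sv$d[1]^2 / sum(sv$d^2)),
            class = "pca_composite")
}

#' @export
print.pca_composite <- function(x, ...) {
  cat("<pca_composite> group '", x$group, "': ", length(x$loading),
      " variables, first component explains ",
      sprintf("%.1f%%", 100 * x$var_share), " of variance\n", sep = "")
  invisible(x)
}

#' Within-cell linear interpolation of missing covariate values
#'
#' Simple stand-in for a full missing-data model: missing values of the
#' given columns are linearly interpolated over quarters within each cell
#' (endpoints carried outward). The modeling functions reject missing
#' values, so interpolation (or a proper imputation) must happen first.
#'
#' @param data Tibble with `cell_id`, `quarter` and the columns in `cols`.
#' @param cols Character vector of column names to interpolate.
#' @return `data` with the columns interpolated.
#' @export
interpolate_within_cell <- function(data, cols) {
  data |>
    dplyr::arrange(.data$cell_id, .data$quarter) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cols),
                                ~ interp_vec(.x, .data$quarter))) |>
    dplyr::ungroup()
}

interp_vec <- function(v, quarter) {
  if (!anyNA(v) || all(is.na(v))) return(v)
  approx(x = quarter[!is.na(v)], y = v[!is.na(v)], xout = quarter, rule = 2)$y
}

#' Assemble the hexagon-quarter design matrix and outcome panel
#'
#' Takes a coded cell-quarter table (one row per retained cell and modeled
#' quarter) and builds the outcome matrix `Y`, the design matrix `X`, and
#' zero offsets `O`. Exposure and history predictors are expected to be
#' lagged already (values at quarter `t` describe events at `t-1`).
#'
#' The design contains: an intercept; the 9 demolition-dose-by-vacancy
#' interaction dummies (reference = zero demolitions within each stratum);
#' 2 vacancy main-effect dummies (low = reference); 3
#' rehabilitation-by-vacancy dummies; the 4 remediation-history columns; one
#' column per `pc_*` composite score present in `data`; and 3
#' quarter-of-year dummies (Q1 = reference). Parcel-derived columns are
#' multiplied by `1 - zero_parcel` so cells without parcels carry zeros.
#'
#' @param data Tibble with columns `cell_id`, `quarter`, `y`, `demo_level`
#'   (factor from [categorize_demolition()]), `vacancy_stratum` (factor from
#'   [categorize_vacancy()]), `rehab` (0/1), `demo_prev4`, `demo_prev8`,
#'   `rehab_prev4`, `rehab_prev8`; optionally `zero_parcel` (0/1, default
#'   0), `quarter_of_year` (1-4, default derived as `((quarter - 1) %% 4) +
#'   1`), and any number of composite score columns named `pc_<group>`.
#' @param W Optional adjacency matrix over the cells (attached for model
#'   fitting).
#' @return A `hex_panel`: list with `Y` (K x N integer matrix), `X`
#'   ((K*N) x p matrix, rows in cell-major order within quarter), `offset`
#'   (K x N zeros), `cells`, `quarters`, and `columns` (tibble of column
#'   name, role, and parent columns for every interaction).
#' @export
build_design_matrix <- function(data, W = NULL) {
  need <- c("cell_id", "quarter", "y", "demo_level", "vacancy_stratum",
            "rehab", "demo_prev4", "demo_prev8", "rehab_prev4", "rehab_prev8")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (anyNA(data[need])) abort("Panel has missing values; impute or interpolate first.")
  if (!"zero_parcel" %in% names(data)) data$zero_parcel <- 0L
  if (!"quarter_of_year" %in% names(data)) {
    data$quarter_of_year <- ((data$quarter - 1L) %% 4L) + 1L
  }
  cells <- sort(unique(data$cell_id))
  quarters <- sort(unique(data$quarter))
  K <- length(cells); N <- length(quarters)
  if (nrow(data) != K * N) {
    abort("`data` must contain exactly one row per (cell, quarter).")
  }
  data <- dplyr::arrange(data, .data$quarter, .data$cell_id)

  pc_cols <- grep("^pc_", names(data), value = TRUE)
  parcel_mask <- 1 - data$zero_parcel

  cols <- list(); meta <- list()
  add <- function(name, values, role, parents = character(0)) {
    cols[[name]] <<- as.numeric(values)
    meta[[name]] <<- tibble::tibble(name = name, role = role,
                                    parents = list(parents))
  }
  add("(Intercept)", rep(1, nrow(data)), "intercept")
  demo_levels <- c("low", "med", "high")
  vac_levels <- c("low", "medium", "high")
  for (dl in demo_levels) for (vl in vac_levels) {
    nm <- paste0("demo_", dl, ":vac_", vl)
    add(nm, (data$demo_level == dl) * (data$vacancy_stratum == vl) * parcel_mask,
        "exposure", c(paste0("demo_", dl), paste0("vac_", vl)))
  }
  for (vl in c("medium", "high")) {
    add(paste0("vac_", vl), (data$vacancy_stratum == vl) * parcel_mask,
        "stratum")
  }
  for (vl in vac_levels) {
    nm <- paste0("rehab:vac_", vl)
    add(nm, data$rehab * (data$vacancy_stratum == vl) * parcel_mask,
        "exposure", c("rehab", paste0("vac_", vl)))
  }
  for (h in c("demo_prev4", "demo_prev8", "rehab_prev4", "rehab_prev8")) {
    add(h, data[[h]] * parcel_mask, "history")
  }
  for (pc in pc_cols) {
    vals <- data[[pc]]
    if (pc == "pc_property") vals <- vals * parcel_mask
    add(pc, vals, "composite")
  }
  for (qq in 2:4) {
    add(paste0("qtr_", qq), as.numeric(data$quarter_of_year == qq), "season")
  }

  X <- do.call(cbind, cols)
  rk <- qr(X)
  if (rk$rank < ncol(X)) {
    dropped <- colnames(X)[rk$pivot[(rk$rank + 1):ncol(X)]]
    warn(paste0("Design matrix is rank deficient; collinear column(s): ",
                paste(dropped, collapse = ", ")))
  }
  Y <- matrix(as.integer(data$y), K, N, dimnames = list(cells, quarters))
  structure(list(
    Y = Y, X = X, offset = matrix(0, K, N, dimnames = list(cells, quarters)),
    cells = cells, quarters = quarters,
    columns = dplyr::bind_rows(meta), W = W
  ), class = "hex_panel")
}

#' @export
print.hex_panel <- function(x, ...) {
  cat("<hex_panel> ", nrow(x$Y), " cells x ", ncol(x$Y), " quarters, ",
      ncol(x$X), " design columns\n", sep = "")
  invisible(x)
}

#' Long tidy view of a panel
#'
#' @param x A `hex_panel`.
#' @param ... Unused.
#' @return Tibble `cell_id`, `quarter`, `y`, and one column per design
#'   column.
#' @export
tidy.hex_panel <- function(x, ...) {
  K <- length(x$cells); N <- length(x$quarters)
  out <- tibble::tibble(
    cell_id = rep(x$cells, N),
    quarter = rep(x$quarters, each = K),
    y = as.vector(x$Y)
  )
  dplyr::bind_cols(out, tibble::as_tibble(x$X))
}

#' Write / read a panel as tidy CSV plus JSON column metadata
#'
#' The CSV is fully long: one row per (cell_id, quarter, variable, value),
#' where variables are `y` plus every design column; the sidecar
#' `<stem>_columns.json` records each design column's role and parents.
#'
#' @param panel A `hex_panel`.
#' @param stem Output path stem; writes `<stem>.csv` and
#'   `<stem>_columns.json`.
#' @return `stem` (write) or a reconstructed `hex_panel` (read).
#' @export
write_panel_csv <- function(panel, stem) {
  long <- tidy(panel) |>
    tidyr::pivot_longer(-c("cell_id", "quarter"), names_to = "variable",
                        values_to = "value")
  utils::write.csv(long, paste0(stem, ".csv"), row.names = FALSE)
  meta <- panel$columns
  meta$parents <- lapply(meta$parents, identity)
  jsonlite::write_json(meta, paste0(stem, "_columns.json"))
  invisible(stem)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(stem) {
  long <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  meta <- jsonlite::fromJSON(paste0(stem, "_columns.json"))
  wide <- tidyr::pivot_wider(long, names_from = "variable",
                             values_from = "value")
  wide <- dplyr::arrange(wide, .data$quarter, .data$cell_id)
  cells <- sort(unique(wide$cell_id))
  quarters <- sort(unique(wide$quarter))
  K <- length(cells); N <- length(quarters)
  X <- as.matrix(wide[meta$name])
  structure(list(
    Y = matrix(as.integer(wide$y), K, N, dimnames = list(cells, quarters)),
    X = X, offset = matrix(0, K, N, dimnames = list(cells, quarters)),
    cells = cells, quarters = quarters,
    columns = tibble::tibble(name = meta$name, role = meta$role,
                             parents = meta$parents),
    W = NULL
  ), class = "hex_panel")
}
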