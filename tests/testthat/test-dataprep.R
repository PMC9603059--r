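test_that("dose and stratum coders match an exhaustive lookup over 0..50", {
  counts <- 0:50
  # independent lookup built with cut()
  demo_ref <- cut(counts, c(-1, 0, 1, 2, Inf),
                  labels = c("ref", "low", "med", "high"))
  vac_ref <- cut(counts, c(-1, 1, 11, Inf),
                 labels = c("low", "medium", "high"))
  expect_equal(as.character(categorize_demolition(counts)),
               as.character(demo_ref))
  expect_equal(as.character(categorize_vacancy(counts)),
               as.character(vac_ref))
  expect_equal(rehab_indicator(counts), as.integer(counts >= 1))
  # printed anchor cases
  expect_equal(as.character(categorize_demolition(c(0, 1, 2, 13))),
               c("ref", "low", "med", "high"))
  expect_equal(as.character(categorize_vacancy(c(1, 2, 11, 12))),
               c("low", "medium", "medium", "high"))
  expect_equal(rehab_indicator(6), 1L)
  expect_error(categorize_demolition(-1), "non-negative")
  expect_error(categorize_vacancy(2.5), "non-negative")
  expect_error(rehab_indicator(-3), "non-negative")
})

test_that("point events are assigned to the containing hexagon", {
  g <- flower_grid()
  # events at cell centres land in those cells
  ev <- tibble::tibble(x = g$center_x, y = g$center_y,
                       quarter = 1L, class = "crime")
  expect_equal(assign_cells(ev, g), g$cell_id)
  counts <- aggregate_events(ev, g)
  expect_equal(sum(counts$count), nrow(g))
  expect_true(all(counts$count[match(g$cell_id, counts$cell_id)] == 1))
  # no events -> all-zero array over the requested quarters
  none <- aggregate_events(ev[0, ], g, quarters = 1:3)
  expect_equal(nrow(none), 0)  # no classes observed
  # far-away point is reported as unassigned, not dropped
  far <- tibble::tibble(x = 100, y = 100, quarter = 1L, class = "crime")
  expect_warning(res <- aggregate_events(far, g), "unassigned")
  expect_equal(sum(res$count), 0)
  expect_equal(sum(attr(res, "unassigned")$count), 1)
})

test_that("scattered points agree with a brute-force point-in-polygon oracle", {
  g <- flower_grid()
  verts <- hex_vertices(g)
  set.seed(7)
  n <- 100
  pts <- tibble::tibble(
    x = runif(n, min(g$center_x) - 1, max(g$center_x) + 1),
    y = runif(n, min(g$center_y) - 1, max(g$center_y) + 1),
    quarter = 1L, class = "crime")
  assigned <- assign_cells(pts, g)
  oracle <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(g))) {
      if (pracma::inpolygon(pts$x[i], pts$y[i],
                            verts[[j]][, 1], verts[[j]][, 2])) {
        oracle[i] <- g$cell_id[j]
        break
      }
    }
  }
  expect_equal(assigned, oracle)
})

test_that("history covariates evaluate the two 4-quarter windows", {
  # single cell, quarters -7..4, all zero -> all-zero history
  base <- tibble::tibble(cell_id = 1L, quarter = -7:4,
                         demolitions = 0L, rehabs = 0L)
  h <- history_covariates(base, start_quarter = 1)
  expect_equal(nrow(h), 4)
  expect_true(all(h$demo_prev4 == 0 & h$demo_prev8 == 0 &
                    h$rehab_prev4 == 0 & h$rehab_prev8 == 0))

  # one demolition exactly 5 quarters before t = 1 falls in the older window
  d5 <- base
  d5$demolitions[d5$quarter == -4] <- 1L
  h5 <- history_covariates(d5, start_quarter = 1)
  expect_equal(h5$demo_prev4[h5$quarter == 1], 0)
  expect_equal(h5$demo_prev8[h5$quarter == 1], 1)

  # rehab counts (..., 2, 0, 0, 0, 1) ending at t-1 -> both indicators on
  rh <- base
  rh$rehabs[rh$quarter %in% c(-4, 0)] <- c(2L, 1L)
  hr <- history_covariates(rh, start_quarter = 1)
  expect_equal(hr$rehab_prev4[hr$quarter == 1], 1)
  expect_equal(hr$rehab_prev8[hr$quarter == 1], 1)

  # insufficient lead-in names the requirement
  expect_error(history_covariates(base, start_quarter = 0), "8 lead-in")
})

test_that("PCA composite is a pinned-sign unit-loading first component", {
  set.seed(11)
  # two perfectly correlated standardized columns -> PC1 explains everything
  z <- rnorm(50)
  x2 <- cbind(a = z, b = 2 * z + 3)
  pc <- pca_first_component(x2, group = "property")
  expect_equal(pc$var_share, 1, tolerance = 1e-12)
  expect_equal(abs(cor(pc$scores, z)), 1, tolerance = 1e-12)
  expect_equal(sum(pc$loading^2), 1, tolerance = 1e-12)
  expect_gt(pc$loading[which.max(abs(pc$loading))], 0)
  expect_equal(mean(pc$scores), 0, tolerance = 1e-12)

  # identity covariance: explained share approaches 1/p
  p <- 4
  big <- matrix(rnorm(4000 * p), ncol = p)
  pcb <- pca_first_component(big)
  expect_lt(abs(pcb$var_share - 1 / p), 0.05)

  # definitional consistency: scores = standardized data %*% loading
  xs <- scale(big, center = pcb$center, scale = pcb$scale)
  expect_equal(pcb$scores, drop(xs %*% pcb$loading), tolerance = 1e-12)

  expect_error(pca_first_component(cbind(a = z, b = rep(1, 50))), "b")
  expect_error(pca_first_component(matrix(1:3, ncol = 1)), "2 variables")
})

make_coded <- function(K = 4, N = 8) {
  tidyr::expand_grid(cell_id = seq_len(K), quarter = seq_len(N)) |>
    dplyr::mutate(
      y = 1L,
      demo_level = categorize_demolition(rep(0L, K * N)),
      vacancy_stratum = categorize_vacancy(rep(0L, K * N)),
      rehab = 0L, demo_prev4 = 0, demo_prev8 = 0,
      rehab_prev4 = 0L, rehab_prev8 = 0L,
      pc_property = rnorm(K * N), pc_community = rnorm(K * N))
}

test_that("design matrix encodes interactions, seasons and parcel masking", {
  set.seed(3)
  coded <- make_coded()
  # one cell-quarter with 2 demolitions and 5 vacancies
  i <- which(coded$cell_id == 2 & coded$quarter == 3)
  coded$demo_level[i] <- categorize_demolition(2L)
  coded$vacancy_stratum[i] <- categorize_vacancy(5L)
  panel <- suppressWarnings(build_design_matrix(coded))
  row <- (3 - 1) * 4 + 2  # quarter-major, cell within quarter
  inter <- grep("^demo_", colnames(panel$X), value = TRUE)
  on <- panel$X[row, inter]
  expect_equal(unname(on["demo_med:vac_medium"]), 1)
  expect_equal(sum(on), 1)  # the other 8 dose-by-stratum dummies are 0

  # column roster: intercept + 9 + 2 + 3 + 4 + PCs + 3 seasonal
  expect_equal(ncol(panel$X), 1 + 9 + 2 + 3 + 4 + 2 + 3)
  expect_equal(panel$columns$name, colnames(panel$X))

  # seasonal dummies: Q1 reference, quarter 3 -> qtr_3
  expect_equal(unname(panel$X[row, c("qtr_2", "qtr_3", "qtr_4")]), c(0, 1, 0))
  q1row <- panel$X[(1 - 1) * 4 + 1, c("qtr_2", "qtr_3", "qtr_4")]
  expect_equal(unname(q1row), c(0, 0, 0))

  # every interaction column equals the product of its parents
  meta <- panel$columns
  demo_cols <- meta$name[meta$role == "exposure"]
  for (cn in demo_cols) {
    parents <- meta$parents[[match(cn, meta$name)]]
    expect_length(parents, 2)
  }

  # zero-parcel cells carry zeros in all parcel-derived columns
  coded2 <- coded
  coded2$zero_parcel <- as.integer(coded2$cell_id == 2)
  coded2$demo_level[i] <- categorize_demolition(3L)
  coded2$vacancy_stratum[i] <- categorize_vacancy(20L)
  coded2$rehab[i] <- 1L
  coded2$demo_prev4[i] <- 2
  panel2 <- suppressWarnings(build_design_matrix(coded2))
  parcel_cols <- panel2$columns$name[panel2$columns$role %in%
                                       c("exposure", "stratum", "history")]
  expect_true(all(panel2$X[row, parcel_cols] == 0))
  expect_true(all(panel2$X[row, "pc_property"] == 0))
  expect_false(all(panel2$X[row, "pc_community"] == 0))
})

test_that("panel assembly is invariant to input row order", {
  set.seed(5)
  coded <- make_coded()
  coded$y <- rpois(nrow(coded), 2)
  p1 <- suppressWarnings(build_design_matrix(coded))
  p2 <- suppressWarnings(build_design_matrix(coded[sample(nrow(coded)), ]))
  expect_equal(p1$Y, p2$Y)
  expect_equal(p1$X, p2$X)
})

test_that("with all exposures zero the exposure block is identically zero", {
  coded <- make_coded()
  panel <- suppressWarnings(build_design_matrix(coded))
  expo <- panel$columns$name[panel$columns$role == "exposure"]
  expect_true(all(panel$X[, expo] == 0))
})

test_that("missing values are rejected and interpolation fills them", {
  coded <- make_coded()
  coded$demo_prev4[5] <- NA
  expect_error(build_design_matrix(coded), "missing")
  df <- tibble::tibble(cell_id = 1L, quarter = 1:5,
                       v = c(1, NA, 3, NA, 5))
  out <- interpolate_within_cell(df, "v")
  expect_equal(out$v, c(1, 2, 3, 4, 5))
})

test_that("panel round-trips through tidy CSV plus column metadata", {
  set.seed(13)
  coded <- make_coded()
  coded$y <- rpois(nrow(coded), 3)
  panel <- suppressWarnings(build_design_matrix(coded))
  stem <- file.path(withr::local_tempdir(), "panel")
  write_panel_csv(panel, stem)
  panel2 <- read_panel_csv(stem)
  expect_equal(panel2$Y, panel$Y)
  expect_equal(unname(panel2$X), unname(panel$X))
  expect_equal(panel2$columns$name, panel$columns$name)
})
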