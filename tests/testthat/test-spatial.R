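test_that("Moran's I matches the brute-force double loop on random graphs", {
  set.seed(19)
  for (trial in 1:100) {
    n <- sample(4:10, 1)
    w <- random_adjacency(n)
    x <- rnorm(n)
    expect_equal(morans_i(x, w), morans_i_bruteforce(x, w), tolerance = 1e-10)
  }
})

test_that("Moran's I handles the canonical hand cases", {
  # 4-node path graph
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1; path4 <- path4 + t(path4)
  x <- c(1, 1, 0, 0)
  expect_equal(morans_i(x, path4), morans_i_bruteforce(x, path4),
               tolerance = 1e-12)
  expect_gt(morans_i(x, path4), 0)  # like values adjacent

  # perfect checkerboard on the 4-cycle: maximal negative autocorrelation
  cyc4 <- matrix(0, 4, 4)
  cyc4[cbind(1:4, c(2, 3, 4, 1))] <- 1; cyc4 <- cyc4 + t(cyc4)
  expect_equal(morans_i(c(1, 0, 1, 0), cyc4), -1, tolerance = 1e-12)

  expect_true(is.na(morans_i(c(2, 2, 2, 2), path4)))     # constant
  expect_true(is.na(morans_i(x, matrix(0, 4, 4))))        # edgeless
  expect_error(morans_i(c(1, 2), matrix(0, 2, 2)), "3 pixels")
  expect_error(morans_i(c(1, 2, 3), matrix(0, 4, 4)), "dimension")
})

test_that("randomly permuted values give near-zero mean z on any graph", {
  set.seed(23)
  w <- random_adjacency(12, p = 0.3)
  x <- rgamma(12, 2)
  zs <- vapply(1:200, function(k) {
    morans_z(sample(x), w, method = "analytic")
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("clustered values give a strongly positive z", {
  # all mass on one neighborhood of a 2-row grid graph
  n <- 20
  w <- matrix(0, n, n)
  for (i in 1:(n - 1)) w[i, i + 1] <- 1
  w <- w + t(w)
  x <- c(rep(5, 4), rep(0, n - 4))
  expect_gt(morans_z(x, w, method = "analytic"), 2)
  expect_gt(morans_z(x, w, method = "permutation", n_perm = 200, seed = 2), 2)
})

test_that("analytic and permutation z agree on a simulated cell", {
  cfg <- small_config(n_a_pixels = 50, n_b_pixels = 50,
                      n_events_per_cell = 600,
                      polarization_kappa = setNames(rep(3, 10), small_markers()))
  cell <- simulate_called_cells(cfg, "acute", n = 1)[[1]]
  pt <- pixel_table(cell, small_panel())
  x <- log1p(pt$counts[, "M01"])
  za <- morans_z(x, pt$adjacency, method = "analytic")
  zp <- morans_z(x, pt$adjacency, method = "permutation", n_perm = 500, seed = 9)
  expect_equal(za, zp, tolerance = 0.5)
})

test_that("polarization score tables exclude controls and degenerate markers", {
  markers <- c(small_markers(8), "ctrl1", "ctrl2", "ctrl3", "ctrl4")
  panel <- small_panel(markers, controls = c("ctrl1", "ctrl2", "ctrl3", "ctrl4"))
  cfg <- small_config(markers = markers)
  cells <- simulate_called_cells(cfg, "acute", n = 3)
  ps <- polarization_scores(cells, panel)
  expect_false(any(ps$marker %in% c("ctrl1", "ctrl2", "ctrl3", "ctrl4")))
  expect_true(all(ps$marker %in% markers[1:8]))
  expect_false(any(is.na(ps$morans_i)))
  # a marker absent from every cell yields no rows
  w <- setNames(rep(1, length(markers)), markers); w["M08"] <- 0
  cells0 <- simulate_called_cells(small_config(markers = markers, abundance = w),
                                  "acute", n = 2, offset = 10)
  ps0 <- polarization_scores(cells0, panel)
  expect_false("M08" %in% ps0$marker)
})

test_that("mean polarization z rank-orders with the injected kappa", {
  mk <- small_markers(6)
  kappa <- setNames(c(0, 0, 2, 2, 6, 6), mk)
  cfg <- small_config(markers = mk, polarization_kappa = kappa,
                      n_events_per_cell = 900, n_a_pixels = 80,
                      n_b_pixels = 80)
  cells <- simulate_called_cells(cfg, "chronic", n = 12)
  ps <- polarization_scores(cells, small_panel(mk))
  mean_z <- tapply(ps$z_score, kappa[ps$marker], mean)
  expect_true(all(diff(mean_z[order(as.numeric(names(mean_z)))]) > 0))
})

test_that("pearson colocalization hits the exact endpoints", {
  counts <- cbind(A = c(0, 1, 2, 5, 9), B = c(0, 1, 2, 5, 9),
                  C = 9 - c(0, 1, 2, 5, 9), D = rep(3, 5))
  pt <- structure(list(cell_id = "c", counts = counts, adjacency = diag(5) * 0),
                  class = "pixel_table")
  expect_equal(pearson_coloc(pt, "A", "B"), 1)
  expect_equal(pearson_coloc(pt, "A", "C", transform = identity), -1)
  expect_true(is.na(pearson_coloc(pt, "A", "D")))
})

test_that("coloc_z is calibrated on independent markers and large when identical", {
  set.seed(41)
  zs <- replicate(100, {
    counts <- cbind(X = rpois(40, 5), Y = rpois(40, 5))
    pt <- structure(list(cell_id = "c", counts = counts, adjacency = NULL),
                    class = "pixel_table")
    coloc_z(pt, "X", "Y", n_perm = 100, seed = sample.int(1e6, 1))
  })
  expect_lt(abs(mean(zs)), 0.3)

  ident <- cbind(X = rpois(30, 8))
  pt2 <- structure(list(cell_id = "c", counts = cbind(ident, Y = ident[, 1]),
                        adjacency = NULL), class = "pixel_table")
  expect_gt(coloc_z(pt2, "X", "Y", n_perm = 200, seed = 3), 3)

  # symmetric in argument order within Monte-Carlo error
  counts <- cbind(X = rpois(50, 6), Y = rpois(50, 6) + rpois(50, 2))
  pt3 <- structure(list(cell_id = "c", counts = counts, adjacency = NULL),
                   class = "pixel_table")
  z_ab <- coloc_z(pt3, "X", "Y", n_perm = 400, seed = 5)
  z_ba <- coloc_z(pt3, "Y", "X", n_perm = 400, seed = 6)
  expect_equal(z_ab, z_ba, tolerance = 0.5)
})

test_that("hotspot sharing raises the mean pairwise correlation", {
  mk <- c("P1", "P2", "F1", "F2")
  kappa <- setNames(c(6, 6, 0, 0), mk)
  mean_r <- vapply(c(0, 0.8), function(s) {
    cfg <- small_config(markers = mk, polarization_kappa = kappa,
                        coloc_pairs = data.frame(marker_a = "P1", marker_b = "P2",
                                                 sharing = s),
                        n_events_per_cell = 800, n_a_pixels = 60,
                        n_b_pixels = 60, seed = 17)
    cells <- simulate_called_cells(cfg, "acute", n = 30)
    cs <- colocalization_scores(cells, small_panel(mk), n_perm = 30)
    mean(cs$pearson_r[cs$marker_a == "P1" & cs$marker_b == "P2"])
  }, numeric(1))
  expect_gt(mean_r[2], mean_r[1])
})

test_that("colocalization tables enumerate pairs canonically without duplicates", {
  markers <- c(small_markers(6), "ctl")
  panel <- small_panel(markers, controls = "ctl")
  cells <- simulate_called_cells(small_config(markers = markers), "acute", n = 2)
  cs <- colocalization_scores(cells, panel, n_perm = 30)
  expect_true(all(cs$marker_a < cs$marker_b))
  expect_false("ctl" %in% c(cs$marker_a, cs$marker_b))
  per_cell <- table(cs$cell_id, paste(cs$marker_a, cs$marker_b))
  expect_true(all(per_cell <= 1))  # never duplicated
  expect_lte(max(table(cs$cell_id)), choose(6, 2))
})

test_that("colocalization scores are reproducible under a fixed seed", {
  cells <- simulate_called_cells(small_config(), "acute", n = 2)
  panel <- small_panel()
  a <- colocalization_scores(cells, panel, n_perm = 50, seed = 12)
  b <- colocalization_scores(cells, panel, n_perm = 50, seed = 12)
  expect_identical(a, b)
  ps_a <- polarization_scores(cells, panel, method = "permutation",
                              n_perm = 50, seed = 12)
  ps_b <- polarization_scores(cells, panel, method = "permutation",
                              n_perm = 50, seed = 12)
  expect_identical(ps_a, ps_b)
})

test_that("gini matches the pairwise formula and its boundary behavior", {
  expect_equal(gini(c(1, 2, 3, 4)), 0.25)
  expect_equal(gini(rep(3, 6)), 0)
  expect_equal(gini(c(2, 4, 6, 8)), gini(c(1, 2, 3, 4)))  # scale invariance
  expect_true(is.na(gini(c(0, 0))))
  expect_error(gini(c(-1, 2)), "nonnegative")
  expect_error(gini(5), "2 values")

  set.seed(3)
  for (trial in 1:100) {
    x <- rgamma(sample(2:12, 1), shape = runif(1, 0.5, 3))
    expect_equal(gini(x), gini_bruteforce(x), tolerance = 1e-12)
    n <- length(x)
    expect_gte(gini(x), 0)
    expect_lte(gini(x), 1 - 1 / n + 1e-12)
  }

  # transferring mass from the poorest to the richest raises G
  x <- c(1, 2, 3, 10)
  y <- c(0.5, 2, 3, 10.5)
  expect_gt(gini(y), gini(x))
})
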