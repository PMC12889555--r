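# Construct score tables directly: the differential module consumes
# (cell, marker/pair, z) records plus condition labels.
make_polar_scores <- function(z_by_marker_cond, n = 30, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (m in names(z_by_marker_cond)) {
    for (cond in c("acute", "chronic")) {
      gen <- z_by_marker_cond[[m]][[cond]]
      rows[[paste(m, cond)]] <- data.frame(
        cell_id = sprintf("%s_c%03d", cond, seq_len(n)), marker = m,
        morans_i = 0, z_score = gen(n), condition = cond,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("differential polarization flags a shifted marker, not a null one", {
  sc <- make_polar_scores(list(
    SHIFT = list(acute = function(n) rnorm(n, 0), chronic = function(n) rnorm(n, 3)),
    NULL1 = list(acute = function(n) rnorm(n, 1), chronic = function(n) rnorm(n, 1))
  ), n = 60, seed = 2)
  dp <- differential_polarization(sc)
  expect_identical(dp$marker[dp$significant], "SHIFT")
  expect_identical(dp$direction[dp$marker == "SHIFT"], "up")
  expect_equal(dp$delta_median_z[dp$marker == "SHIFT"],
               median(sc$z_score[sc$marker == "SHIFT" & sc$condition == "chronic"]) -
                 median(sc$z_score[sc$marker == "SHIFT" & sc$condition == "acute"]))
})

test_that("untested markers are reported but excluded from the Bonferroni denominator", {
  sc <- make_polar_scores(list(
    A = list(acute = function(n) rnorm(n), chronic = function(n) rnorm(n, 2)),
    B = list(acute = function(n) rnorm(n), chronic = function(n) rnorm(n))
  ), n = 40, seed = 3)
  # marker C exists only in chronic cells
  sc <- rbind(sc, data.frame(cell_id = sprintf("chronic_x%02d", 1:10),
                             marker = "C", morans_i = 0, z_score = rnorm(10),
                             condition = "chronic", stringsAsFactors = FALSE))
  dp <- differential_polarization(sc)
  expect_true("C" %in% dp$marker)
  expect_false(dp$tested[dp$marker == "C"])
  expect_true(is.na(dp$p_adjusted[dp$marker == "C"]))
  # Bonferroni multiplies by the 2 tested markers only
  expect_equal(dp$p_adjusted[dp$tested],
               pmin(1, dp$p_value[dp$tested] * 2))
})

test_that("swapping condition labels negates the contrast and keeps p-values", {
  sc <- make_polar_scores(list(
    A = list(acute = function(n) rnorm(n, 0.5), chronic = function(n) rnorm(n, 1.4))
  ), n = 50, seed = 4)
  swapped <- sc
  swapped$condition <- ifelse(sc$condition == "acute", "chronic", "acute")
  d1 <- differential_polarization(sc)
  d2 <- differential_polarization(swapped)
  expect_equal(d1$delta_median_z, -d2$delta_median_z)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)

  v1 <- variability_test(sc, n_perm = 200, seed = 5)
  v2 <- variability_test(swapped, n_perm = 200, seed = 5)
  expect_equal(v1$observed_stat, -v2$observed_stat)
})

test_that("differential colocalization applies both the p and the delta gates", {
  set.seed(6)
  n <- 60
  mk_pair <- function(a, b, za, zc) {
    rbind(data.frame(cell_id = sprintf("a%02d", 1:n), marker_a = a, marker_b = b,
                     pearson_r = 0, z_score = za(n), condition = "acute"),
          data.frame(cell_id = sprintf("c%02d", 1:n), marker_a = a, marker_b = b,
                     pearson_r = 0, z_score = zc(n), condition = "chronic"))
  }
  sc <- rbind(
    # large shift: significant
    mk_pair("CD37", "CD82", function(n) rnorm(n, 0, 0.5), function(n) rnorm(n, 3, 0.5)),
    # highly significant p but |delta| < 1: gated out
    mk_pair("CD2", "CD54", function(n) rnorm(n, 0, 0.1), function(n) rnorm(n, 0.5, 0.1)),
    # pure null
    mk_pair("CD3E", "CD44", function(n) rnorm(n), function(n) rnorm(n)))
  dc <- differential_colocalization(sc)
  expect_equal(nrow(dc), 3)
  expect_true(dc$significant[dc$marker_a == "CD37"])
  small <- dc[dc$marker_a == "CD2", ]
  expect_lt(small$p_adjusted, 0.001)
  expect_false(small$significant)      # effect-size gate
  expect_false(dc$significant[dc$marker_a == "CD3E"])
})

test_that("variability test finds overdispersed chronic scores", {
  set.seed(8)
  n <- 150
  sc <- rbind(
    data.frame(cell_id = sprintf("a%03d", 1:n), marker = "VAR", morans_i = 0,
               z_score = rnorm(n, 2, 0.3), condition = "acute"),
    data.frame(cell_id = sprintf("c%03d", 1:n), marker = "VAR", morans_i = 0,
               z_score = c(rnorm(n / 2, 0.3, 0.3), rnorm(n / 2, 4, 0.3)),
               condition = "chronic"),
    data.frame(cell_id = sprintf("a%03d", 1:n), marker = "FLAT", morans_i = 0,
               z_score = rnorm(n, 2, 0.5), condition = "acute"),
    data.frame(cell_id = sprintf("c%03d", 1:n), marker = "FLAT", morans_i = 0,
               z_score = rnorm(n, 2, 0.5), condition = "chronic"))
  vt <- variability_test(sc, n_perm = 500, seed = 9)
  var_row <- vt[vt$marker == "VAR", ]
  expect_true(var_row$significant)
  expect_gt(var_row$gini_chronic, var_row$gini_acute)
  expect_false(vt$significant[vt$marker == "FLAT"])
})

test_that("permutation p-values respect the discrete floor and reproducibility", {
  set.seed(10)
  n <- 40
  sc <- data.frame(cell_id = sprintf("x%03d", 1:(2 * n)), marker = "M",
                   morans_i = 0,
                   z_score = c(rnorm(n, 0, 0.1), c(rnorm(n - 5, 0, 0.1), rnorm(5, 8))),
                   condition = rep(c("acute", "chronic"), each = n))
  v <- variability_test(sc, n_perm = 2000, seed = 11)
  expect_gte(v$p_permutation, 1 / 2001)
  expect_gte(v$p_montecarlo, 1 / 2001)
  v2 <- variability_test(sc, n_perm = 2000, seed = 11)
  expect_identical(v, v2)
  # degenerate marker: untested
  flat <- data.frame(cell_id = sprintf("y%02d", 1:20), marker = "Z",
                     morans_i = 0, z_score = 1,
                     condition = rep(c("acute", "chronic"), each = 10))
  vflat <- variability_test(flat, n_perm = 100, seed = 1)
  expect_false(vflat$tested)
})

test_that("permutation p-values are valid under the null", {
  set.seed(12)
  ps <- replicate(60, {
    sc <- data.frame(cell_id = sprintf("x%03d", 1:60), marker = "M",
                     morans_i = 0, z_score = rnorm(60),
                     condition = rep(c("acute", "chronic"), each = 30))
    variability_test(sc, n_perm = 200, seed = sample.int(1e6, 1))$p_value
  })
  # stochastically dominates uniform: empirical CDF at alpha below alpha
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 60))
  }
})

test_that("phenotype subsets reuse the identical code path", {
  sc <- make_polar_scores(list(
    A = list(acute = function(n) rnorm(n), chronic = function(n) rnorm(n, 2.5))
  ), n = 40, seed = 13)
  sc$phenotype <- "CD8"
  all_r <- differential_polarization(sc, subset = "all")
  cd8_r <- differential_polarization(sc, subset = "CD8")
  expect_equal(all_r$p_value, cd8_r$p_value)
  expect_equal(all_r$delta_median_z, cd8_r$delta_median_z)
  expect_error(differential_polarization(sc[, names(sc) != "phenotype"],
                                         subset = "CD8"), "phenotype")
})

test_that("summaries render counts as one-decimal percentages", {
  mk_results <- function(k, n) {
    data.frame(marker = sprintf("M%03d", seq_len(n)),
               significant = seq_len(n) <= k)
  }
  expect_identical(summarize_significance(mk_results(35, 76))$label, "46.1%")
  expect_identical(summarize_significance(mk_results(561, 2850))$label, "19.7%")
  expect_identical(summarize_significance(mk_results(0, 40))$label, "0.0%")

  subsets <- list(
    CD8 = mk_results(31, 76),
    CD4 = mk_results(24, 76))
  # make 7 CD8 hits unique: shift CD4 hits to overlap on 24 of the 31
  subsets$CD4$significant <- c(rep(FALSE, 7), rep(TRUE, 24), rep(FALSE, 45))
  tab <- summarize_significance(subsets)
  cd8 <- tab[tab$subset == "CD8", ]
  expect_equal(cd8$n_unique, 7)
  expect_identical(cd8$unique_label, "22.6%")
  expect_identical(cd8$label, "40.8%")
})

test_that("the signed-significance matrix mirrors the pair table", {
  dc <- data.frame(marker_a = c("A", "A", "B"), marker_b = c("B", "C", "C"),
                   delta_median_z = c(2, -3, 0.2),
                   significant = c(TRUE, TRUE, FALSE))
  m <- significance_matrix(dc)
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["B", "A"], 1L)
  expect_equal(m["A", "C"], -1L)
  expect_equal(m["B", "C"], 0L)
  expect_equal(diag(m), c(A = 0L, B = 0L, C = 0L))
})
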