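# Spatial scores on the per-cell A-pixel graph: Moran's I polarization,
# Pearson colocalization with permutation nulls, and the Gini dispersion
# primitive.

#' Moran's I spatial autocorrelation
#'
#' `I = (N/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with binary, symmetric, row-unnormalized weights `w`, `W = sum_ij w_ij`
#' and `N` pixels. Positive I means like values sit on adjacent pixels
#' (polarization); the null expectation is `-1/(N-1)`. Undefined (NA) for
#' constant values or a weightless graph.
#'
#' @param values numeric vector, one value per A-pixel
#' @param adjacency symmetric 0/1 matrix or sparse Matrix, no self-loops
#' @return Moran's I, or `NA_real_` when undefined
#' @export
morans_i <- function(values, adjacency) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) stop("Moran's I needs at least 3 pixels")
  if (nrow(adjacency) != n) stop("adjacency dimension does not match values")
  xd <- x - mean(x)
  s2 <- sum(xd^2)
  if (s2 == 0) return(NA_real_)
  W <- sum(adjacency)
  if (W == 0) return(NA_real_)
  num <- as.numeric(crossprod(xd, as.numeric(adjacency %*% xd)))
  (n / W) * num / s2
}

# Graph-level constants for the analytic randomization variance.
.moran_graph_stats <- function(adjacency) {
  deg <- Matrix::rowSums(adjacency)
  list(W = sum(deg),            # ordered pair count for binary symmetric w
       S1 = 2 * sum(deg),       # (w_ij + w_ji)^2 = 4 on each ordered edge
       S2 = sum((2 * deg)^2))
}

# Analytic z under the randomization null, vectorized over the columns of
# xmat (pixels x markers). Returns I, E[I], sd, z per column.
.morans_all <- function(xmat, adjacency) {
  n <- nrow(xmat)
  gs <- .moran_graph_stats(adjacency)
  W <- gs$W; S1 <- gs$S1; S2 <- gs$S2
  xd <- sweep(xmat, 2, colMeans(xmat))
  s2 <- colSums(xd^2)
  num <- colSums(xd * as.matrix(adjacency %*% xd))
  I <- ifelse(s2 > 0 & W > 0, (n / W) * num / s2, NA_real_)
  EI <- -1 / (n - 1)
  z <- sd <- rep(NA_real_, ncol(xmat))
  if (n >= 4 && W > 0) {
    m2 <- s2 / n
    m4 <- colSums(xd^4) / n
    b2 <- ifelse(m2 > 0, m4 / m2^2, NA_real_)
    EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
              b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)) /
      ((n - 1) * (n - 2) * (n - 3) * W^2)
    v <- EI2 - EI^2
    sd <- ifelse(v > 0, sqrt(v), NA_real_)
    z <- (I - EI) / sd
  }
  data.frame(morans_i = I, z_score = z, sd_null = sd)
}

#' Standardized Moran's I
#'
#' `"analytic"` uses the closed-form randomization null:
#' `E[I] = -1/(N-1)` and the randomization variance (which involves the
#' sample kurtosis of the values). `"permutation"` standardizes against the
#' mean and sd of I over `n_perm` random relabelings of the pixel values;
#' it is deterministic given `seed`.
#'
#' @inheritParams morans_i
#' @param method `"analytic"` or `"permutation"`
#' @param n_perm permutations for the empirical null
#' @param seed RNG seed for the permutation null
#' @return z-score, or `NA_real_` when I or the null sd is undefined
#' @export
morans_z <- function(values, adjacency, method = c("analytic", "permutation"),
                     n_perm = 200, seed = 1L) {
  method <- match.arg(method)
  I_obs <- morans_i(values, adjacency)
  if (is.na(I_obs)) return(NA_real_)
  if (method == "analytic") {
    res <- .morans_all(matrix(as.numeric(values), ncol = 1), adjacency)
    return(res$z_score[1])
  }
  x <- as.numeric(values)
  I_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) morans_i(sample(x), adjacency),
           numeric(1))
  })
  s <- stats::sd(I_perm)
  if (is.na(s) || s == 0) return(NA_real_)
  (I_obs - mean(I_perm)) / s
}

#' Per-cell, per-marker polarization scores
#'
#' Computes Moran's I and its z-score for every (cell, marker) with
#' non-constant log1p pixel counts. Control antibodies are excluded, as are
#' markers absent from a cell. Per-cell scores are independent, so the table
#' is order-independent.
#'
#' @param cells list of called cells, or a list of precomputed
#'   [pixel_table()] objects via `tables`
#' @param panel panel data.frame
#' @param method passed to [morans_z()] (analytic default)
#' @param n_perm,seed permutation-null controls
#' @param transform count transform applied per pixel (default `log1p`)
#' @param tables optional precomputed pixel tables matching `cells`
#' @return data.frame: `cell_id`, `marker`, `morans_i`, `z_score`, `method`,
#'   plus `condition`/`donor`/`sample_id` when available on the cells
#' @export
polarization_scores <- function(cells, panel, method = c("analytic", "permutation"),
                                n_perm = 200, seed = 7L, transform = log1p,
                                tables = NULL) {
  method <- match.arg(method)
  keep_m <- target_markers(panel)
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    pt <- if (!is.null(tables)) tables[[i]] else pixel_table(cell, panel)
    x <- transform(pt$counts[, intersect(colnames(pt$counts), keep_m), drop = FALSE])
    nz <- colSums(x) > 0
    varying <- nz & matrixStats_colSds(x) > 0
    x <- x[, varying, drop = FALSE]
    if (ncol(x) == 0 || nrow(x) < 3) next
    if (method == "analytic") {
      res <- .morans_all(x, pt$adjacency)
    } else {
      cell_seed <- derive_seed(seed, i)
      res <- data.frame(
        morans_i = apply(x, 2, morans_i, adjacency = pt$adjacency),
        z_score = vapply(seq_len(ncol(x)), function(j) {
          morans_z(x[, j], pt$adjacency, method = "permutation",
                   n_perm = n_perm, seed = derive_seed(cell_seed, j))
        }, numeric(1)))
    }
    keep <- !is.na(res$morans_i)
    if (!any(keep)) next
    df <- data.frame(cell_id = pt$cell_id, marker = colnames(x)[keep],
                     morans_i = res$morans_i[keep], z_score = res$z_score[keep],
                     method = method, stringsAsFactors = FALSE)
    for (f in c("condition", "donor", "sample_id")) {
      if (!is.null(cell[[f]])) df[[f]] <- cell[[f]]
    }
    out[[i]] <- df
  }
  res <- data.table::rbindlist(out, fill = TRUE)
  as.data.frame(res)
}

# colSds without an extra dependency
matrixStats_colSds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  cm <- colMeans(x)
  sqrt(pmax(0, (colSums(x^2) - n * cm^2) / (n - 1)))
}

#' Pairwise Pearson colocalization of two markers in one cell
#'
#' Pearson correlation of log1p event counts across the cell's A-pixels.
#' Undefined (NA) when either column is constant.
#'
#' @param pt a [pixel_table()]
#' @param marker_a,marker_b marker names
#' @param transform count transform (default `log1p`)
#' @return correlation in \[-1, 1\], or `NA_real_`
#' @export
pearson_coloc <- function(pt, marker_a, marker_b, transform = log1p) {
  x <- transform(pt$counts[, marker_a])
  y <- transform(pt$counts[, marker_b])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Permutation z-score for pairwise colocalization
#'
#' Standardizes the observed correlation against its null distribution over
#' `n_perm` independent shufflings of `marker_b`'s counts across pixels:
#' `z = (r_obs - mean r_perm) / sd r_perm`. Deterministic given `seed`.
#'
#' @inheritParams pearson_coloc
#' @param n_perm number of shuffles
#' @param seed RNG seed
#' @return z-score, or `NA_real_` when r or the null sd is undefined
#' @export
coloc_z <- function(pt, marker_a, marker_b, n_perm = 200, seed = 1L,
                    transform = log1p) {
  r_obs <- pearson_coloc(pt, marker_a, marker_b, transform = transform)
  if (is.na(r_obs)) return(NA_real_)
  x <- transform(pt$counts[, marker_a])
  y <- transform(pt$counts[, marker_b])
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) stats::cor(x, sample(y)), numeric(1))
  })
  s <- stats::sd(r_perm)
  if (is.na(s) || s == 0) return(NA_real_)
  (r_obs - mean(r_perm)) / s
}

#' Per-cell colocalization score table for all marker pairs
#'
#' For each cell, computes the Pearson correlation and permutation z-score
#' for every unordered pair of non-control markers, in canonical
#' lexicographic order. Self-pairs and control antibodies are dropped; pairs
#' where either marker has fewer than `min_events` events in the cell, or a
#' constant pixel profile, are skipped (degenerate correlations).
#'
#' The permutation null is batched: at each of the `n_perm` iterations one
#' row permutation of the pixel table is applied and correlations of all
#' original columns against all permuted columns are computed at once, so
#' every pair sees `n_perm` independent shuffles of its second marker.
#'
#' @inheritParams polarization_scores
#' @param min_events minimum per-marker event count within a cell
#' @return data.frame: `cell_id`, `marker_a`, `marker_b`, `pearson_r`,
#'   `z_score`, plus metadata columns when available
#' @export
colocalization_scores <- function(cells, panel, n_perm = 200, seed = 7L,
                                  min_events = 5, transform = log1p,
                                  tables = NULL) {
  keep_m <- sort(target_markers(panel))
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    pt <- if (!is.null(tables)) tables[[i]] else pixel_table(cell, panel)
    cm <- pt$counts[, intersect(colnames(pt$counts), keep_m), drop = FALSE]
    ok <- colSums(cm) >= min_events
    x <- transform(cm[, ok, drop = FALSE])
    ok2 <- matrixStats_colSds(x) > 0
    x <- x[, ok2, drop = FALSE]
    m <- ncol(x)
    if (m < 2 || nrow(x) < 3) next
    x <- x[, order(colnames(x)), drop = FALSE]
    r_obs <- stats::cor(x)
    n_pix <- nrow(x)
    mean_r <- matrix(0, m, m); m2_r <- matrix(0, m, m)
    with_seed(derive_seed(seed, i), {
      for (k in seq_len(n_perm)) {
        rp <- stats::cor(x, x[sample.int(n_pix), , drop = FALSE])
        d <- rp - mean_r
        mean_r <- mean_r + d / k
        m2_r <- m2_r + d * (rp - mean_r)
      }
    })
    sd_r <- sqrt(m2_r / (n_perm - 1))
    z <- (r_obs - mean_r) / sd_r
    z[!is.finite(z)] <- NA_real_
    iu <- which(upper.tri(r_obs), arr.ind = TRUE)
    df <- data.frame(cell_id = pt$cell_id,
                     marker_a = colnames(x)[iu[, 1]],
                     marker_b = colnames(x)[iu[, 2]],
                     pearson_r = r_obs[iu],
                     z_score = z[iu],
                     stringsAsFactors = FALSE)
    for (f in c("condition", "donor", "sample_id")) {
      if (!is.null(cell[[f]])) df[[f]] <- cell[[f]]
    }
    out[[i]] <- df
  }
  as.data.frame(data.table::rbindlist(out, fill = TRUE))
}

#' Gini coefficient (population form)
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 xbar)`, the population (biased)
#' denominator, computed via the sorted-value identity. G lies in
#' `[0, 1 - 1/n]`; 0 means all values equal. Values must be nonnegative and
#' not all zero.
#'
#' @param values nonnegative numeric vector, length >= 2
#' @return the Gini coefficient, or `NA_real_` for an all-zero vector
#' @export
#' @examples
#' gini(c(1, 2, 3, 4))  # 0.25
gini <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2) stop("gini needs at least 2 values")
  if (any(x < 0)) stop("gini requires nonnegative values")
  if (all(x == 0)) return(NA_real_)
  n <- length(x)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(x))
}
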