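# Marker abundance: CLR normalization, PCA/Louvain clustering, differential
# abundance, trogocytosis-confound flagging.

#' Centered log-ratio normalization
#'
#' Per cell: `log(count + 1) - mean(log(count + 1))` across panel markers.
#' CLR is the convention for antibody-count single-cell data because library
#' size (total edges per cell) is a technical quantity; every normalized row
#' sums to zero and is invariant to rescaling the cell's counts.
#'
#' @param counts nonnegative integer matrix, cells x markers
#' @return numeric matrix of the same shape
#' @export
clr_normalize <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    stop("all-zero cell(s): ", paste(rownames(counts)[zero], collapse = ", "))
  }
  lg <- log(counts + 1)
  lg - rowMeans(lg)
}

#' Cluster cells by normalized marker profile
#'
#' PCA to `n_pcs` components (capped at cells - 1 and at the marker count),
#' a k-nearest-neighbor graph on the PC scores, then Louvain community
#' detection at the given resolution. Deterministic given `seed`.
#'
#' @param normalized CLR matrix from [clr_normalize()]
#' @param resolution Louvain resolution (default 1)
#' @param n_pcs number of principal components (default 20)
#' @param k neighbors per cell (default 15, capped at cells - 1)
#' @param seed RNG seed
#' @return integer vector of cluster labels, named by cell
#' @export
cluster_cells <- function(normalized, resolution = 1, n_pcs = 20, k = 15,
                          seed = 1L) {
  n <- nrow(normalized)
  if (n < 2) stop("clustering needs at least 2 cells")
  n_pcs <- min(n_pcs, n - 1, ncol(normalized))
  pcs <- stats::prcomp(normalized, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(pcs))
  nn <- apply(d, 1, function(row) order(row)[2:(k + 1)])  # drop self
  edges <- cbind(rep(seq_len(n), each = k), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  stats::setNames(as.integer(igraph::membership(cl)), rownames(normalized))
}

#' Differential marker abundance between two cell groups
#'
#' Per marker: two-sided Wilcoxon rank-sum test on CLR values between the
#' groups, Benjamini-Hochberg adjustment across markers, and a log2 fold
#' change of group means of `expm1`-backtransformed CLR values (means are
#' floored at `1e-9` before taking the ratio so the fold change is always
#' defined). A marker is flagged significant when `p_adjusted < 0.01` and
#' `log2_fold_change > 1`. A marker constant across both groups is
#' tie-degenerate: its p-value is set to 1.
#'
#' @param normalized CLR matrix
#' @param group_a,group_b row indices or names of the two groups (fold change
#'   is a over b)
#' @param p_cutoff,lfc_cutoff significance cutoffs
#' @return data.frame of class-free results: `marker`, `log2_fold_change`,
#'   `p_value`, `p_adjusted`, `significant`
#' @export
differential_abundance <- function(normalized, group_a, group_b,
                                   p_cutoff = 0.01, lfc_cutoff = 1) {
  xa <- normalized[group_a, , drop = FALSE]
  xb <- normalized[group_b, , drop = FALSE]
  if (nrow(xa) == 0 || nrow(xb) == 0) stop("both groups must be nonempty")
  if (nrow(xa) < 3 || nrow(xb) < 3) {
    warning("group with fewer than 3 cells; tests run but are weakly powered")
  }
  res <- lapply(colnames(normalized), function(m) {
    a <- xa[, m]; b <- xb[, m]
    if (length(unique(c(a, b))) == 1L) {
      p <- 1
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    ma <- max(mean(expm1(a)), 1e-9)
    mb <- max(mean(expm1(b)), 1e-9)
    data.frame(marker = m, log2_fold_change = log2(ma / mb), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < p_cutoff & out$log2_fold_change > lfc_cutoff
  out
}

#' Flag markers confounded by trogocytosis
#'
#' In co-culture data, markers belonging to the target (B-lineage) cells can
#' be pulled onto T cells, confounding surface-marker attribution. Clusters
#' are labeled B-cell-like when their mean CLR level of any `b_markers`
#' exceeds the across-cluster mean by `margin` CLR units; differential
#' abundance of B-like vs the rest is then run and markers passing the usual
#' cutoffs with higher levels in B-like clusters are flagged.
#'
#' @param normalized CLR matrix
#' @param clusters cluster labels from [cluster_cells()]
#' @param b_markers B-lineage anchor markers (default `"CD19"`)
#' @param margin CLR-unit margin for B-likeness (default 1)
#' @param ... passed to [differential_abundance()]
#' @return named logical vector over markers (TRUE = flagged)
#' @export
flag_trogocytosis <- function(normalized, clusters, b_markers = "CD19",
                              margin = 1, ...) {
  b_markers <- intersect(b_markers, colnames(normalized))
  empty <- stats::setNames(rep(FALSE, ncol(normalized)), colnames(normalized))
  if (length(b_markers) == 0) {
    message("no B-lineage anchor markers in matrix; nothing flagged")
    return(empty)
  }
  cl_means <- vapply(b_markers, function(m) {
    tapply(normalized[, m], clusters, mean)
  }, numeric(length(unique(clusters))))
  cl_means <- matrix(cl_means, ncol = length(b_markers),
                     dimnames = list(names(tapply(normalized[, b_markers[1]], clusters, mean)),
                                     b_markers))
  b_like_cl <- rownames(cl_means)[apply(cl_means, 1, function(v) {
    any(v > colMeans(cl_means) + margin)
  })]
  if (length(b_like_cl) == 0 || length(b_like_cl) == nrow(cl_means)) {
    message("no B-cell-like cluster separation found; nothing flagged")
    return(empty)
  }
  in_b <- as.character(clusters) %in% b_like_cl
  de <- differential_abundance(normalized, which(in_b), which(!in_b), ...)
  flags <- empty
  flags[de$marker[de$significant]] <- TRUE
  flags
}

#' Label cells as CD4- or CD8-positive
#'
#' A simple operational rule for phenotype subsetting: CD8-positive when the
#' cell's CLR(CD8) exceeds CLR(CD4), CD4-positive otherwise. The marker
#' names are overridable for panels using different aliases.
#'
#' @param normalized CLR matrix
#' @param cd8,cd4 marker column names
#' @return character vector (`"CD8"`/`"CD4"`), named by cell
#' @export
assign_phenotype <- function(normalized, cd8 = "CD8", cd4 = "CD4") {
  if (!all(c(cd8, cd4) %in% colnames(normalized))) {
    stop("markers ", cd8, " and ", cd4, " must both be in the matrix")
  }
  stats::setNames(ifelse(normalized[, cd8] > normalized[, cd4], "CD8", "CD4"),
                  rownames(normalized))
}
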