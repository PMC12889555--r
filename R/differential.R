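# Condition contrasts on score tables: per-marker differential polarization,
# per-pair differential colocalization, and the Gini variability analysis.

# Join score rows with condition labels. `labels` may be NULL (labels
# already on the scores), or a data.frame with cell_id, condition and
# optionally a phenotype column used for subsetting.
.with_labels <- function(scores, labels, subset = "all") {
  df <- scores
  if (!is.null(labels)) {
    keep <- setdiff(names(labels), setdiff(names(df), "cell_id"))
    df <- merge(df, labels[, unique(c("cell_id", keep)), drop = FALSE],
                by = "cell_id")
  }
  if (!"condition" %in% names(df)) stop("no condition labels available")
  if (!identical(subset, "all")) {
    if (!"phenotype" %in% names(df)) stop("subsetting requires a 'phenotype' column")
    df <- df[df$phenotype == subset, , drop = FALSE]
  }
  df
}

.mann_whitney <- function(za, zc) {
  wt <- suppressWarnings(stats::wilcox.test(zc, za, exact = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Differential polarization between acute and chronic cells
#'
#' Per marker, the per-cell Moran's-I z-scores of the two conditions are
#' compared with a two-sided Mann-Whitney U test. P-values are
#' Bonferroni-adjusted over the number of *tested* markers; a marker is
#' tested when both conditions contribute at least `min_cells` cells with a
#' defined score, and untested markers appear in the output with
#' `tested = FALSE` and NA statistics. Significance requires
#' `p_adjusted < 0.001`; direction is the sign of the chronic - acute median
#' z difference.
#'
#' @param scores polarization score table ([polarization_scores()])
#' @param labels optional data.frame `cell_id`, `condition`
#'   (acute/chronic), and `phenotype` when subsetting
#' @param subset `"all"` or a phenotype level (e.g. `"CD4"`, `"CD8"`)
#' @param min_cells minimum cells per condition per marker (default 2)
#' @param alpha adjusted-p significance cutoff (default 0.001)
#' @return data.frame: `marker`, `subset`, `n_acute`, `n_chronic`,
#'   `median_z_acute`, `median_z_chronic`, `delta_median_z`, `U`, `p_value`,
#'   `p_adjusted`, `significant`, `direction`, `tested`
#' @export
differential_polarization <- function(scores, labels = NULL, subset = "all",
                                      min_cells = 2, alpha = 0.001) {
  df <- .with_labels(scores, labels, subset)
  df <- df[!is.na(df$z_score), , drop = FALSE]
  markers <- sort(unique(scores$marker))
  rows <- lapply(markers, function(m) {
    za <- df$z_score[df$marker == m & df$condition == "acute"]
    zc <- df$z_score[df$marker == m & df$condition == "chronic"]
    base <- data.frame(marker = m, subset = subset,
                       n_acute = length(za), n_chronic = length(zc),
                       stringsAsFactors = FALSE)
    if (length(za) < min_cells || length(zc) < min_cells ||
        length(unique(c(za, zc))) < 2) {
      cbind(base, median_z_acute = NA_real_, median_z_chronic = NA_real_,
            delta_median_z = NA_real_, U = NA_real_, p_value = NA_real_,
            tested = FALSE)
    } else {
      mw <- .mann_whitney(za, zc)
      cbind(base, median_z_acute = stats::median(za),
            median_z_chronic = stats::median(zc),
            delta_median_z = stats::median(zc) - stats::median(za),
            U = mw$U, p_value = mw$p, tested = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  if (!any(out$tested)) message("no markers testable in subset '", subset, "'")
  m_tested <- sum(out$tested)
  out$p_adjusted <- ifelse(out$tested, pmin(1, out$p_value * m_tested), NA_real_)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out$direction <- ifelse(is.na(out$delta_median_z), NA_character_,
                          ifelse(out$delta_median_z >= 0, "up", "down"))
  rownames(out) <- NULL
  out
}

#' Differential colocalization between acute and chronic cells
#'
#' Per unordered marker pair, the per-cell Pearson z-scores of the two
#' conditions are compared with a two-sided Mann-Whitney U test, with
#' Bonferroni adjustment over tested pairs. Significance requires
#' `p_adjusted < 0.001` *and* `|delta_median_z| > 1` (an effect-size gate on
#' the condition contrast).
#'
#' @param scores colocalization score table ([colocalization_scores()])
#' @inheritParams differential_polarization
#' @param delta_cutoff effect-size gate on `|delta_median_z|` (default 1)
#' @return data.frame keyed by `marker_a`, `marker_b` with the same
#'   statistics columns as [differential_polarization()]
#' @export
differential_colocalization <- function(scores, labels = NULL, subset = "all",
                                        min_cells = 2, alpha = 0.001,
                                        delta_cutoff = 1) {
  df <- .with_labels(scores, labels, subset)
  df <- df[!is.na(df$z_score), , drop = FALSE]
  key_all <- unique(scores[, c("marker_a", "marker_b")])
  key_all <- key_all[order(key_all$marker_a, key_all$marker_b), , drop = FALSE]
  dkey <- paste(df$marker_a, df$marker_b, sep = "\r")
  rows <- lapply(seq_len(nrow(key_all)), function(i) {
    k <- paste(key_all$marker_a[i], key_all$marker_b[i], sep = "\r")
    sel <- dkey == k
    za <- df$z_score[sel & df$condition == "acute"]
    zc <- df$z_score[sel & df$condition == "chronic"]
    base <- data.frame(marker_a = key_all$marker_a[i],
                       marker_b = key_all$marker_b[i], subset = subset,
                       n_acute = length(za), n_chronic = length(zc),
                       stringsAsFactors = FALSE)
    if (length(za) < min_cells || length(zc) < min_cells ||
        length(unique(c(za, zc))) < 2) {
      cbind(base, median_z_acute = NA_real_, median_z_chronic = NA_real_,
            delta_median_z = NA_real_, U = NA_real_, p_value = NA_real_,
            tested = FALSE)
    } else {
      mw <- .mann_whitney(za, zc)
      cbind(base, median_z_acute = stats::median(za),
            median_z_chronic = stats::median(zc),
            delta_median_z = stats::median(zc) - stats::median(za),
            U = mw$U, p_value = mw$p, tested = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  m_tested <- sum(out$tested)
  out$p_adjusted <- ifelse(out$tested, pmin(1, out$p_value * m_tested), NA_real_)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha &
    abs(out$delta_median_z) > delta_cutoff
  out$direction <- ifelse(is.na(out$delta_median_z), NA_character_,
                          ifelse(out$delta_median_z >= 0, "up", "down"))
  rownames(out) <- NULL
  out
}

# Gini of a z-score vector shifted to nonnegativity by the pooled minimum.
.gini_shifted <- function(z, shift) {
  x <- z - shift
  if (all(x == 0)) return(0)
  gini(x)
}

#' Variability analysis of polarization scores
#'
#' Tests, per marker, whether the cell-to-cell dispersion of polarization
#' z-scores differs between conditions. The statistic is
#' `gini(chronic) - gini(acute)` on z-scores shifted to nonnegativity by the
#' pooled minimum. Two nulls are evaluated: (1) `n_perm` acute/chronic label
#' permutations preserving group sizes; (2) `n_perm` Monte-Carlo resamples
#' drawing both groups with replacement from the pooled background scores
#' (which, being exchangeable draws, exclude the observed assignment
#' ordering). Both p-values use the add-one estimator
#' `(1 + #{|stat| >= |observed|}) / (n_perm + 1)`; the reported p is their
#' maximum (conservative), adjusted across markers with Benjamini-Hochberg.
#' Significance requires `p_adjusted < 0.01`.
#'
#' @inheritParams differential_polarization
#' @param n_perm permutations and resamples per null (default 2000)
#' @param seed RNG seed
#' @param min_cells minimum cells per condition per marker (default 5)
#' @param alpha adjusted-p cutoff (default 0.01)
#' @return data.frame: `marker`, `subset`, `gini_acute`, `gini_chronic`,
#'   `observed_stat`, `p_permutation`, `p_montecarlo`, `p_value`,
#'   `p_adjusted`, `significant`, `tested`
#' @export
variability_test <- function(scores, labels = NULL, subset = "all",
                             n_perm = 2000, seed = 7L, min_cells = 5,
                             alpha = 0.01) {
  df <- .with_labels(scores, labels, subset)
  df <- df[!is.na(df$z_score), , drop = FALSE]
  markers <- sort(unique(scores$marker))
  rows <- lapply(seq_along(markers), function(mi) {
    m <- markers[mi]
    za <- df$z_score[df$marker == m & df$condition == "acute"]
    zc <- df$z_score[df$marker == m & df$condition == "chronic"]
    base <- data.frame(marker = m, subset = subset, stringsAsFactors = FALSE)
    if (length(za) < min_cells || length(zc) < min_cells ||
        length(unique(c(za, zc))) < 2) {
      return(cbind(base, gini_acute = NA_real_, gini_chronic = NA_real_,
                   observed_stat = NA_real_, p_permutation = NA_real_,
                   p_montecarlo = NA_real_, p_value = NA_real_, tested = FALSE))
    }
    pool <- c(za, zc)
    shift <- min(pool)
    na <- length(za); nc <- length(zc); n <- na + nc
    g_a <- .gini_shifted(za, shift)
    g_c <- .gini_shifted(zc, shift)
    obs <- g_c - g_a
    stats_pm <- with_seed(derive_seed(seed, 1L, mi), {
      vapply(seq_len(n_perm), function(k) {
        idx <- sample.int(n, na)
        .gini_shifted(pool[-idx], shift) - .gini_shifted(pool[idx], shift)
      }, numeric(1))
    })
    stats_mc <- with_seed(derive_seed(seed, 2L, mi), {
      vapply(seq_len(n_perm), function(k) {
        ra <- pool[sample.int(n, na, replace = TRUE)]
        rc <- pool[sample.int(n, nc, replace = TRUE)]
        sh <- min(ra, rc)
        .gini_shifted(rc, sh) - .gini_shifted(ra, sh)
      }, numeric(1))
    })
    p_pm <- (1 + sum(abs(stats_pm) >= abs(obs))) / (n_perm + 1)
    p_mc <- (1 + sum(abs(stats_mc) >= abs(obs))) / (n_perm + 1)
    cbind(base, gini_acute = g_a, gini_chronic = g_c, observed_stat = obs,
          p_permutation = p_pm, p_montecarlo = p_mc,
          p_value = max(p_pm, p_mc), tested = TRUE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  out$p_adjusted[out$tested] <- stats::p.adjust(out$p_value[out$tested], "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Summarize significant results
#'
#' For a single differential result table: the significant count, the
#' denominator (by default the number of rows, i.e. the panel markers or all
#' candidate pairs) and the percentage rendered to one decimal place. For a
#' *named list* of result tables (one per subset), additionally reports each
#' subset's uniquely significant items (significant there and in no other
#' subset).
#'
#' @param results a differential result data.frame, or a named list of them
#' @param n_total optional denominator override
#' @return for a single table: list with `n_significant`, `n_total`,
#'   `percent` (numeric) and `label` (e.g. `"46.1%"`); for a list: a
#'   data.frame with one row per subset plus unique-significance columns
#' @export
summarize_significance <- function(results, n_total = NULL) {
  item_key <- function(df) {
    if (all(c("marker_a", "marker_b") %in% names(df))) {
      paste(df$marker_a, df$marker_b, sep = "/")
    } else df$marker
  }
  if (is.data.frame(results)) {
    k <- sum(results$significant, na.rm = TRUE)
    n <- n_total %||% nrow(results)
    return(list(n_significant = k, n_total = n, percent = 100 * k / n,
                label = format_percent(k, n)))
  }
  stopifnot(is.list(results), !is.null(names(results)))
  sig_sets <- lapply(results, function(df) item_key(df)[which(df$significant)])
  rows <- lapply(names(results), function(nm) {
    df <- results[[nm]]
    k <- length(sig_sets[[nm]])
    n <- n_total %||% nrow(df)
    others <- unlist(sig_sets[setdiff(names(results), nm)], use.names = FALSE)
    uniq <- setdiff(sig_sets[[nm]], others)
    data.frame(subset = nm, n_significant = k, n_total = n,
               percent_of_total = 100 * k / n,
               label = format_percent(k, n),
               n_unique = length(uniq),
               percent_unique = if (k > 0) 100 * length(uniq) / k else 0,
               unique_label = if (k > 0) format_percent(length(uniq), k) else "0.0%",
               unique_items = paste(sort(uniq), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signed-significance matrix for colocalization results
#'
#' A symmetric markers x markers matrix with +1 for pairs significantly
#' increased in chronic, -1 for significantly decreased, 0 otherwise --
#' the input for clustermap-style displays.
#'
#' @param diff_coloc a [differential_colocalization()] result
#' @param markers optional marker universe (default: markers in the table)
#' @return integer matrix
#' @export
significance_matrix <- function(diff_coloc, markers = NULL) {
  markers <- markers %||% sort(unique(c(diff_coloc$marker_a, diff_coloc$marker_b)))
  m <- matrix(0L, length(markers), length(markers),
              dimnames = list(markers, markers))
  sig <- diff_coloc[which(diff_coloc$significant), , drop = FALSE]
  if (nrow(sig)) {
    s <- ifelse(sig$delta_median_z >= 0, 1L, -1L)
    m[cbind(sig$marker_a, sig$marker_b)] <- s
    m[cbind(sig$marker_b, sig$marker_a)] <- s
  }
  m
}
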