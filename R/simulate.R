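# Synthetic edge-list generator: unit-sphere cells with von Mises-Fisher
# marker hotspots, read out as bipartite A-pixel/B-pixel edge lists.

# n points uniform on the unit sphere, as an n x 3 matrix.
sphere_uniform <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# n points on a golden-angle (Fibonacci) spiral: a low-discrepancy layout
# whose points carry near-equal capture areas. Used as the default pixel
# layout so that, with zero polarization, per-pixel counts are exchangeable:
# fully random pixel placement produces a spatially autocorrelated capture
# area field (sparse regions have large cells whose neighbors are also
# large), which reads out as spurious positive Moran's I at high event depth.
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 + sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# A uniformly random 3D rotation (QR of a Gaussian matrix, det-corrected).
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Pixel coordinates according to the configured layout. The lattice is
# randomly rotated per call so distinct cells see distinct geometry.
place_pixels <- function(n, layout) {
  switch(layout,
         random = sphere_uniform(n),
         lattice = sphere_lattice(n) %*% random_rotation(),
         stop("unknown pixel layout: ", layout))
}

# von Mises-Fisher sample on S^2 about mean direction mu, concentration kappa.
# W (cosine to mu) is drawn by inversion of its closed-form CDF; the azimuth
# is uniform; the frame is rotated from the z-axis onto mu (Rodrigues).
rvmf <- function(n, mu, kappa) {
  if (n == 0) return(matrix(numeric(), 0, 3))
  if (kappa < 1e-12) return(sphere_uniform(n))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- pmin(1, pmax(-1, w))
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  x <- cbind(s * cos(phi), s * sin(phi), w)
  rotate_from_pole(x, mu)
}

# Rotate points so the +z pole maps onto unit vector mu.
rotate_from_pole <- function(x, mu) {
  mu <- mu / sqrt(sum(mu^2))
  cz <- mu[3]
  if (cz > 1 - 1e-12) return(x)
  if (cz < -1 + 1e-12) return(cbind(x[, 1], -x[, 2], -x[, 3]))
  a <- c(-mu[2], mu[1], 0)               # axis = z cross mu
  a <- a / sqrt(sum(a^2))
  st <- sqrt(1 - cz^2)
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + st * K + (1 - cz) * (K %*% K)
  x %*% t(R)
}

# Per-cell hotspot centers for every marker; coloc_pairs may overwrite
# marker_b's center with marker_a's (probability = the pair's sharing level).
.hotspot_centers <- function(config, condition) {
  centers <- sphere_uniform(length(config$markers))
  rownames(centers) <- config$markers
  cp <- config$coloc_pairs
  if (nrow(cp)) {
    scol <- paste0("sharing_", condition)
    share <- stats::runif(nrow(cp)) < cp[[scol]]
    for (i in which(share)) {
      centers[cp$marker_b[i], ] <- centers[cp$marker_a[i], ]
    }
  }
  centers
}

#' Simulate one cell's binding-event edge list
#'
#' Places pixels on the unit sphere per the configured layout, draws
#' `n_events_per_cell`
#' binding events (marker from the condition's abundance weights; location
#' from a uniform/von Mises-Fisher mixture), attaches each event to the
#' nearest A-pixel and nearest B-pixel within the capture radius, and emits
#' one edge record per kept event with a fresh sequential UMI. Duplicate
#' reads (verbatim record repeats) are appended at `duplicate_read_rate`.
#' Fully deterministic given `(config$seed, condition, cell_index)`.
#'
#' @param config a [simulation_config()]
#' @param condition `"acute"` or `"chronic"`
#' @param cell_index integer; distinct indices give independent cells
#' @param id_prefix prefix for pixel identifiers (defaults to
#'   `"c<cell_index>_"`), used to keep cells in disjoint graph components
#' @return list with `edges` (data.frame `upia`, `upib`, `umi`, `marker`) and
#'   `truth` (condition, per-marker kept counts, drop count, hotspot centers)
#' @export
simulate_cell <- function(config, condition, cell_index, id_prefix = NULL) {
  stopifnot(inherits(config, "pixel_sim_config"))
  condition <- match.arg(condition, c("acute", "chronic"))
  if (is.null(id_prefix)) id_prefix <- sprintf("c%d_", cell_index)
  seed <- derive_seed(config$seed, condition_code(condition), cell_index)
  with_seed(seed, .simulate_cell_impl(config, condition, id_prefix))
}

.simulate_cell_impl <- function(config, condition, id_prefix) {
  markers <- config$markers
  n_ev <- config$n_events_per_cell
  w <- config$abundance[[condition]]
  kappa <- config$polarization_kappa[[condition]]

  A <- place_pixels(config$n_a_pixels, config$pixel_layout)
  B <- place_pixels(config$n_b_pixels, config$pixel_layout)
  centers <- .hotspot_centers(config, condition)

  mk <- sample(markers, n_ev, replace = TRUE, prob = w)
  kap_ev <- kappa[mk]
  in_hot <- stats::runif(n_ev) < kap_ev / (kap_ev + 2)

  loc <- matrix(0, n_ev, 3)
  if (any(!in_hot)) loc[!in_hot, ] <- sphere_uniform(sum(!in_hot))
  for (m in unique(mk[in_hot])) {
    idx <- which(in_hot & mk == m)
    loc[idx, ] <- rvmf(length(idx), centers[m, ], kappa[m])
  }

  cos_r <- cos(config$capture_radius)
  SA <- loc %*% t(A)                       # cosine similarity event x pixel
  ia <- max.col(SA, ties.method = "first") # nearest A-pixel, lowest index on ties
  ok_a <- SA[cbind(seq_len(n_ev), ia)] >= cos_r
  SB <- loc %*% t(B)
  ib <- max.col(SB, ties.method = "first")
  ok_b <- SB[cbind(seq_len(n_ev), ib)] >= cos_r
  keep <- ok_a & ok_b

  n_kept <- sum(keep)
  if (n_ev > 0 && n_kept < 0.5 * n_ev) {
    warning(sprintf("capture_radius drops %.0f%% of events", 100 * (1 - n_kept / n_ev)))
  }

  edges <- data.frame(
    upia = sprintf("%sA%04d", id_prefix, ia[keep]),
    upib = sprintf("%sB%04d", id_prefix, ib[keep]),
    umi = sprintf("u%06d", seq_len(n_kept)),
    marker = mk[keep],
    stringsAsFactors = FALSE
  )
  if (config$duplicate_read_rate > 0 && n_kept > 0) {
    dup <- stats::runif(n_kept) < config$duplicate_read_rate
    edges <- rbind(edges, edges[dup, , drop = FALSE])
    rownames(edges) <- NULL
  }

  counts <- table(factor(mk[keep], levels = markers))
  truth <- list(
    condition = condition,
    marker_counts = stats::setNames(as.integer(counts), markers),
    n_events = n_ev,
    n_kept = n_kept,
    n_dropped = n_ev - n_kept,
    hotspot_centers = centers
  )
  list(edges = edges, truth = truth)
}

# A small connected bipartite debris component (below the calling threshold).
# A zig-zag path over all pixels guarantees connectivity; remaining edges are
# random A-B pairs.
.simulate_debris_component <- function(config, condition, n_edges, id_prefix) {
  n_a <- max(1L, ceiling(n_edges / 4))
  n_b <- max(1L, ceiling(n_edges / 4))
  a_ids <- sprintf("%sA%03d", id_prefix, seq_len(n_a))
  b_ids <- sprintf("%sB%03d", id_prefix, seq_len(n_b))
  n_path <- n_a + n_b - 1L
  ia_path <- ceiling(seq_len(n_path) / 2)
  ib_path <- floor(seq_len(n_path) / 2) + 1L
  ia_path <- pmin(ia_path, n_a); ib_path <- pmin(ib_path, n_b)
  n_extra <- max(0L, n_edges - n_path)
  ia <- c(ia_path, sample.int(n_a, n_extra, replace = TRUE))
  ib <- c(ib_path, sample.int(n_b, n_extra, replace = TRUE))
  ia <- ia[seq_len(n_edges)]; ib <- ib[seq_len(n_edges)]
  data.frame(
    upia = a_ids[ia],
    upib = b_ids[ib],
    umi = sprintf("u%06d", seq_len(n_edges)),
    marker = sample(config$markers, n_edges, replace = TRUE,
                    prob = config$abundance[[condition]]),
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-donor experiment and write it to disk
#'
#' Generates `n_cells_per_condition` cells for every donor x condition
#' sample, adds `n_debris_components` small disconnected bipartite components
#' per sample, and writes one tab-separated edge list per sample plus a
#' sample sheet, a panel file, and the ground truth (JSON). Cells of distinct
#' samples never share pixel identifiers.
#'
#' @param config a [simulation_config()]
#' @param n_donors number of donors (each contributes one acute and one
#'   chronic sample)
#' @param dir output directory (created if missing)
#' @param parquet also write a columnar (parquet) mirror of each edge list;
#'   requires the `arrow` package
#' @return invisibly, a list with `sample_sheet`, `panel`, `truth` and file
#'   `paths`
#' @export
simulate_experiment <- function(config, n_donors, dir, parquet = FALSE) {
  stopifnot(inherits(config, "pixel_sim_config"), n_donors >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  panel <- data.frame(
    marker = config$markers,
    is_control = as.integer(config$markers %in% config$control_markers),
    stringsAsFactors = FALSE
  )
  panel_path <- file.path(dir, "panel.tsv")
  write_panel(panel, panel_path)

  sheet <- list(); truth_cells <- list(); paths <- character()
  sample_no <- 0L
  for (donor in seq_len(n_donors)) {
    for (condition in c("acute", "chronic")) {
      sample_no <- sample_no + 1L
      sample_id <- sprintf("d%d_%s", donor, condition)
      parts <- vector("list", config$n_cells_per_condition + 1L)
      for (j in seq_len(config$n_cells_per_condition)) {
        cell_index <- (sample_no - 1L) * config$n_cells_per_condition + j
        prefix <- sprintf("%s_c%04d_", sample_id, j)
        sim <- simulate_cell(config, condition, cell_index, id_prefix = prefix)
        parts[[j]] <- sim$edges
        truth_cells[[paste0(sample_id, sprintf("_c%04d", j))]] <- c(
          sim$truth[c("condition", "marker_counts", "n_events", "n_kept", "n_dropped")],
          list(donor = donor, sample_id = sample_id)
        )
      }
      debris_seed <- derive_seed(config$seed, 7L, sample_no)
      parts[[config$n_cells_per_condition + 1L]] <- with_seed(debris_seed, {
        do.call(rbind, lapply(seq_len(config$n_debris_components), function(k) {
          ne <- sample(seq(config$debris_edge_range[1], config$debris_edge_range[2]), 1)
          .simulate_debris_component(config, condition, ne,
                                     sprintf("%s_dbr%03d_", sample_id, k))
        }))
      })
      edges <- data.table::rbindlist(parts)
      path <- file.path(dir, paste0(sample_id, ".tsv"))
      tryCatch(data.table::fwrite(edges, path, sep = "\t"),
               error = function(e) stop("failed to write ", path, ": ", conditionMessage(e)))
      if (parquet) {
        if (!requireNamespace("arrow", quietly = TRUE)) {
          stop("parquet mirror requires the 'arrow' package")
        }
        arrow::write_parquet(edges, sub("\\.tsv$", ".parquet", path))
      }
      paths <- c(paths, path)
      sheet[[sample_id]] <- data.frame(
        sample_id = sample_id, donor = sprintf("donor%d", donor),
        condition = condition, replicate = 1L, path = path,
        stringsAsFactors = FALSE
      )
    }
  }
  sample_sheet <- do.call(rbind, sheet)
  rownames(sample_sheet) <- NULL
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  data.table::fwrite(sample_sheet, sheet_path, sep = "\t")

  kap <- config$polarization_kappa
  cp <- config$coloc_pairs
  truth <- list(
    cells = truth_cells,
    polarization_differs = stats::setNames(
      kap$acute != kap$chronic, config$markers),
    colocalization_differs = if (nrow(cp)) {
      stats::setNames(cp$sharing_acute != cp$sharing_chronic,
                      paste(cp$marker_a, cp$marker_b, sep = "/"))
    } else stats::setNames(logical(), character())
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(sample_sheet = sample_sheet, panel = panel, truth = truth,
                 paths = list(samples = paths, sample_sheet = sheet_path,
                              panel = panel_path, truth = truth_path)))
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `donor`, `condition`, `replicate`,
#' `path`.
#' @param path file path
#' @return data.frame
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "donor", "condition", "replicate", "path")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  df
}
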