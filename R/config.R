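#' Simulation configuration for synthetic pixel-graph experiments
#'
#' Defines the generative model for synthetic antibody binding-event edge
#' lists. Each simulated cell is a unit sphere carrying `n_a_pixels` A-pixels
#' and `n_b_pixels` B-pixels (layout per `pixel_layout`). Binding events draw
#' a marker from condition-specific abundance weights and a surface location
#' from a mixture of the uniform sphere and a marker-specific von Mises-Fisher
#' hotspot; the hotspot mixture weight is `kappa / (kappa + 2)` so that
#' `polarization_kappa = 0` gives a fully uniform (unpolarized) marker and
#' increasing kappa both sharpens and loads the hotspot. Events attach to the
#' nearest A-pixel and nearest B-pixel within `capture_radius` (great-circle
#' angle); events with no pixel in range are dropped.
#'
#' @param markers character vector of panel marker names (targets + controls)
#' @param control_markers subset of `markers` flagged as isotype controls
#' @param n_cells_per_condition cells simulated per donor and per condition
#' @param abundance per-condition relative abundance weights: a named numeric
#'   vector recycled to both conditions, or `list(acute = ..., chronic = ...)`
#'   of named vectors. Unnamed markers get weight 1. Weights must be
#'   nonnegative with a positive sum per condition.
#' @param polarization_kappa per-marker, per-condition von Mises-Fisher
#'   concentration: named numeric vector (both conditions) or
#'   `list(acute = ..., chronic = ...)`. Missing markers default to 0
#'   (uniform).
#' @param coloc_pairs data.frame with columns `marker_a`, `marker_b` and
#'   either `sharing` or `sharing_acute`/`sharing_chronic` in \[0, 1\]: the
#'   probability that `marker_b`'s hotspot center is replaced by
#'   `marker_a`'s in a given cell, inducing colocalization.
#' @param n_a_pixels,n_b_pixels pixels per cell
#' @param n_events_per_cell binding events drawn per cell (before drop-out
#'   and duplicate injection)
#' @param capture_radius angular capture radius in radians linking an event
#'   to pixels
#' @param n_debris_components small non-cell components added per sample
#' @param debris_edge_range integer interval (length 2) for debris edge counts
#' @param duplicate_read_rate probability that an emitted record is repeated
#'   verbatim (sequencing duplicate)
#' @param pixel_layout `"lattice"` (default): pixels on a randomly rotated
#'   golden-angle spiral, giving near-equal capture areas so that
#'   zero-kappa markers are genuinely unpolarized; `"random"`: fully uniform
#'   random placement, whose spatially autocorrelated capture-area field
#'   adds a positive polarization baseline at high event depth
#' @param seed base integer seed; all randomness derives from it
#' @return an object of class `pixel_sim_config`
#' @export
#' @examples
#' cfg <- simulation_config(markers = c("CD3E", "CD4", "mIgG1"),
#'                          control_markers = "mIgG1",
#'                          n_cells_per_condition = 2,
#'                          n_events_per_cell = 500,
#'                          n_a_pixels = 60, n_b_pixels = 60)
simulation_config <- function(markers,
                              control_markers = character(),
                              n_cells_per_condition = 50,
                              abundance = NULL,
                              polarization_kappa = NULL,
                              coloc_pairs = NULL,
                              n_a_pixels = 300,
                              n_b_pixels = 300,
                              n_events_per_cell = 12000,
                              capture_radius = 0.3,
                              n_debris_components = 10,
                              debris_edge_range = c(10, 100),
                              duplicate_read_rate = 0.1,
                              pixel_layout = c("lattice", "random"),
                              seed = 1L) {
  pixel_layout <- match.arg(pixel_layout)
  markers <- as.character(markers)
  if (anyDuplicated(markers)) stop("duplicate marker names")
  if (!all(control_markers %in% markers)) stop("control_markers must be a subset of markers")
  if (capture_radius <= 0) stop("capture_radius must be > 0")
  if (duplicate_read_rate < 0 || duplicate_read_rate > 1) stop("duplicate_read_rate must be in [0,1]")
  stopifnot(n_cells_per_condition >= 0, n_a_pixels >= 1, n_b_pixels >= 1,
            n_events_per_cell >= 0, n_debris_components >= 0,
            length(debris_edge_range) == 2,
            debris_edge_range[1] >= 1, debris_edge_range[2] >= debris_edge_range[1])

  abundance <- .per_condition(abundance, markers, default = 1)
  for (cond in names(abundance)) {
    w <- abundance[[cond]]
    if (any(w < 0)) stop("abundance weights must be nonnegative")
    if (sum(w) <= 0) stop("total abundance weight is zero for condition ", cond)
  }
  kappa <- .per_condition(polarization_kappa, markers, default = 0)
  for (cond in names(kappa)) {
    if (any(kappa[[cond]] < 0)) stop("polarization_kappa must be nonnegative")
  }
  coloc_pairs <- .normalize_coloc_pairs(coloc_pairs, markers)

  structure(list(
    markers = markers,
    control_markers = as.character(control_markers),
    n_cells_per_condition = as.integer(n_cells_per_condition),
    abundance = abundance,
    polarization_kappa = kappa,
    coloc_pairs = coloc_pairs,
    n_a_pixels = as.integer(n_a_pixels),
    n_b_pixels = as.integer(n_b_pixels),
    n_events_per_cell = as.integer(n_events_per_cell),
    capture_radius = as.numeric(capture_radius),
    n_debris_components = as.integer(n_debris_components),
    debris_edge_range = as.integer(debris_edge_range),
    duplicate_read_rate = as.numeric(duplicate_read_rate),
    pixel_layout = pixel_layout,
    seed = as.integer(seed)
  ), class = "pixel_sim_config")
}

# Expand a per-marker spec (NULL, named vector, or list(acute=, chronic=))
# into a list of full named vectors, one per condition.
.per_condition <- function(x, markers, default) {
  expand <- function(v) {
    out <- stats::setNames(rep(default, length(markers)), markers)
    if (!is.null(v)) {
      if (is.null(names(v))) stop("per-marker values must be named")
      bad <- setdiff(names(v), markers)
      if (length(bad)) stop("unknown markers: ", paste(bad, collapse = ", "))
      out[names(v)] <- as.numeric(v)
    }
    out
  }
  if (is.list(x) && !is.data.frame(x)) {
    list(acute = expand(x$acute), chronic = expand(x$chronic))
  } else {
    list(acute = expand(x), chronic = expand(x))
  }
}

.normalize_coloc_pairs <- function(cp, markers) {
  if (is.null(cp) || nrow(as.data.frame(cp)) == 0) {
    return(data.frame(marker_a = character(), marker_b = character(),
                      sharing_acute = numeric(), sharing_chronic = numeric(),
                      stringsAsFactors = FALSE))
  }
  cp <- as.data.frame(cp)
  if (!all(c("marker_a", "marker_b") %in% names(cp))) {
    stop("coloc_pairs needs columns marker_a, marker_b")
  }
  if ("sharing" %in% names(cp)) {
    cp$sharing_acute <- cp$sharing
    cp$sharing_chronic <- cp$sharing
  }
  if (!all(c("sharing_acute", "sharing_chronic") %in% names(cp))) {
    stop("coloc_pairs needs 'sharing' or 'sharing_acute' + 'sharing_chronic'")
  }
  bad <- setdiff(c(cp$marker_a, cp$marker_b), markers)
  if (length(bad)) stop("coloc_pairs references unknown markers: ", paste(bad, collapse = ", "))
  s <- c(cp$sharing_acute, cp$sharing_chronic)
  if (any(s < 0 | s > 1)) stop("hotspot sharing must be in [0,1]")
  if (any(cp$marker_a == cp$marker_b)) stop("coloc_pairs must not contain self-pairs")
  cp[, c("marker_a", "marker_b", "sharing_acute", "sharing_chronic")]
}

#' @export
print.pixel_sim_config <- function(x, ...) {
  cat("pixel_sim_config:", length(x$markers), "markers (",
      length(x$control_markers), "controls ),",
      x$n_cells_per_condition, "cells/condition,",
      x$n_events_per_cell, "events/cell,",
      x$n_a_pixels, "A-pixels,", x$n_b_pixels, "B-pixels\n")
  invisible(x)
}
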