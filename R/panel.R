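#' Default antibody panel
#'
#' An 80-plex panel of 76 surface-protein targets plus 4 isotype controls,
#' typical of immune-cell surface-proteome assays. Target names follow CD
#' nomenclature; controls are isotype antibodies with no human target and are
#' excluded from polarization and colocalization testing.
#'
#' @return a data.frame with columns `marker` (character) and `is_control`
#'   (integer, 0/1)
#' @export
#' @examples
#' panel <- default_panel()
#' sum(panel$is_control == 0)  # 76 targets
default_panel <- function() {
  targets <- c(
    "CD2", "CD3E", "CD4", "CD5", "CD6", "CD7", "CD8", "CD9",
    "CD11a", "CD11b", "CD11c", "CD14", "CD16", "CD18", "CD19", "CD20",
    "CD22", "CD25", "CD26", "CD27", "CD28", "CD29", "CD31", "CD33",
    "CD35", "CD36", "CD37", "CD38", "CD40", "CD43", "CD44", "CD45",
    "CD45RA", "CD45RB", "CD47", "CD48", "CD49d", "CD50", "CD52", "CD53",
    "CD54", "CD55", "CD58", "CD59", "CD62L", "CD63", "CD69", "CD71",
    "CD72", "CD82", "CD84", "CD102", "CD107a", "CD137", "CD150", "CD161",
    "CD162", "CD163", "CD200", "CD226", "CD229", "CD244", "CD278", "CD279",
    "CD366", "HLA-ABC", "HLA-DR", "B2M", "TCRab", "NGFR", "CD49a", "CD49b",
    "CD101", "CD152", "CD223", "CD314"
  )
  controls <- c("mIgG1", "mIgG2a", "mIgG2b", "rIgG2b")
  data.frame(
    marker = c(targets, controls),
    is_control = c(rep(0L, length(targets)), rep(1L, length(controls))),
    stringsAsFactors = FALSE
  )
}

#' Read or write a panel file
#'
#' The panel file is tab-separated with header `marker<TAB>is_control`,
#' `is_control` in {0, 1}.
#'
#' @param path file path
#' @return `read_panel()` returns the panel data.frame.
#' @export
read_panel <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "marker"))
  need <- c("marker", "is_control")
  if (!all(need %in% names(dt))) {
    stop("panel file ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(dt[, need, with = FALSE])
  df$is_control <- as.integer(df$is_control)
  if (anyDuplicated(df$marker)) stop("duplicate markers in panel file ", path)
  if (!all(df$is_control %in% c(0L, 1L))) stop("is_control must be 0 or 1")
  df
}

#' @rdname read_panel
#' @param panel a panel data.frame
#' @export
write_panel <- function(panel, path) {
  data.table::fwrite(panel, path, sep = "\t")
  invisible(path)
}

# Markers eligible for spatial testing: panel targets, controls removed.
target_markers <- function(panel) {
  panel$marker[panel$is_control == 0L]
}

#' Enumerate unordered marker pairs
#'
#' All m(m-1)/2 unordered pairs of non-control markers, in canonical
#' lexicographic order (`marker_a` < `marker_b`). Self-pairs are never
#' included; pairwise colocalization of a marker with itself is the domain of
#' polarization analysis.
#'
#' @param panel panel data.frame, or a character vector of marker names
#' @return data.frame with columns `marker_a`, `marker_b`
#' @export
#' @examples
#' nrow(marker_pairs(default_panel()))  # 76 targets -> 2850 pairs
marker_pairs <- function(panel) {
  markers <- if (is.data.frame(panel)) target_markers(panel) else as.character(panel)
  markers <- sort(unique(markers))
  m <- length(markers)
  if (m < 2) return(data.frame(marker_a = character(), marker_b = character()))
  idx <- utils::combn(m, 2)
  data.frame(marker_a = markers[idx[1, ]], marker_b = markers[idx[2, ]],
             stringsAsFactors = FALSE)
}
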