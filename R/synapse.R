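# Immune-synapse interpretation of differential colocalization: zone maps
# (cSMAC / pSMAC / dSMAC) and anchor-centric partner tables.

.zone_levels <- c("cSMAC", "pSMAC", "dSMAC", "general", "unknown")

#' Load an immune-synapse zone map
#'
#' Reads a YAML file mapping zone names (`cSMAC`, `pSMAC`, `dSMAC`,
#' `general`) to marker lists. A marker may appear in at most one zone;
#' panel markers not listed are assigned to `"unknown"`. With no path, the
#' packaged default map is used (anchors CD3E, CD11a and CD44 plus the
#' adhesion partners placed in the pSMAC).
#'
#' @param path YAML file, or `NULL` for the packaged default
#' @param panel optional panel data.frame; its unlisted markers are added to
#'   `"unknown"`
#' @return named character vector: marker -> zone (class `zone_map`)
#' @export
load_zone_map <- function(path = NULL, panel = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "zones.yaml", package = "pixelpol")
  }
  raw <- yaml::read_yaml(path)
  raw <- raw[lengths(raw) > 0]
  bad_zone <- setdiff(names(raw), .zone_levels)
  if (length(bad_zone)) stop("unknown zone name(s): ", paste(bad_zone, collapse = ", "))
  zones <- rep(names(raw), lengths(raw))
  markers <- unlist(raw, use.names = FALSE)
  dup <- unique(markers[duplicated(markers)])
  if (length(dup)) {
    stop("marker(s) assigned to more than one zone: ", paste(dup, collapse = ", "))
  }
  map <- stats::setNames(zones, markers)
  if (!is.null(panel)) {
    missing <- setdiff(panel$marker, names(map))
    map <- c(map, stats::setNames(rep("unknown", length(missing)), missing))
  }
  structure(map, class = "zone_map")
}

#' @rdname load_zone_map
#' @export
default_zone_map <- function(panel = NULL) {
  load_zone_map(NULL, panel = panel)
}

#' Anchor-centric partner table
#'
#' Restricts a differential colocalization table to the significant pairs
#' involving one anchor marker (e.g. CD3E for the cSMAC), annotates each
#' partner with its synapse zone, and sorts by `|delta_median_z|`
#' descending. The tables for all anchors together cover every significant
#' pair touching any anchor, once per anchor it touches.
#'
#' @param diff_coloc a [differential_colocalization()] result
#' @param zone_map a [load_zone_map()] result
#' @param anchor anchor marker name
#' @param panel optional panel data.frame used to validate the anchor
#' @return data.frame: `anchor`, `partner`, `partner_zone`,
#'   `delta_median_z`, `p_adjusted`, `direction`
#' @export
anchor_partners <- function(diff_coloc, zone_map, anchor, panel = NULL) {
  universe <- if (!is.null(panel)) panel$marker else
    unique(c(diff_coloc$marker_a, diff_coloc$marker_b, names(zone_map)))
  if (!anchor %in% universe) stop("anchor marker not in panel: ", anchor)
  sig <- diff_coloc[which(diff_coloc$significant &
                            (diff_coloc$marker_a == anchor |
                               diff_coloc$marker_b == anchor)), , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(anchor = character(), partner = character(),
                      partner_zone = character(), delta_median_z = numeric(),
                      p_adjusted = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  partner <- ifelse(sig$marker_a == anchor, sig$marker_b, sig$marker_a)
  zone <- unname(ifelse(partner %in% names(zone_map),
                        zone_map[partner], "unknown"))
  out <- data.frame(anchor = anchor, partner = partner, partner_zone = zone,
                    delta_median_z = sig$delta_median_z,
                    p_adjusted = sig$p_adjusted, direction = sig$direction,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta_median_z), out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}
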