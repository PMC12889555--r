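# Pixel-graph reconstruction: edge-list parsing, UMI deduplication,
# connected-component partitioning and cell calling.

#' Parse an edge-list file
#'
#' Reads a tab-separated edge list with header
#' `upia<TAB>upib<TAB>umi<TAB>marker`. Rows whose marker is absent from the
#' panel (case-sensitive exact match) are rejected; the rejection count is
#' reported as a message. Rows with empty pixel identifiers are a parse
#' error.
#'
#' @param path edge-list file
#' @param panel panel data.frame (see [read_panel()])
#' @return data.frame of edge records (`upia`, `upib`, `umi`, `marker`)
#' @export
parse_edge_list <- function(path, panel) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  need <- c("upia", "upib", "umi", "marker")
  if (!identical(names(dt)[seq_along(need)], need)) {
    stop("malformed edge list ", path, ": expected header ",
         paste(need, collapse = "\t"))
  }
  dt <- dt[, need, with = FALSE]
  bad <- which(dt$upia == "" | dt$upib == "" | dt$umi == "" | is.na(dt$upia) |
                 is.na(dt$upib) | is.na(dt$umi))
  if (length(bad)) {
    stop("malformed edge list ", path, ": empty field at data line ", bad[1])
  }
  off <- !(dt$marker %in% panel$marker)
  if (any(off)) {
    message(sum(off), " record(s) with off-panel markers rejected from ", basename(path))
    dt <- dt[!off]
  }
  as.data.frame(dt)
}

#' Deduplicate binding events
#'
#' Collapses exact duplicate records (identical `upia`, `upib`, `umi`,
#' `marker` tuples) to a single record, the UMI semantics of unique-event
#' counting. The result is returned in canonical sort order so it does not
#' depend on input order; the operation is idempotent.
#'
#' @param records edge-record data.frame
#' @return deduplicated data.frame
#' @export
dedupe_events <- function(records) {
  dt <- data.table::as.data.table(records)
  dt <- unique(dt, by = c("upia", "upib", "umi", "marker"))
  data.table::setorder(dt, upia, upib, umi, marker)
  out <- as.data.frame(dt)
  rownames(out) <- NULL
  out
}

#' Partition edge records into graph components
#'
#' Builds the bipartite multigraph over A- and B-pixel identifiers and
#' partitions it into connected components. Optionally, components larger
#' than `size_ceiling` edges are refined by Leiden modularity clustering on
#' the simple graph (the recovery path for merged cells / doublets);
#' refinement is off by default. Components are returned sorted by
#' decreasing edge count (ties by first A-pixel name).
#'
#' @param records deduplicated edge records
#' @param size_ceiling edge count above which a component is re-clustered
#'   (default `Inf`: no refinement)
#' @param resolution Leiden resolution for refinement
#' @param seed RNG seed for the (stochastic) refinement pass
#' @return list of components; each has `edges`, `a_nodes`, `b_nodes`,
#'   `n_edges`
#' @export
build_components <- function(records, size_ceiling = Inf, resolution = 1,
                             seed = 1L) {
  if (nrow(records) == 0) return(list())
  # A- and B-pixel namespaces are distinct; prefix to avoid name collisions
  va <- paste0("A:", records$upia)
  vb <- paste0("B:", records$upib)
  verts <- unique(c(va, vb))
  g <- igraph::graph_from_edgelist(cbind(va, vb), directed = FALSE)
  memb <- igraph::components(g)$membership
  edge_comp <- as.integer(memb[va])

  if (is.finite(size_ceiling)) {
    sizes <- tabulate(edge_comp)
    next_id <- max(edge_comp)
    for (comp in which(sizes > size_ceiling)) {
      idx <- which(edge_comp == comp)
      sub <- igraph::simplify(igraph::graph_from_edgelist(
        cbind(va[idx], vb[idx]), directed = FALSE))
      cl <- with_seed(derive_seed(seed, comp), {
        igraph::cluster_leiden(sub, objective_function = "modularity",
                               resolution = resolution)
      })
      cm <- igraph::membership(cl)
      # assign each edge to its A-pixel's community
      new <- next_id + as.integer(cm[va[idx]])
      edge_comp[idx] <- new
      next_id <- max(next_id, max(new))
    }
  }

  groups <- split(seq_len(nrow(records)), edge_comp)
  comps <- lapply(groups, function(idx) {
    e <- records[idx, , drop = FALSE]
    rownames(e) <- NULL
    structure(list(edges = e,
                   a_nodes = unique(e$upia),
                   b_nodes = unique(e$upib),
                   n_edges = nrow(e)),
              class = "pixel_component")
  })
  ord <- order(-vapply(comps, `[[`, integer(1), "n_edges"),
               vapply(comps, function(c) min(c$a_nodes), character(1)))
  unname(comps[ord])
}

#' Call cells from graph components
#'
#' Keeps exactly the components whose edge count is strictly greater than
#' `min_edges` (default 7000) and attaches sample metadata. Components at or
#' below the threshold are treated as debris and discarded.
#'
#' @param components output of [build_components()]
#' @param min_edges strict edge-count threshold
#' @param meta optional named list / one-row data.frame with `sample_id`,
#'   `donor`, `condition`, `replicate`
#' @return list of called cells (class `pixel_cell`), each adding `cell_id`
#'   and the metadata fields to the component
#' @export
call_cells <- function(components, min_edges = 7000, meta = NULL) {
  kept <- Filter(function(cc) cc$n_edges > min_edges, components)
  sample_id <- if (!is.null(meta)) meta$sample_id else "sample"
  lapply(seq_along(kept), function(i) {
    cc <- kept[[i]]
    cc$cell_id <- sprintf("%s_cell%04d", sample_id, i)
    cc$sample_id <- sample_id
    cc$donor <- if (!is.null(meta)) meta$donor else NA
    cc$condition <- if (!is.null(meta)) meta$condition else NA
    cc$replicate <- if (!is.null(meta)) meta$replicate else NA
    class(cc) <- c("pixel_cell", "pixel_component")
    cc
  })
}

#' @export
print.pixel_component <- function(x, ...) {
  cat(if (inherits(x, "pixel_cell")) paste0("pixel_cell ", x$cell_id) else "pixel_component",
      ":", x$n_edges, "edges,", length(x$a_nodes), "A-pixels,",
      length(x$b_nodes), "B-pixels\n")
  invisible(x)
}

#' Per-cell marker count matrix
#'
#' Entry (cell, marker) is the number of deduplicated binding events carrying
#' that marker in that cell. Columns cover the full panel (zero-filled), so
#' row sums equal each cell's edge count.
#'
#' @param cells list of called cells
#' @param panel panel data.frame
#' @return integer matrix, rows = cells, columns = panel markers
#' @export
count_matrix <- function(cells, panel) {
  markers <- panel$marker
  out <- matrix(0L, nrow = length(cells), ncol = length(markers),
                dimnames = list(vapply(cells, `[[`, character(1), "cell_id"),
                                markers))
  for (i in seq_along(cells)) {
    tab <- table(factor(cells[[i]]$edges$marker, levels = markers))
    out[i, ] <- as.integer(tab)
  }
  out
}

#' Per-A-pixel count table and adjacency for one cell
#'
#' Rows are the cell's A-pixels, columns the panel markers, entries
#' deduplicated event counts; column sums equal the cell's marker counts.
#' Two A-pixels are adjacent iff they share at least one B-pixel neighbor
#' (binary, symmetric, no self-loops) -- the spatial weight graph for
#' polarization and the pixel index for colocalization.
#'
#' @param cell a called cell
#' @param panel optional panel data.frame; if supplied, columns cover the
#'   full panel
#' @return object of class `pixel_table`: list with `counts` (matrix),
#'   `adjacency` (sparse symmetric 0/1 Matrix) and `cell_id`
#' @export
pixel_table <- function(cell, panel = NULL) {
  e <- cell$edges
  a_levels <- sort(unique(e$upia))
  m_levels <- if (is.null(panel)) sort(unique(e$marker)) else panel$marker
  fa <- factor(e$upia, levels = a_levels)
  fm <- factor(e$marker, levels = m_levels)
  counts <- unclass(table(fa, fm))
  dimnames(counts) <- list(a_levels, m_levels)

  b_levels <- sort(unique(e$upib))
  fb <- factor(e$upib, levels = b_levels)
  pair <- !duplicated(paste(e$upia, e$upib, sep = "\r"))
  inc <- Matrix::sparseMatrix(i = as.integer(fa)[pair], j = as.integer(fb)[pair],
                              x = 1, dims = c(length(a_levels), length(b_levels)))
  adj <- Matrix::tcrossprod(inc)
  adj <- methods::as(adj > 0, "dMatrix") * 1
  diag(adj) <- 0
  adj <- Matrix::drop0(adj)
  dimnames(adj) <- list(a_levels, a_levels)

  structure(list(cell_id = cell$cell_id %||% NA_character_,
                 counts = counts, adjacency = adj),
            class = "pixel_table")
}

#' Process one sample end to end
#'
#' Parse, deduplicate, build components and call cells for one edge-list
#' file.
#'
#' @param path edge-list file
#' @param panel panel data.frame
#' @param meta sample metadata (named list / one-row data.frame)
#' @param min_edges cell-calling threshold (strict)
#' @param ... passed to [build_components()]
#' @return list of called cells
#' @export
process_sample <- function(path, panel, meta = NULL, min_edges = 7000, ...) {
  records <- dedupe_events(parse_edge_list(path, panel))
  call_cells(build_components(records, ...), min_edges = min_edges, meta = meta)
}

#' Process a whole experiment from a sample sheet
#'
#' @param sample_sheet data.frame from [read_sample_sheet()]
#' @param panel panel data.frame
#' @param min_edges cell-calling threshold
#' @param ... passed to [build_components()]
#' @return list with `cells` (all called cells), `counts` (count matrix) and
#'   `cell_meta` (data.frame: cell_id, sample_id, donor, condition,
#'   replicate, n_edges, n_a_pixels, n_b_pixels)
#' @export
process_experiment <- function(sample_sheet, panel, min_edges = 7000, ...) {
  cells <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    meta <- as.list(sample_sheet[i, ])
    cells <- c(cells, process_sample(meta$path, panel, meta = meta,
                                     min_edges = min_edges, ...))
  }
  meta_df <- do.call(rbind, lapply(cells, function(cc) {
    data.frame(cell_id = cc$cell_id, sample_id = cc$sample_id,
               donor = cc$donor, condition = cc$condition,
               replicate = cc$replicate, n_edges = cc$n_edges,
               n_a_pixels = length(cc$a_nodes), n_b_pixels = length(cc$b_nodes),
               stringsAsFactors = FALSE)
  }))
  list(cells = cells, counts = count_matrix(cells, panel), cell_meta = meta_df)
}

#' Write / read a count matrix as MatrixMarket plus row/column TSVs
#'
#' `<prefix>.mtx` holds the sparse counts, `<prefix>.rows.tsv` the cell ids,
#' `<prefix>.cols.tsv` the marker names.
#'
#' @param counts integer matrix (cells x markers)
#' @param prefix output path prefix
#' @return `read_count_matrix()` returns the dense integer matrix.
#' @export
write_count_matrix <- function(counts, prefix) {
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".rows.tsv"))
  writeLines(colnames(counts), paste0(prefix, ".cols.tsv"))
  invisible(prefix)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.tsv")),
                      readLines(paste0(prefix, ".cols.tsv")))
  storage.mode(m) <- "integer"
  m
}
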