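# Shared fixtures: small simulation configs and brute-force oracles.

small_markers <- function(m = 10) sprintf("M%02d", seq_len(m))

# A reduced-scale config: cells small enough for fast module tests.
small_config <- function(markers = small_markers(), ...) {
  defaults <- list(
    markers = markers,
    n_cells_per_condition = 3,
    n_events_per_cell = 400,
    n_a_pixels = 60, n_b_pixels = 60,
    capture_radius = 0.45,
    n_debris_components = 2,
    debris_edge_range = c(5, 20),
    duplicate_read_rate = 0.1,
    seed = 42
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

small_panel <- function(markers = small_markers(), controls = character()) {
  data.frame(marker = markers, is_control = as.integer(markers %in% controls),
             stringsAsFactors = FALSE)
}

# Simulate n cells of one condition and call them (low threshold).
simulate_called_cells <- function(config, condition = "acute", n = 5,
                                  offset = 0, min_edges = 10) {
  lapply(seq_len(n), function(i) {
    sim <- simulate_cell(config, condition, i + offset)
    cc <- call_cells(build_components(sim$edges), min_edges = min_edges,
                     meta = list(sample_id = paste0("s_", condition),
                                 donor = "d1", condition = condition,
                                 replicate = 1L))[[1]]
    cc$cell_id <- sprintf("%s_c%03d", condition, i + offset)
    cc
  })
}

# --- independent oracles -----------------------------------------------

# Moran's I by literal double loop over all ordered pixel pairs.
morans_i_bruteforce <- function(x, w) {
  w <- as.matrix(w)
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
    }
  }
  (n / sum(w)) * num / sum((x - xb)^2)
}

# Gini by the literal pairwise-difference formula.
gini_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Connected components by union-find over the bipartite edge list.
components_bruteforce <- function(records) {
  nodes <- unique(c(paste0("A:", records$upia), paste0("B:", records$upib)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) { while (parent[[v]] != v) v <- parent[[v]]; v }
  for (k in seq_len(nrow(records))) {
    ra <- find(paste0("A:", records$upia[k]))
    rb <- find(paste0("B:", records$upib[k]))
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# A random symmetric 0/1 adjacency with no self-loops, guaranteed >=1 edge.
random_adjacency <- function(n, p = 0.4) {
  repeat {
    w <- matrix(stats::rbinom(n * n, 1, p), n)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    diag(w) <- 0
    if (sum(w) > 0) return(w)
  }
}
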