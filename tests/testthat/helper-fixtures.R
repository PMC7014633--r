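# Shared fixtures and independent oracles. Oracles are deliberately naive
# (dense sampling, Floyd-Warshall, exhaustive subset evaluation) and stay
# independent of the code paths they check.

# Unit square A-B-C-D (1 km sides) plus diagonal A-C of 1.5 km.
unit_square_net <- function() {
  build_network(
    data.frame(id = c("A", "B", "C", "D"),
               x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000)),
    data.frame(from = c("A", "B", "C", "D", "A"),
               to = c("B", "C", "D", "A", "C"),
               length_km = c(1, 1, 1, 1, 1.5)))
}

# Path graph v0 - v1 - ... - v<n-1> with unit (1 km) edges, 1000 m apart.
line_net <- function(n = 5) {
  ids <- paste0("v", seq_len(n) - 1)
  build_network(
    data.frame(id = ids, x = (seq_len(n) - 1) * 1000, y = 0),
    data.frame(from = ids[-n], to = ids[-1], length_km = 1))
}

# Random connected network: random spanning tree over permuted nodes plus
# extra random edges; lengths uniform in (0.1, 2] km.
rand_net <- function(n_nodes, extra_edges = n_nodes) {
  ids <- sprintf("r%02d", seq_len(n_nodes))
  nodes <- data.frame(id = ids,
                      x = runif(n_nodes, 0, 5000), y = runif(n_nodes, 0, 5000))
  perm <- sample(n_nodes)
  from <- perm[-n_nodes]
  to <- perm[-1]
  if (extra_edges > 0) {
    for (k in seq_len(extra_edges)) {
      pair <- sample(n_nodes, 2)
      from <- c(from, pair[1]); to <- c(to, pair[2])
    }
  }
  keep <- !duplicated(paste(pmin(from, to), pmax(from, to)))
  from <- from[keep]; to <- to[keep]
  build_network(nodes, data.frame(from = ids[from], to = ids[to],
                                  length_km = runif(length(from), 0.1, 2)))
}

# Independent all-pairs shortest-path oracle: Floyd-Warshall on the raw
# edge table.
fw_distances <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (r in seq_len(nrow(network$edges))) {
    i <- match(network$edges$from[r], ids)
    j <- match(network$edges$to[r], ids)
    w <- network$edges$length_km[r]
    D[i, j] <- min(D[i, j], w)
    D[j, i] <- min(D[j, i], w)
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Independent p-median oracle: evaluate every k-subset with explicit loops.
pmedian_brute <- function(dm, candidates, k, weights) {
  best <- NULL
  best_obj <- Inf
  for (s in utils::combn(sort(candidates), k, simplify = FALSE)) {
    obj <- 0
    for (jj in seq_len(ncol(dm)))
      obj <- obj + weights[jj] * min(dm[s, jj])
    if (obj < best_obj) {
      best_obj <- obj
      best <- s
    }
  }
  list(selected = best, objective = best_obj)
}

# Random p-median instance: dense random distances, random weights.
rand_pmedian_instance <- function(n_cand = 8, n_dem = 40) {
  dm <- matrix(runif(n_cand * n_dem, 0, 10), n_cand, n_dem,
               dimnames = list(sprintf("f%02d", seq_len(n_cand)),
                               sprintf("d%02d", seq_len(n_dem))))
  list(dm = dm, weights = runif(n_dem, 0, 5))
}

# Small synthetic city for fast pipeline tests (structure of the default,
# scaled down).
small_city_config <- function(seed = 11, ...) {
  city_config(rows = 8, cols = 8, spacing_m = 250, n_neighborhoods = 40,
              seed = seed, ...)
}

tiny_neighborhoods <- function() {
  data.frame(id = c("N1", "N2", "N3"),
             x = c(0, 1000, 2000), y = c(0, 0, 0),
             population = c(100, 300, 50),
             households = c(26, 79, 13),
             hci = c(0.2, 0.4, 0.3),
             dengue_cases = c(1, 3, 0),
             stringsAsFactors = FALSE)
}
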