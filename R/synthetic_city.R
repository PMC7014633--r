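#' Synthetic city generator
#'
#' Generates road networks, neighborhoods and facilities with the spatial
#' structure the pipeline assumes about a mid-sized coastal city: a
#' connected, roughly gridded street network; demand aggregated to a few
#' hundred census-block centroids; housing condition worsening toward the
#' urban periphery; dengue cases concentrated near the center; two central
#' active spray hubs plus dispersed candidate subcenters. Every default is a
#' stated modelling choice (see the methods vignette), not a fit to data.
#'
#' @name synthetic_city
NULL

#' Configuration for the synthetic city
#'
#' @param rows,cols grid dimensions of the street lattice (default 24 x 24)
#' @param spacing_m lattice spacing in meters (default 250, a typical
#'   urban block scale)
#' @param jitter_m uniform node coordinate jitter (default 30)
#' @param edge_dropout fraction of non-spanning-tree edges removed
#'   (default 0.05); a spanning-tree guard keeps the graph connected
#' @param n_neighborhoods number of census-block centroids (default 254)
#' @param pop_meanlog,pop_sdlog lognormal block population parameters
#'   (defaults log(700) and 0.7: median 700, right-skewed)
#' @param mean_household_size persons per household (default 3.8)
#' @param hci_beta0,hci_beta1,hci_noise_sd HCI gradient: clamp01(beta0 +
#'   beta1 * normalized center distance + N(0, sd)). Defaults 0.15, 0.25,
#'   0.05 give band means rising from roughly 0.2 centrally to roughly
#'   0.34 at the periphery.
#' @param dengue_r0 per-person case rate at the city center (default 0.02)
#' @param dengue_lambda exponential decay of the case rate over normalized
#'   center distance (default 2); with `dengue_r0` this yields citywide
#'   incidence of roughly 80 per 10,000
#' @param n_active_hubs central active spray hubs (default 2)
#' @param n_candidates candidate subcenters, quadrant-stratified (default 8)
#' @param snap_tolerance_m snap tolerance carried into the pipeline
#' @param seed integer RNG seed
#' @export
city_config <- function(rows = 24, cols = 24, spacing_m = 250, jitter_m = 30,
                        edge_dropout = 0.05, n_neighborhoods = 254,
                        pop_meanlog = log(700), pop_sdlog = 0.7,
                        mean_household_size = 3.8,
                        hci_beta0 = 0.15, hci_beta1 = 0.25,
                        hci_noise_sd = 0.05,
                        dengue_r0 = 0.02, dengue_lambda = 2,
                        n_active_hubs = 2, n_candidates = 8,
                        snap_tolerance_m = 500, seed = 1) {
  cfg <- as.list(environment())
  if (rows < 2 || cols < 2)
    stop_vectorops("grid must be at least 2 x 2",
                   class = "vectorops_validation_error")
  if (edge_dropout < 0 || edge_dropout >= 1)
    stop_vectorops("edge_dropout must be in [0, 1)",
                   class = "vectorops_validation_error")
  for (f in c("spacing_m", "n_neighborhoods", "mean_household_size"))
    assert_scalar_number(cfg[[f]], f, positive = TRUE)
  structure(cfg, class = "city_config")
}

#' Generate a jittered-grid road network
#'
#' Nodes sit on a `rows` x `cols` lattice with uniform jitter; edges join
#' lattice neighbors with Euclidean lengths. A random spanning tree is kept
#' intact and the remaining edges are dropped independently with
#' probability `edge_dropout`, so the network is connected by construction.
#'
#' @param config a [city_config()]
#' @param seed optional seed (NULL: ambient RNG stream)
#' @return a `road_network`
#' @export
generate_network <- function(config, seed = NULL) {
  with_seed(seed, {
    r <- config$rows; cl <- config$cols; sp <- config$spacing_m
    gx <- rep(seq_len(cl) - 1, times = r) * sp
    gy <- rep(seq_len(r) - 1, each = cl) * sp
    n <- r * cl
    jx <- stats::runif(n, -config$jitter_m, config$jitter_m)
    jy <- stats::runif(n, -config$jitter_m, config$jitter_m)
    ids <- sprintf("n%04d", seq_len(n))
    nodes <- data.frame(id = ids, x = gx + jx, y = gy + jy,
                        stringsAsFactors = FALSE)

    idx <- function(row, col) (row - 1) * cl + col
    from <- integer(0); to <- integer(0)
    for (row in seq_len(r)) for (col in seq_len(cl)) {
      if (col < cl) { from <- c(from, idx(row, col)); to <- c(to, idx(row, col + 1)) }
      if (row < r)  { from <- c(from, idx(row, col)); to <- c(to, idx(row + 1, col)) }
    }
    edges <- data.frame(from = ids[from], to = ids[to],
                        stringsAsFactors = FALSE)

    if (config$edge_dropout > 0) {
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes["id"])
      tree <- igraph::mst(g, weights = stats::runif(nrow(edges)))
      eid <- igraph::get_edge_ids(tree,
        as.vector(t(cbind(edges$from, edges$to))), error = FALSE)
      in_tree <- eid != 0
      drop <- !in_tree & stats::runif(nrow(edges)) < config$edge_dropout
      edges <- edges[!drop, ]
    }
    build_network(nodes, edges)
  })
}

# normalized straight-line distance to the network's coordinate centroid;
# the monotone gradient, not the metric, is what matters for emulation
center_distance_norm <- function(network, x, y) {
  cx <- mean(network$nodes$x); cy <- mean(network$nodes$y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  dmax <- max(sqrt((network$nodes$x - cx)^2 + (network$nodes$y - cy)^2))
  d / dmax
}

#' Generate synthetic neighborhoods over a network
#'
#' Centroids are uniform over the network's bounding box (well inside the
#' 500 m snap tolerance of a 250 m lattice). Population is lognormal;
#' households are population / mean household size; HCI follows the
#' increasing center-distance gradient; dengue cases are Poisson with a
#' per-person rate decaying exponentially from the center.
#'
#' @param network a `road_network`
#' @param config a [city_config()]
#' @param seed optional seed
#' @return neighborhood data.frame (id, x, y, population, households, hci,
#'   dengue_cases)
#' @export
generate_neighborhoods <- function(network, config, seed = NULL) {
  with_seed(seed, {
    n <- config$n_neighborhoods
    xr <- range(network$nodes$x); yr <- range(network$nodes$y)
    x <- stats::runif(n, xr[1], xr[2])
    y <- stats::runif(n, yr[1], yr[2])
    dn <- center_distance_norm(network, x, y)
    population <- round(stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog))
    population <- pmax(population, 1)
    households <- pmax(1, round(population / config$mean_household_size))
    hci <- clamp01(config$hci_beta0 + config$hci_beta1 * dn +
                     stats::rnorm(n, 0, config$hci_noise_sd))
    rate <- config$dengue_r0 * exp(-config$dengue_lambda * dn)
    dengue_cases <- stats::rpois(n, population * rate)
    data.frame(id = sprintf("N%03d", seq_len(n)), x = x, y = y,
               population = population, households = households,
               hci = hci, dengue_cases = dengue_cases,
               stringsAsFactors = FALSE)
  })
}

#' Place active hubs and candidate subcenters on network nodes
#'
#' Active hubs are sampled from nodes in the innermost quartile of center
#' distance (the consolidated, centrally located deployment facilities);
#' candidates are stratified over the four quadrants around the centroid
#' (the dispersed subcenters formerly used for deployment). Facilities sit
#' exactly on network nodes, so snapping attaches them with zero offset.
#'
#' @param network a `road_network`
#' @param config a [city_config()]
#' @param seed optional seed
#' @return data.frame: id, x, y, role ("active"/"candidate"), node_id
#' @export
place_facilities <- function(network, config, seed = NULL) {
  with_seed(seed, {
    nd <- network$nodes
    dn <- center_distance_norm(network, nd$x, nd$y)
    inner <- which(dn <= stats::quantile(dn, 0.25))
    if (length(inner) < config$n_active_hubs)
      stop_vectorops("not enough central nodes for the active hubs",
                     class = "vectorops_validation_error")
    hubs <- inner[sample.int(length(inner), config$n_active_hubs)]

    cx <- mean(nd$x); cy <- mean(nd$y)
    quadrant <- 1L + (nd$x >= cx) + 2L * (nd$y >= cy)
    avail <- setdiff(seq_len(nrow(nd)), hubs)
    per_q <- rep(config$n_candidates %/% 4, 4) +
      (seq_len(4) <= config$n_candidates %% 4)
    cand <- integer(0)
    for (q in 1:4) {
      pool <- avail[quadrant[avail] == q]
      if (length(pool) < per_q[q])
        stop_vectorops("not enough nodes in quadrant ", q, " for candidates",
                       class = "vectorops_validation_error")
      pick <- pool[sample.int(length(pool), per_q[q])]
      cand <- c(cand, pick)
      avail <- setdiff(avail, pick)
    }
    sel <- c(hubs, cand)
    data.frame(
      id = c(sprintf("H%d", seq_along(hubs)), sprintf("C%d", seq_along(cand))),
      x = nd$x[sel], y = nd$y[sel],
      role = rep(c("active", "candidate"), c(length(hubs), length(cand))),
      node_id = nd$id[sel],
      stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic city
#'
#' Seeds the RNG once from `config$seed` and draws the network,
#' neighborhoods and facilities from that single stream, so a config fully
#' determines the city.
#'
#' @param config a [city_config()]
#' @return a `synthetic_city`: list with `network`, `neighborhoods`,
#'   `facilities` and the `config` echo.
#' @export
generate_city <- function(config = city_config()) {
  with_seed(config$seed, {
    network <- generate_network(config)
    neighborhoods <- generate_neighborhoods(network, config)
    facilities <- place_facilities(network, config)
    structure(list(network = network, neighborhoods = neighborhoods,
                   facilities = facilities, config = config),
              class = "synthetic_city")
  })
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf(
    "<synthetic_city> %d nodes / %d edges; %d neighborhoods; %d facilities (seed %s)\n",
    nrow(x$network$nodes), nrow(x$network$edges), nrow(x$neighborhoods),
    nrow(x$facilities), format(x$config$seed)))
  invisible(x)
}
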