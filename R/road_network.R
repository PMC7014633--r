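#' Road network graph construction, point snapping and shortest paths
#'
#' The road network is the impedance surface for every downstream analysis:
#' an undirected planar graph with node coordinates in projected meters and
#' edge lengths in kilometers. All roads carry the same impedance (driving
#' distance), so no speed or road-class attributes are modelled.
#'
#' @name road_network
NULL

new_road_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' Build a validated road network from node and edge tables
#'
#' @param node_table data.frame with columns `id`, `x`, `y` (planar meters).
#' @param edge_table data.frame with columns `from`, `to` and optionally
#'   `length_m` (or `length_km`). Missing lengths are computed as the planar
#'   Euclidean distance between the endpoint nodes.
#' @return A `road_network` object: `$nodes` (id, x, y) and `$edges`
#'   (from, to, length_km), with attribute `n_components` reporting the
#'   number of connected components.
#' @examples
#' net <- build_network(
#'   data.frame(id = c("a", "b"), x = c(0, 1000), y = 0),
#'   data.frame(from = "a", to = "b"))
#' net$edges$length_km  # 1
#' @export
build_network <- function(node_table, edge_table) {
  req_n <- c("id", "x", "y")
  if (!all(req_n %in% names(node_table)))
    stop_vectorops("node table must have columns id, x, y",
                   class = "vectorops_structural_error")
  nodes <- data.frame(id = as.character(node_table$id),
                      x = as.numeric(node_table$x),
                      y = as.numeric(node_table$y),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id))
    stop_vectorops("duplicate node ids", class = "vectorops_structural_error")
  if (anyNA(nodes$x) || anyNA(nodes$y))
    stop_vectorops("node coordinates must be numeric and non-missing",
                   class = "vectorops_structural_error")

  if (!all(c("from", "to") %in% names(edge_table)))
    stop_vectorops("edge table must have columns from, to",
                   class = "vectorops_structural_error")
  from <- as.character(edge_table$from)
  to <- as.character(edge_table$to)
  unknown <- setdiff(c(from, to), nodes$id)
  if (length(unknown))
    stop_vectorops("edge endpoint(s) not present in node table: ",
                   paste(unknown, collapse = ", "),
                   class = "vectorops_structural_error")
  if (any(from == to))
    stop_vectorops("self-loop edges are not allowed",
                   class = "vectorops_structural_error")

  if ("length_km" %in% names(edge_table)) {
    len_km <- as.numeric(edge_table$length_km)
  } else if ("length_m" %in% names(edge_table)) {
    len_km <- as.numeric(edge_table$length_m) / 1000
  } else {
    len_km <- rep(NA_real_, length(from))
  }
  if (anyNA(len_km)) {
    i <- match(from, nodes$id)
    j <- match(to, nodes$id)
    eucl <- sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2) / 1000
    len_km[is.na(len_km)] <- eucl[is.na(len_km)]
  }
  if (any(!is.finite(len_km) | len_km <= 0))
    stop_vectorops("all edge lengths must be finite and strictly positive",
                   class = "vectorops_validation_error")

  edges <- data.frame(from = from, to = to, length_km = len_km,
                      stringsAsFactors = FALSE)
  net <- new_road_network(nodes, edges)
  attr(net, "n_components") <- n_components(net)
  net
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges),
              attr(x, "n_components") %||% n_components(x)))
  invisible(x)
}

# igraph view of a road network; vertex names are node ids, edge weights km.
net_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = network$nodes["id"])
  igraph::E(g)$weight <- network$edges$length_km
  g
}

#' Number of connected components of a road network
#' @param network a `road_network`
#' @export
n_components <- function(network) {
  if (nrow(network$edges) == 0L) return(nrow(network$nodes))
  igraph::components(net_igraph(network))$no
}

#' Snap tolerance configuration
#'
#' Demand and facility points are attached to the nearest point on the road
#' network; points farther than `tolerance_m` from every edge are flagged
#' unreachable and excluded from analyses (never silently dropped).
#'
#' @param tolerance_m maximum straight-line snap distance in meters
#'   (default 500, the search tolerance used for block centroids).
#' @export
snap_config <- function(tolerance_m = 500) {
  assert_scalar_number(tolerance_m, "tolerance_m", positive = TRUE)
  structure(list(tolerance_m = tolerance_m), class = "snap_config")
}

# Nearest point on any edge to (px, py): perpendicular projection clamped to
# the segment. Returns the edge row index, parameter t along it, projected
# coordinates and offset in meters. Ties keep the lowest edge index.
nearest_edge_projection <- function(network, px, py) {
  nd <- network$nodes
  i <- match(network$edges$from, nd$id)
  j <- match(network$edges$to, nd$id)
  ax <- nd$x[i]; ay <- nd$y[i]
  bx <- nd$x[j]; by <- nd$y[j]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t[len2 == 0] <- 0
  t <- clamp01(t)
  qx <- ax + t * dx
  qy <- ay + t * dy
  d <- sqrt((px - qx)^2 + (py - qy)^2)
  e <- which.min(d)
  list(edge = e, t = t[e], x = qx[e], y = qy[e], offset_m = d[e])
}

#' Snap a point onto the road network
#'
#' The attachment is the globally nearest point on any edge. When that point
#' falls strictly inside an edge, a virtual node is inserted there, splitting
#' the host edge into two edges whose lengths sum exactly to the original
#' length, so all pre-existing network distances are preserved. When the
#' offset exceeds the tolerance the network is returned unmodified and the
#' snap is flagged unreachable.
#'
#' @param network a `road_network`
#' @param point numeric length-2 vector `c(x, y)` in meters
#' @param point_id id used to name the inserted virtual node (`pt_<id>`)
#' @param config a [snap_config()]
#' @return list with `network` (possibly augmented) and `snap`, a one-row
#'   data.frame: `point_id`, `node_id` (NA when unreachable), `offset_m`,
#'   `reachable`.
#' @export
snap_point <- function(network, point, point_id = "pt", config = snap_config()) {
  if (nrow(network$nodes) == 0L || nrow(network$edges) == 0L)
    stop_vectorops("cannot snap to an empty network",
                   class = "vectorops_structural_error")
  pr <- nearest_edge_projection(network, point[1], point[2])
  if (pr$offset_m > config$tolerance_m) {
    snap <- data.frame(point_id = as.character(point_id), node_id = NA_character_,
                       offset_m = pr$offset_m, reachable = FALSE,
                       stringsAsFactors = FALSE)
    return(list(network = network, snap = snap))
  }
  edge <- network$edges[pr$edge, ]
  # attach to an existing endpoint when the projection lands on one
  # (sub-millimeter along-edge distance), avoiding zero-length split edges
  eps_km <- 1e-6 / 1000
  split_km <- pr$t * edge$length_km
  if (split_km < eps_km) {
    node_id <- edge$from
  } else if (edge$length_km - split_km < eps_km) {
    node_id <- edge$to
  } else {
    node_id <- paste0("pt_", point_id)
    if (node_id %in% network$nodes$id)
      stop_vectorops("virtual node id collision: ", node_id,
                     class = "vectorops_structural_error")
    network$nodes <- rbind(network$nodes,
                           data.frame(id = node_id, x = pr$x, y = pr$y,
                                      stringsAsFactors = FALSE))
    new_edges <- data.frame(from = c(edge$from, node_id),
                            to = c(node_id, edge$to),
                            length_km = c(split_km, edge$length_km - split_km),
                            stringsAsFactors = FALSE)
    network$edges <- rbind(network$edges[-pr$edge, ], new_edges)
    attr(network, "n_components") <- attr(network, "n_components")  # unchanged
  }
  snap <- data.frame(point_id = as.character(point_id), node_id = node_id,
                     offset_m = pr$offset_m, reachable = TRUE,
                     stringsAsFactors = FALSE)
  list(network = network, snap = snap)
}

#' Snap many points sequentially
#'
#' @param network a `road_network`
#' @param points data.frame with columns `id`, `x`, `y`
#' @param config a [snap_config()]
#' @return list with the augmented `network` and `snaps`, one row per point
#'   in input order.
#' @export
snap_points <- function(network, points, config = snap_config()) {
  snaps <- vector("list", nrow(points))
  for (r in seq_len(nrow(points))) {
    res <- snap_point(network, c(points$x[r], points$y[r]),
                      point_id = points$id[r], config = config)
    network <- res$network
    snaps[[r]] <- res$snap
  }
  list(network = network, snaps = do.call(rbind, snaps))
}

#' Shortest route between two nodes
#'
#' Dijkstra's algorithm over km edge lengths. Among equal-length routes the
#' lexicographically smallest node sequence is returned, so results are
#' reproducible bit-for-bit.
#'
#' @param network a `road_network`
#' @param origin,destination node ids
#' @return a `route`: list with `origin`, `destination`, `node_sequence`,
#'   `length_km`, `reachable`. A cross-component query returns
#'   `reachable = FALSE` with infinite length ("no route"), not an error.
#' @export
shortest_path <- function(network, origin, destination) {
  ids <- network$nodes$id
  if (!(origin %in% ids) || !(destination %in% ids))
    stop_vectorops("origin/destination not in network",
                   class = "vectorops_structural_error")
  if (origin == destination)
    return(new_route(origin, destination, origin, 0))

  n <- length(ids)
  rank <- match(ids, sort(ids))          # lexicographic order of node ids
  o <- match(origin, ids)
  dst <- match(destination, ids)

  ei <- match(network$edges$from, ids)
  ej <- match(network$edges$to, ids)
  w <- network$edges$length_km
  adj <- vector("list", n)               # adjacency: cbind(neighbor, weight)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- rbind(adj[[ei[k]]], c(ej[k], w[k]))
    adj[[ej[k]]] <- rbind(adj[[ej[k]]], c(ei[k], w[k]))
  }

  dist <- rep(Inf, n)
  dist[o] <- 0
  paths <- vector("list", n)
  paths[[o]] <- o
  done <- logical(n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[order(dist[cand], rank[cand])][1L]
    if (u == dst) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1L]
      nd <- dist[u] + nb[r, 2L]
      if (nd < dist[v]) {
        dist[v] <- nd
        paths[[v]] <- c(paths[[u]], v)
      } else if (nd == dist[v] &&
                 lex_less(rank[c(paths[[u]], v)], rank[paths[[v]]])) {
        paths[[v]] <- c(paths[[u]], v)
      }
    }
  }
  if (!is.finite(dist[dst]))
    return(new_route(origin, destination, NULL, Inf, reachable = FALSE))
  new_route(origin, destination, ids[paths[[dst]]], dist[dst])
}

new_route <- function(origin, destination, node_sequence, length_km,
                      reachable = TRUE) {
  structure(list(origin = origin, destination = destination,
                 node_sequence = node_sequence, length_km = length_km,
                 reachable = reachable),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  if (!x$reachable)
    cat(sprintf("<route> %s -> %s: no route\n", x$origin, x$destination))
  else
    cat(sprintf("<route> %s -> %s: %.3f km via %d node(s)\n",
                x$origin, x$destination, x$length_km, length(x$node_sequence)))
  invisible(x)
}

#' Network distance matrix between node sets
#'
#' Batch Dijkstra (delegated to igraph). Unreachable pairs are `Inf`.
#'
#' @param network a `road_network`
#' @param origins,destinations character vectors of node ids
#' @return numeric matrix of km distances, dimnames origins x destinations.
#' @export
distance_matrix <- function(network, origins, destinations) {
  ids <- network$nodes$id
  unknown <- setdiff(c(origins, destinations), ids)
  if (length(unknown))
    stop_vectorops("unknown node id(s): ", paste(unknown, collapse = ", "),
                   class = "vectorops_structural_error")
  g <- net_igraph(network)
  m <- igraph::distances(g, v = origins, to = destinations,
                         weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  m[origins, destinations, drop = FALSE]
}
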