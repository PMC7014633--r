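#' Readers and writers for networks, facilities and routes
#'
#' Road networks travel either as a GeoJSON FeatureCollection of LineString
#' features (each chain decomposed into edges; optional numeric property
#' `length_m`, optional `from`/`to` node ids) or as a node/edge CSV pair.
#' Coordinates are planar meters throughout; no CRS handling is attempted.
#'
#' @name io
NULL

coord_key <- function(x, y) sprintf("%.6f_%.6f", x, y)

#' Read a road network from a GeoJSON file of LineStrings
#'
#' Each LineString chain is decomposed into consecutive-vertex edges. Nodes
#' are deduplicated by coordinates (micrometre precision); `from`/`to`
#' properties, when present on two-vertex segments, name the endpoint nodes,
#' otherwise ids are assigned in order of first appearance.
#'
#' @param path GeoJSON file path
#' @return a `road_network`
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop_vectorops("expected a GeoJSON FeatureCollection",
                   class = "vectorops_structural_error")
  node_id <- character(0)   # keyed by coord_key
  node_x <- numeric(0); node_y <- numeric(0)
  ef <- character(0); et <- character(0); el <- numeric(0)
  next_id <- 0L

  intern <- function(x, y, hint = NULL) {
    key <- coord_key(x, y)
    hit <- match(key, names(node_id))
    if (!is.na(hit)) return(node_id[[hit]])
    id <- if (length(hint) == 1L && !is.na(hint) && !(hint %in% node_id)) hint else {
      next_id <<- next_id + 1L
      sprintf("v%04d", next_id)
    }
    node_id[[key]] <<- id
    node_x[[key]] <<- x
    node_y[[key]] <<- y
    id
  }

  for (f in fc$features) {
    if (!identical(f$geometry$type, "LineString"))
      stop_vectorops("network features must be LineStrings",
                     class = "vectorops_structural_error")
    cc <- f$geometry$coordinates
    if (length(cc) < 2L)
      stop_vectorops("LineString needs at least two vertices",
                     class = "vectorops_structural_error")
    p <- f$properties
    two_vertex <- length(cc) == 2L
    for (s in seq_len(length(cc) - 1L)) {
      a <- cc[[s]]; b <- cc[[s + 1L]]
      ia <- intern(a[[1]], a[[2]],
                   hint = if (two_vertex) as.character(p$from %||% NULL))
      ib <- intern(b[[1]], b[[2]],
                   hint = if (two_vertex) as.character(p$to %||% NULL))
      ef <- c(ef, ia); et <- c(et, ib)
      len <- if (two_vertex && !is.null(p$length_m))
        as.numeric(p$length_m) else NA_real_
      el <- c(el, len)
    }
  }
  nodes <- data.frame(id = unname(node_id), x = unname(node_x),
                      y = unname(node_y), stringsAsFactors = FALSE)
  edges <- data.frame(from = ef, to = et, length_m = el,
                      stringsAsFactors = FALSE)
  build_network(nodes, edges)
}

#' Read a road network from node/edge CSV files
#'
#' @param node_path CSV with columns `node_id,x,y` (or `id,x,y`)
#' @param edge_path CSV with columns `from,to` and optional `length_m`
#' @return a `road_network`
#' @export
read_network_csv <- function(node_path, edge_path) {
  nd <- utils::read.csv(node_path, stringsAsFactors = FALSE)
  if ("node_id" %in% names(nd)) names(nd)[names(nd) == "node_id"] <- "id"
  ed <- utils::read.csv(edge_path, stringsAsFactors = FALSE)
  build_network(nd, ed)
}

#' Write a road network as GeoJSON LineStrings
#'
#' One two-vertex LineString per edge, with `from`, `to` and `length_m`
#' properties, so [read_network_geojson()] round-trips node ids and lengths.
#'
#' @param network a `road_network`
#' @param path output path
#' @export
write_network_geojson <- function(network, path) {
  nd <- network$nodes
  i <- match(network$edges$from, nd$id)
  j <- match(network$edges$to, nd$id)
  feats <- lapply(seq_len(nrow(network$edges)), function(k) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(nd$x[i[k]], nd$y[i[k]]),
                                            c(nd$x[j[k]], nd$y[j[k]]))),
         properties = list(from = network$edges$from[k],
                           to = network$edges$to[k],
                           length_m = network$edges$length_km[k] * 1000))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write facilities as GeoJSON Points
#' @param facilities data.frame with id, x, y, role
#' @param path output path
#' @export
write_facilities_geojson <- function(facilities, path) {
  feats <- lapply(seq_len(nrow(facilities)), function(k) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(facilities$x[k], facilities$y[k])),
         properties = list(id = facilities$id[k], role = facilities$role[k]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write routes as GeoJSON LineStrings
#'
#' @param routes list of `route` objects (unreachable routes are skipped)
#' @param network the `road_network` the routes traverse (for coordinates)
#' @param path output path
#' @export
write_routes_geojson <- function(routes, network, path) {
  nd <- network$nodes
  feats <- list()
  for (rt in routes) {
    if (!rt$reachable) next
    i <- match(rt$node_sequence, nd$id)
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(i, function(k) c(nd$x[k], nd$y[k]))),
      properties = list(origin = rt$origin, destination = rt$destination,
                        length_km = rt$length_km))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write a synthetic city in the formats the readers consume
#'
#' Emits `network.geojson`, `neighborhoods.csv`, `facilities.geojson` and a
#' `city_config.json` sidecar echoing the generator configuration, so a
#' generated city round-trips through the full file-based pipeline.
#'
#' @param city a `synthetic_city`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(network = file.path(dir, "network.geojson"),
             neighborhoods = file.path(dir, "neighborhoods.csv"),
             facilities = file.path(dir, "facilities.geojson"),
             config = file.path(dir, "city_config.json"))
  write_network_geojson(city$network, paths[["network"]])
  utils::write.csv(city$neighborhoods, paths[["neighborhoods"]],
                   row.names = FALSE)
  write_facilities_geojson(city$facilities, paths[["facilities"]])
  jsonlite::write_json(unclass(city$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
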