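#' Closest-facility routing and the trip/fuel access-cost model
#'
#' A spray team treats a fixed number of households per deployment before
#' returning to its hub to refill, so treating a whole neighborhood takes
#' `ceiling(households / capacity)` round trips. Each round trip burns fuel
#' along the optimized hub-to-centroid route, priced at the pump. The total
#' access cost of a neighborhood is trips x round-trip fuel cost.
#'
#' @name route_costing
NULL

#' Trip and fuel cost model
#'
#' @param fuel_price_per_l pump price of gasoline, USD per liter
#'   (default 0.61, Ecuador 2016 average)
#' @param fuel_economy_km_per_l city fuel economy of the service truck,
#'   km per liter (default 5.53, a standard 2010 pickup)
#' @param households_per_trip households treated per deployment before the
#'   team must return to refill backpack sprayers (default 25)
#' @param round_trip_factor distance multiplier per trip (default 2:
#'   hub -> neighborhood -> hub)
#' @export
cost_model <- function(fuel_price_per_l = 0.61,
                       fuel_economy_km_per_l = 5.53,
                       households_per_trip = 25,
                       round_trip_factor = 2) {
  assert_scalar_number(fuel_price_per_l, "fuel_price_per_l", positive = TRUE)
  assert_scalar_number(fuel_economy_km_per_l, "fuel_economy_km_per_l",
                       positive = TRUE)
  assert_scalar_number(households_per_trip, "households_per_trip",
                       positive = TRUE)
  assert_scalar_number(round_trip_factor, "round_trip_factor", positive = TRUE)
  if (households_per_trip != round(households_per_trip) ||
      households_per_trip < 1)
    stop_vectorops("households_per_trip must be an integer >= 1",
                   class = "vectorops_validation_error")
  structure(list(fuel_price_per_l = fuel_price_per_l,
                 fuel_economy_km_per_l = fuel_economy_km_per_l,
                 households_per_trip = households_per_trip,
                 round_trip_factor = round_trip_factor),
            class = "cost_model")
}

#' Number of deployment trips needed to treat every household once
#'
#' @param households household count(s), >= 0
#' @param model a [cost_model()]
#' @return `ceiling(households / households_per_trip)`; 0 households need
#'   0 trips. Vectorized.
#' @export
trips_required <- function(households, model = cost_model()) {
  if (any(households < 0))
    stop_vectorops("households must be nonnegative",
                   class = "vectorops_validation_error")
  as.integer(ceiling(households / model$households_per_trip))
}

#' Fuel cost of one round trip along a route
#'
#' Cost = round_trip_factor x one_way_km / fuel_economy x fuel_price.
#' Full floating precision is retained; round to cents only for display.
#'
#' @param one_way_km one-way route length(s) in km, >= 0
#' @param model a [cost_model()]
#' @return USD per round trip. Vectorized.
#' @export
round_trip_fuel_cost <- function(one_way_km, model = cost_model()) {
  if (any(one_way_km < 0))
    stop_vectorops("one_way_km must be nonnegative",
                   class = "vectorops_validation_error")
  model$round_trip_factor * one_way_km / model$fuel_economy_km_per_l *
    model$fuel_price_per_l
}

#' Closest facility to a single neighborhood node
#'
#' Ties are broken by the lexicographically smallest facility id.
#'
#' @param network a snapped `road_network`
#' @param facility_nodes named character vector: facility id -> node id
#' @param neighborhood_node node id of the demand point
#' @return list with `facility_id` and the shortest `route` (a "no route"
#'   result when no facility is reachable).
#' @export
closest_facility <- function(network, facility_nodes, neighborhood_node) {
  if (is.null(names(facility_nodes)))
    names(facility_nodes) <- facility_nodes
  dm <- distance_matrix(network, unname(facility_nodes), neighborhood_node)
  d <- dm[, 1L]
  if (!any(is.finite(d)))
    return(list(facility_id = NA_character_,
                route = new_route(NA_character_, neighborhood_node, NULL, Inf,
                                  reachable = FALSE)))
  ord <- order(d, names(facility_nodes))
  best <- ord[1L]
  list(facility_id = names(facility_nodes)[best],
       route = shortest_path(network, facility_nodes[[best]],
                             neighborhood_node))
}

# Batch closest-facility assignment (distances only; no path extraction).
# Returns data.frame: id, facility_id, one_way_km — id order preserved.
closest_facility_table <- function(network, facility_nodes,
                                   neighborhood_nodes, neighborhood_ids) {
  dm <- distance_matrix(network, unname(facility_nodes), neighborhood_nodes)
  fid <- names(facility_nodes)
  ford <- order(fid)                     # tie-break: smallest facility id
  dm <- dm[ford, , drop = FALSE]
  fid <- fid[ford]
  best <- apply(dm, 2L, which.min)
  d <- dm[cbind(best, seq_len(ncol(dm)))]
  data.frame(id = neighborhood_ids,
             facility_id = ifelse(is.finite(d), fid[best], NA_character_),
             one_way_km = d, stringsAsFactors = FALSE)
}

#' Access cost of treating one neighborhood
#'
#' @param route a `route` from the assigned facility to the neighborhood
#' @param households household count in the neighborhood
#' @param model a [cost_model()]
#' @return one-row data.frame: id (destination node), facility_id (origin),
#'   one_way_km, trips, per_trip_cost_usd, total_cost_usd.
#' @export
neighborhood_access_cost <- function(route, households, model = cost_model()) {
  if (!route$reachable)
    stop_vectorops("cannot cost an unreachable route",
                   class = "vectorops_validation_error")
  trips <- trips_required(households, model)
  per_trip <- round_trip_fuel_cost(route$length_km, model)
  data.frame(id = route$destination, facility_id = route$origin,
             one_way_km = route$length_km, trips = trips,
             per_trip_cost_usd = per_trip,
             total_cost_usd = trips * per_trip,
             stringsAsFactors = FALSE)
}

#' Closest-facility access costs for all neighborhoods
#'
#' @param network a snapped `road_network`
#' @param facility_nodes named character vector: facility id -> node id
#' @param neighborhood_nodes node ids of snapped, reachable neighborhoods
#' @param neighborhoods neighborhood data.frame aligned with
#'   `neighborhood_nodes` (supplies ids and household counts)
#' @param model a [cost_model()]
#' @return data.frame: id, facility_id, one_way_km, trips,
#'   per_trip_cost_usd, total_cost_usd.
#' @export
access_costs <- function(network, facility_nodes, neighborhood_nodes,
                         neighborhoods, model = cost_model()) {
  cf <- closest_facility_table(network, facility_nodes, neighborhood_nodes,
                               neighborhoods$id)
  cf$trips <- trips_required(neighborhoods$households, model)
  cf$per_trip_cost_usd <- round_trip_fuel_cost(
    ifelse(is.finite(cf$one_way_km), cf$one_way_km, 0), model)
  cf$per_trip_cost_usd[!is.finite(cf$one_way_km)] <- NA_real_
  cf$total_cost_usd <- cf$trips * cf$per_trip_cost_usd
  cf
}

#' Quantile class edges for a cost distribution
#'
#' @param costs total access costs
#' @param n_classes number of classes (default 5)
#' @return increasing vector of class upper bounds (length `n_classes`),
#'   the last equal to the maximum cost.
#' @export
cost_class_edges <- function(costs, n_classes = 5) {
  q <- stats::quantile(costs, probs = seq_len(n_classes) / n_classes,
                       names = FALSE, type = 7)
  unique(q)
}

#' Summarize neighborhoods by access-cost class
#'
#' Classes are upper-closed intervals on total cost: class i is
#' `(edges[i-1], edges[i]]` with the first class starting at 0. Costs above
#' the last edge fall in the last class (relevant when edges are fixed from
#' a baseline scenario and an alternative exceeds them).
#'
#' @param costs data.frame from [access_costs()]
#' @param neighborhoods neighborhood data.frame (matched on `id`)
#' @param edges increasing class upper bounds; default: quintiles of the
#'   observed total-cost distribution via [cost_class_edges()]
#' @param hci_weighting see [summarize_bins()]
#' @return data.frame: cost_class, cost_min, cost_max, n_neighborhoods,
#'   population, mean_hci, incidence_per_10k.
#' @export
cost_bin_summary <- function(costs, neighborhoods, edges = NULL,
                             hci_weighting = "unweighted") {
  ok <- is.finite(costs$total_cost_usd)
  cc <- costs[ok, ]
  nb <- neighborhoods[match(cc$id, neighborhoods$id), ]
  if (is.null(edges)) edges <- cost_class_edges(cc$total_cost_usd)
  if (length(edges) < 1L || is.unsorted(edges, strictly = TRUE))
    stop_vectorops("class edges must be strictly increasing",
                   class = "vectorops_validation_error")
  n <- length(edges)
  idx <- rowSums(outer(cc$total_cost_usd, edges[-n], ">")) + 1L
  lo <- c(0, edges[-n])
  labels <- sprintf("%.2f-%.2f", lo, edges)
  grp <- factor(labels[idx], levels = labels)
  out <- summarize_groups(nb, grp, hci_weighting, "cost_class")
  out <- cbind(out[1L], cost_min = lo, cost_max = edges, out[-1L])
  out
}
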