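#' End-to-end pipeline and command-line interface
#'
#' `run_pipeline()` composes the stages in analysis order: build or load the
#' city, snap facilities and neighborhoods onto the network, bin
#' neighborhoods into service-area ranges from the active hubs, cost the
#' closest-facility routes, solve the location-allocation scenarios and
#' compare each against the active-hub baseline. Every output is a plain
#' CSV/JSON/GeoJSON file and the whole bundle is byte-reproducible for a
#' fixed config and seed.
#'
#' @name pipeline_cli
NULL

#' Pipeline run configuration
#'
#' @param network_path,neighborhoods_path,facilities_path input files
#'   (GeoJSON/CSV; see [read_network_geojson()], [read_neighborhoods()],
#'   [read_facilities()]). Leave NULL to generate a synthetic city instead.
#' @param synth a [city_config()] used when input paths are NULL
#' @param snap a [snap_config()]
#' @param bins a [service_bins()] scheme
#' @param model a [cost_model()]
#' @param k number of hubs to site in location-allocation (default 2)
#' @param modes weighting scenarios to run (default all four)
#' @param class_edges fixed cost-class upper bounds, or NULL for baseline
#'   quintiles
#' @param grade_maxima passed to [read_neighborhoods()]
#' @param write_routes write a routes GeoJSON (default TRUE)
#' @export
run_config <- function(network_path = NULL, neighborhoods_path = NULL,
                       facilities_path = NULL, synth = city_config(),
                       snap = snap_config(), bins = service_bins(),
                       model = cost_model(), k = 2,
                       modes = c("distance_only", "population",
                                 "dengue_cases", "hci"),
                       class_edges = NULL, grade_maxima = NULL,
                       write_routes = TRUE) {
  paths <- c(network_path, neighborhoods_path, facilities_path)
  if (length(paths) > 0 && length(paths) < 3)
    stop_vectorops("provide all three input paths or none",
                   class = "vectorops_validation_error")
  structure(as.list(environment()), class = "run_config")
}

# Load or synthesize the city described by a run_config.
acquire_city <- function(config) {
  if (!is.null(config$network_path)) {
    for (p in c(config$network_path, config$neighborhoods_path,
                config$facilities_path))
      if (!file.exists(p))
        stop_vectorops("input file not found: ", p,
                       class = "vectorops_config_error")
    network <- if (grepl("\\.(geojson|json)$", config$network_path))
      read_network_geojson(config$network_path)
    else stop_vectorops("network input must be GeoJSON; use ",
                        "read_network_csv() + run_pipeline_city() for CSV",
                        class = "vectorops_config_error")
    list(network = network,
         neighborhoods = read_neighborhoods(config$neighborhoods_path,
                                            grade_maxima = config$grade_maxima),
         facilities = read_facilities(config$facilities_path))
  } else {
    city <- generate_city(config$synth)
    list(network = city$network, neighborhoods = city$neighborhoods,
         facilities = city$facilities)
  }
}

#' Validate pipeline inputs without running analyses
#'
#' Reports structural problems: disconnected networks, facilities or
#' neighborhoods beyond the snap tolerance, facilities on a component with
#' no demand, negative counts.
#'
#' @param config a [run_config()]
#' @return data.frame with columns `stage`, `problem` (zero rows when clean)
#' @export
validate_inputs <- function(config) {
  city <- acquire_city(config)
  probs <- list()
  add <- function(stage, problem)
    probs[[length(probs) + 1L]] <<- data.frame(stage = stage,
                                               problem = problem,
                                               stringsAsFactors = FALSE)
  nc <- attr(city$network, "n_components") %||% n_components(city$network)
  if (nc > 1) add("network", sprintf("network has %d components", nc))
  for (tbl in c("neighborhoods", "facilities")) {
    df <- city[[tbl]]
    for (r in seq_len(nrow(df))) {
      pr <- nearest_edge_projection(city$network, df$x[r], df$y[r])
      if (pr$offset_m > config$snap$tolerance_m)
        add(tbl, sprintf("%s %s is %.0f m from the network (tolerance %.0f m)",
                         tbl, df$id[r], pr$offset_m, config$snap$tolerance_m))
    }
  }
  if (any(city$neighborhoods$population < 0))
    add("neighborhoods", "negative population")
  if (!any(city$facilities$role == "active"))
    add("facilities", "no active facility")
  if (length(probs)) do.call(rbind, probs)
  else data.frame(stage = character(0), problem = character(0))
}

#' Run the full pipeline and write the report bundle
#'
#' Writes to `out_dir`: `neighborhoods_out.csv` (per-neighborhood distance,
#' band, closest facility, trips, costs), `unreachable.csv` (excluded demand
#' points), `bins_summary.csv` (service-area band summary),
#' `cost_classes.csv` (access-cost class summary),
#' `allocation_<mode>.json` and `comparison_<mode>.json` per weighting
#' scenario, `routes.geojson`, and `run_log.json` (solver choices,
#' exclusions, config echo).
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the in-memory results
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  city <- acquire_city(config)
  network <- city$network
  nb <- city$neighborhoods
  fac <- city$facilities

  # snap facilities first (stable virtual-node ids), then neighborhoods
  sf <- snap_points(network, fac, config = config$snap)
  network <- sf$network
  if (any(!sf$snaps$reachable))
    stop_vectorops("facility beyond snap tolerance: ",
                   paste(sf$snaps$point_id[!sf$snaps$reachable],
                         collapse = ", "),
                   class = "vectorops_validation_error")
  fac_nodes <- stats::setNames(sf$snaps$node_id, fac$id)

  sn <- snap_points(network, nb, config = config$snap)
  network <- sn$network
  reach <- sn$snaps$reachable
  unreachable <- cbind(nb[!reach, c("id", "x", "y")],
                       offset_m = sn$snaps$offset_m[!reach])
  nb_r <- nb[reach, ]
  nb_nodes <- sn$snaps$node_id[reach]
  if (!nrow(nb_r))
    stop_vectorops("no reachable neighborhoods",
                   class = "vectorops_validation_error")

  active <- fac_nodes[fac$id[fac$role == "active"]]

  # service-area bands from the active hubs
  dmin <- min_facility_distance(network, unname(active), nb_nodes)
  band <- assign_bin(dmin, config$bins)
  bins_summary <- summarize_bins(nb_r, dmin, config$bins)

  # closest-facility routing and access costs (baseline = active hubs)
  baseline <- access_costs(network, active, nb_nodes, nb_r, config$model)
  class_edges <- config$class_edges %||%
    cost_class_edges(baseline$total_cost_usd)
  cost_classes <- cost_bin_summary(baseline, nb_r, edges = class_edges)

  nb_out <- data.frame(nb_r[c("id", "x", "y", "population", "households",
                              "hci", "dengue_cases")],
                       node_id = nb_nodes,
                       min_hub_distance_km = unname(dmin),
                       service_band = as.character(band),
                       facility_id = baseline$facility_id,
                       one_way_km = baseline$one_way_km,
                       trips = baseline$trips,
                       per_trip_cost_usd = baseline$per_trip_cost_usd,
                       total_cost_usd = baseline$total_cost_usd,
                       per_trip_cost_usd_cents = round(baseline$per_trip_cost_usd, 2),
                       total_cost_usd_cents = round(baseline$total_cost_usd, 2),
                       stringsAsFactors = FALSE)

  # location-allocation over the full candidate pool (active + candidates)
  dm <- distance_matrix(network, unname(fac_nodes), nb_nodes)
  rownames(dm) <- names(fac_nodes)
  colnames(dm) <- nb_r$id
  allocations <- list()
  comparisons <- list()
  for (mode in config$modes) {
    w <- scenario_weights(nb_r, mode)
    alloc <- solve_enumerate(dm, names(fac_nodes), config$k, w)
    sel_nodes <- fac_nodes[alloc$selected]
    alt <- access_costs(network, sel_nodes, nb_nodes, nb_r, config$model)
    cmp <- compare_scenarios(baseline, alt, nb_r, class_edges = class_edges)
    allocations[[mode]] <- alloc
    comparisons[[mode]] <- cmp
    jsonlite::write_json(
      list(mode = mode, k = config$k, selected = alloc$selected,
           objective = alloc$objective, solver = alloc$solver,
           assignments = as.list(alloc$assignments)),
      file.path(out_dir, paste0("allocation_", mode, ".json")),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(cmp,
      file.path(out_dir, paste0("comparison_", mode, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  if (isTRUE(config$write_routes)) {
    routes <- extract_routes(network, baseline, fac_nodes,
                             stats::setNames(nb_nodes, nb_r$id))
    write_routes_geojson(routes, network, file.path(out_dir, "routes.geojson"))
  }

  utils::write.csv(nb_out, file.path(out_dir, "neighborhoods_out.csv"),
                   row.names = FALSE)
  utils::write.csv(unreachable, file.path(out_dir, "unreachable.csv"),
                   row.names = FALSE)
  utils::write.csv(bins_summary, file.path(out_dir, "bins_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(cost_classes, file.path(out_dir, "cost_classes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_neighborhoods = nrow(nb), n_reachable = nrow(nb_r),
         excluded = unreachable$id, solver = "exact",
         class_edges = class_edges,
         modes = config$modes, k = config$k),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(network = network, neighborhoods = nb_r,
                 facilities = fac, facility_nodes = fac_nodes,
                 neighborhood_nodes = nb_nodes,
                 min_hub_distance_km = dmin, bins_summary = bins_summary,
                 baseline_costs = baseline, cost_classes = cost_classes,
                 class_edges = class_edges,
                 allocations = allocations, comparisons = comparisons,
                 unreachable = unreachable))
}

# Shortest routes from each neighborhood's assigned facility, extracted in
# batch per facility via igraph (the deterministic single-pair API is
# shortest_path(); route geometry here is for display output).
extract_routes <- function(network, costs, fac_nodes, nb_nodes) {
  g <- net_igraph(network)
  routes <- list()
  for (fid in unique(costs$facility_id)) {
    if (is.na(fid)) next
    sel <- which(costs$facility_id == fid)
    targets <- nb_nodes[costs$id[sel]]
    sp <- igraph::shortest_paths(g, from = fac_nodes[[fid]], to = targets,
                                 weights = igraph::E(g)$weight,
                                 output = "vpath")
    for (i in seq_along(sel)) {
      seq_ids <- igraph::as_ids(sp$vpath[[i]])
      routes[[costs$id[sel[i]]]] <-
        new_route(fac_nodes[[fid]], targets[[i]], seq_ids,
                  costs$one_way_km[sel[i]])
    }
  }
  routes
}

#' Command-line entry point
#'
#' Subcommands: `run` (full bundle), `synth` (write a synthetic city),
#' `service-areas`, `routes`, `allocate`, `compare` (stage subsets of
#' `run`), each with `--config cfg.json`, `--seed N`, `--out DIR`.
#' A JSON config may override any [run_config()]/[city_config()] default
#' via sections `synth`, `snap`, `bins`, `model`, `allocation`, `inputs`.
#'
#' @param args character vector of CLI arguments
#'   (default `commandArgs(trailingOnly = TRUE)`)
#' @return integer exit status (0 on success), invisibly
#' @export
vectorops_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: vectorops <run|synth|service-areas|routes|allocate|compare>",
    "[--config cfg.json] [--seed N] [--out DIR]")
  status <- tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    cmd <- args[[1]]
    opts <- parse_cli_opts(args[-1])
    cfg <- build_run_config(opts)
    out <- opts$out %||% "vectorops_out"
    switch(cmd,
      synth = {
        write_city(generate_city(cfg$synth), out)
        message("synthetic city written to ", out)
      },
      run = ,
      `service-areas` = ,
      routes = ,
      allocate = ,
      compare = {
        if (cmd != "run") {
          cfg$modes <- if (cmd %in% c("allocate", "compare")) cfg$modes
                       else character(0)
          cfg$write_routes <- cmd %in% c("run", "routes")
        }
        res <- run_pipeline(cfg, out)
        message("report bundle written to ", out)
      },
      stop(usage, call. = FALSE))
    0L
  }, error = function(e) {
    message("vectorops error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% c("config", "seed", "out"))
      stop("unknown option: ", args[[i]], call. = FALSE)
    if (i == length(args)) stop("missing value for --", key, call. = FALSE)
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

# Merge a JSON config document and --seed into a run_config.
build_run_config <- function(opts) {
  doc <- if (!is.null(opts$config))
    jsonlite::fromJSON(opts$config, simplifyVector = TRUE) else list()
  synth_args <- as.list(doc$synth %||% list())
  if (!is.null(opts$seed)) synth_args$seed <- as.integer(opts$seed)
  synth <- do.call(city_config, synth_args)
  cfg <- run_config(
    network_path = doc$inputs$network %||% NULL,
    neighborhoods_path = doc$inputs$neighborhoods %||% NULL,
    facilities_path = doc$inputs$facilities %||% NULL,
    synth = synth,
    snap = do.call(snap_config, as.list(doc$snap %||% list())),
    bins = do.call(service_bins, as.list(doc$bins %||% list())),
    model = do.call(cost_model, as.list(doc$model %||% list())),
    k = doc$allocation$k %||% 2,
    modes = doc$allocation$modes %||%
      c("distance_only", "population", "dengue_cases", "hci"),
    class_edges = doc$class_edges %||% NULL,
    grade_maxima = doc$grade_maxima %||% NULL)
  cfg
}
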