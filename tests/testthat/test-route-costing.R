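test_that("cost_model validates its parameters", {
  m <- cost_model()
  expect_equal(m$fuel_price_per_l, 0.61)
  expect_equal(m$fuel_economy_km_per_l, 5.53)
  expect_equal(m$households_per_trip, 25)
  expect_error(cost_model(fuel_price_per_l = 0),
               class = "vectorops_validation_error")
  expect_error(cost_model(households_per_trip = 2.5),
               class = "vectorops_validation_error")
})

test_that("trips_required is the ceiling of households over capacity", {
  m <- cost_model()
  expect_identical(trips_required(c(0, 1, 25, 26, 50, 51), m),
                   c(0L, 1L, 1L, 2L, 2L, 3L))
  expect_error(trips_required(-1, m), class = "vectorops_validation_error")
})

test_that("round_trip_fuel_cost follows the fuel model", {
  m <- cost_model()
  expect_equal(round_trip_fuel_cost(0, m), 0)
  # one fuel-economy unit each way = exactly 2 L
  expect_equal(round_trip_fuel_cost(5.53, m), 2 * 0.61)
  # longest observed one-way route rounds to the printed $1.28
  expect_equal(round(round_trip_fuel_cost(5.78, m), 2), 1.28)
  # linear scalings: doubling price doubles cost, doubling economy halves it
  expect_equal(round_trip_fuel_cost(3, cost_model(fuel_price_per_l = 1.22)),
               2 * round_trip_fuel_cost(3, m))
  expect_equal(round_trip_fuel_cost(3, cost_model(fuel_economy_km_per_l = 11.06)),
               round_trip_fuel_cost(3, m) / 2)
})

test_that("closest_facility picks the nearest facility, ties to smallest id", {
  ln <- line_net(5)
  fac <- c(F0 = "v0", F4 = "v4")
  res <- closest_facility(ln, fac, "v1")
  expect_equal(res$facility_id, "F0")
  expect_equal(res$route$length_km, 1)
  # equidistant demand: smaller facility id wins
  tie <- closest_facility(ln, fac, "v2")
  expect_equal(tie$facility_id, "F0")
  # single facility
  expect_equal(closest_facility(ln, c(F4 = "v4"), "v1")$facility_id, "F4")
})

test_that("neighborhood_access_cost composes trips and fuel", {
  m <- cost_model()
  r553 <- structure(list(origin = "h", destination = "n",
                         node_sequence = c("h", "n"), length_km = 5.53,
                         reachable = TRUE), class = "route")
  cost <- neighborhood_access_cost(r553, 50, m)
  expect_equal(cost$trips, 2L)
  expect_equal(cost$total_cost_usd, 2 * 1.22)
  # single-trip case matches the route cost endpoint
  r578 <- structure(list(origin = "h", destination = "n",
                         node_sequence = c("h", "n"), length_km = 5.78,
                         reachable = TRUE), class = "route")
  expect_equal(round(neighborhood_access_cost(r578, 25, m)$total_cost_usd, 2),
               1.28)
  # zero households cost nothing
  expect_equal(neighborhood_access_cost(r578, 0, m)$total_cost_usd, 0)
})

test_that("access cost is monotone in households and distance", {
  m <- cost_model()
  mk <- function(km) structure(list(origin = "h", destination = "n",
                                    node_sequence = c("h", "n"),
                                    length_km = km, reachable = TRUE),
                               class = "route")
  set.seed(31)
  hh <- sort(sample(0:200, 20))
  costs_h <- vapply(hh, function(h)
    neighborhood_access_cost(mk(3), h, m)$total_cost_usd, numeric(1))
  expect_true(all(diff(costs_h) >= 0))
  kms <- sort(runif(20, 0.1, 8))
  costs_d <- vapply(kms, function(km)
    neighborhood_access_cost(mk(km), 30, m)$total_cost_usd, numeric(1))
  expect_true(all(diff(costs_d) > 0))
})

test_that("cost_bin_summary classes costs and cross-checks service areas", {
  nb <- tiny_neighborhoods()
  costs <- data.frame(id = c("N1", "N2"), facility_id = "F",
                      one_way_km = c(1, 3), trips = c(2, 4),
                      per_trip_cost_usd = c(0.5, 1.25),
                      total_cost_usd = c(1, 5))
  s <- cost_bin_summary(costs, nb, edges = c(2, 10))
  expect_equal(s$n_neighborhoods, c(1, 1))
  expect_equal(s$population, c(100, 300))
  expect_error(cost_bin_summary(costs, nb, edges = c(10, 2)),
               class = "vectorops_validation_error")
  # all equal costs: single nonempty quantile class
  costs$total_cost_usd <- 2
  s2 <- cost_bin_summary(costs, nb)
  expect_equal(sum(s2$n_neighborhoods > 0), 1)

  # cross-module consistency on a synthetic city: closest-facility distance
  # equals min_facility_distance, and classes partition neighborhoods
  city <- generate_city(small_city_config(seed = 4))
  sn <- snap_points(city$network, city$neighborhoods)
  hubs <- setNames(city$facilities$node_id[city$facilities$role == "active"],
                   city$facilities$id[city$facilities$role == "active"])
  nbr <- city$neighborhoods[sn$snaps$reachable, ]
  nodes <- sn$snaps$node_id[sn$snaps$reachable]
  ac <- access_costs(sn$network, hubs, nodes, nbr)
  dmin <- min_facility_distance(sn$network, unname(hubs), nodes)
  expect_equal(ac$one_way_km, unname(dmin), tolerance = 1e-9)
  s3 <- cost_bin_summary(ac, nbr)
  expect_equal(sum(s3$n_neighborhoods), nrow(nbr))
})
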