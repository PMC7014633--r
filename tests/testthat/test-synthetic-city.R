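test_that("generate_network builds a connected jittered grid", {
  cfg <- city_config(rows = 3, cols = 3, jitter_m = 0, edge_dropout = 0,
                     spacing_m = 250)
  net <- generate_network(cfg, seed = 1)
  expect_equal(nrow(net$nodes), 9)
  expect_equal(nrow(net$edges), 12)
  expect_equal(net$edges$length_km, rep(0.25, 12))

  # dropout keeps the graph connected, any seed
  cfg2 <- small_city_config(edge_dropout = 0.3)
  for (seed in c(1, 7, 99)) {
    net2 <- generate_network(cfg2, seed = seed)
    expect_equal(attr(net2, "n_components"), 1)
    expect_lt(nrow(net2$edges), 2 * 8 * 7)  # some edges actually dropped
  }

  # determinism
  expect_identical(generate_network(cfg2, seed = 5),
                   generate_network(cfg2, seed = 5))
})

test_that("generate_neighborhoods follows the stated attribute models", {
  cfg <- small_city_config()
  net <- generate_network(cfg, seed = 2)

  # degenerate gradient: all HCI equal beta0
  cfg0 <- small_city_config(hci_beta1 = 0, hci_noise_sd = 0)
  nb0 <- generate_neighborhoods(net, cfg0, seed = 3)
  expect_true(all(nb0$hci == cfg0$hci_beta0))
  expect_true(all(nb0$population >= 1))
  expect_true(all(nb0$households >= 1))
  expect_true(all(nb0$dengue_cases >= 0))

  # strong decay concentrates cases centrally (inner half vs outer half)
  cfg_hot <- small_city_config(dengue_lambda = 6)
  cx <- mean(net$nodes$x); cy <- mean(net$nodes$y)
  ok <- 0
  for (seed in 1:20) {
    nb <- generate_neighborhoods(net, cfg_hot, seed = seed)
    d <- sqrt((nb$x - cx)^2 + (nb$y - cy)^2)
    inner <- d <= stats::median(d)
    rate_in <- sum(nb$dengue_cases[inner]) / sum(nb$population[inner])
    rate_out <- sum(nb$dengue_cases[!inner]) / sum(nb$population[!inner])
    ok <- ok + (rate_in > rate_out)
  }
  expect_gte(ok, 19)

  # HCI correlates positively with center distance under defaults
  pos <- 0
  for (seed in 1:50) {
    nb <- generate_neighborhoods(net, cfg, seed = seed)
    d <- sqrt((nb$x - cx)^2 + (nb$y - cy)^2)
    pos <- pos + (stats::cor(nb$hci, d, method = "spearman") > 0)
  }
  expect_gte(pos, 48)  # >= 95% of seeds
})

test_that("place_facilities yields central hubs and stratified candidates", {
  cfg <- small_city_config()
  net <- generate_network(cfg, seed = 6)
  fac <- place_facilities(net, cfg, seed = 6)
  expect_equal(sum(fac$role == "active"), 2)
  expect_equal(sum(fac$role == "candidate"), 8)
  expect_true(all(fac$node_id %in% net$nodes$id))

  # hubs lie in the innermost center-distance quartile
  cx <- mean(net$nodes$x); cy <- mean(net$nodes$y)
  dn <- sqrt((net$nodes$x - cx)^2 + (net$nodes$y - cy)^2)
  hub_d <- dn[match(fac$node_id[fac$role == "active"], net$nodes$id)]
  expect_true(all(hub_d <= stats::quantile(dn, 0.25)))

  # candidates cover all four quadrants
  cand <- fac[fac$role == "candidate", ]
  quad <- 1 + (cand$x >= cx) + 2 * (cand$y >= cy)
  expect_setequal(unique(quad), 1:4)

  # no candidates requested
  fac0 <- place_facilities(net, small_city_config(n_candidates = 0), seed = 1)
  expect_equal(nrow(fac0), 2)

  expect_identical(place_facilities(net, cfg, seed = 9),
                   place_facilities(net, cfg, seed = 9))
})

test_that("generate_city is fully deterministic under a fixed seed", {
  a <- generate_city(small_city_config(seed = 123))
  b <- generate_city(small_city_config(seed = 123))
  expect_identical(a$network, b$network)
  expect_identical(a$neighborhoods, b$neighborhoods)
  expect_identical(a$facilities, b$facilities)
  c2 <- generate_city(small_city_config(seed = 124))
  expect_false(identical(a$neighborhoods, c2$neighborhoods))

  # every neighborhood lies within the snap tolerance of the network
  sn <- snap_points(a$network, a$neighborhoods,
                    snap_config(a$config$snap_tolerance_m))
  expect_true(all(sn$snaps$reachable))
})
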