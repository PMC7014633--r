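test_that("scenario_weights maps modes to attributes", {
  nb <- tiny_neighborhoods()
  expect_equal(unname(scenario_weights(nb, "distance_only")), rep(1, 3))
  expect_equal(unname(scenario_weights(nb, "population")), c(100, 300, 50))
  expect_equal(unname(scenario_weights(nb, "dengue_cases")), c(1, 3, 0))
  expect_equal(unname(scenario_weights(nb, "hci")), c(0.2, 0.4, 0.3))
  expect_error(scenario_weights(nb, "bogus"))
})

test_that("pmedian_objective sums weighted nearest distances", {
  ln <- line_net(5)
  dm <- distance_matrix(ln, ln$nodes$id, ln$nodes$id)
  expect_equal(pmedian_objective(dm, "v2", rep(1, 5)), 6)  # 2+1+0+1+2
  expect_equal(pmedian_objective(dm, "v2", rep(0, 5)), 0)
  expect_equal(pmedian_objective(dm, ln$nodes$id, runif(5)), 0)
  expect_error(pmedian_objective(dm, character(0), rep(1, 5)),
               class = "vectorops_validation_error")
})

test_that("solve_enumerate finds the exhaustive optimum", {
  ln <- line_net(5)
  dm <- distance_matrix(ln, c("v0", "v2", "v4"), ln$nodes$id)
  w <- c(5, 1, 1, 1, 3)
  oracle <- pmedian_brute(dm, rownames(dm), 1, w)
  res <- solve_enumerate(dm, k = 1, weights = w)
  expect_equal(res$selected, oracle$selected)
  expect_equal(res$objective, oracle$objective)

  # k = |candidates|: everything selected, minimal possible objective
  all_res <- solve_enumerate(dm, k = 3, weights = w)
  expect_equal(all_res$selected, c("v0", "v2", "v4"))

  # positive weight scaling leaves the selection unchanged, scales objective
  res10 <- solve_enumerate(dm, k = 1, weights = 10 * w)
  expect_equal(res10$selected, res$selected)
  expect_equal(res10$objective, 10 * res$objective)

  # objective recomputes from assignments (internal consistency)
  d_assigned <- dm[cbind(res$assignments, colnames(dm))]
  expect_equal(sum(w * d_assigned), res$objective, tolerance = 1e-9)

  expect_error(solve_enumerate(dm, k = 2, weights = w, enumeration_limit = 1),
               class = "vectorops_limit_error")
})

test_that("enumerated optimum beats every k-subset on random instances", {
  set.seed(13)
  for (rep in 1:5) {
    inst <- rand_pmedian_instance(n_cand = sample(5:12, 1), n_dem = 30)
    k <- sample(2:3, 1)
    res <- solve_enumerate(inst$dm, k = k, weights = inst$weights)
    for (s in utils::combn(rownames(inst$dm), k, simplify = FALSE))
      expect_lte(res$objective,
                 pmedian_objective(inst$dm, s, inst$weights) + 1e-12)
    # adding a candidate never increases the optimum
    bigger <- rbind(inst$dm, fx = runif(ncol(inst$dm), 0, 10))
    res2 <- solve_enumerate(bigger, k = k, weights = inst$weights)
    expect_lte(res2$objective, res$objective + 1e-12)
  }
})

test_that("Teitz-Bart is seeded, reproducible and bounded below by exact", {
  set.seed(17)
  inst <- rand_pmedian_instance(n_cand = 9, n_dem = 40)
  exact <- solve_enumerate(inst$dm, k = 3, weights = inst$weights)
  h1 <- solve_teitz_bart(inst$dm, k = 3, weights = inst$weights,
                         restarts = 5, seed = 123)
  h2 <- solve_teitz_bart(inst$dm, k = 3, weights = inst$weights,
                         restarts = 5, seed = 123)
  expect_identical(h1$selected, h2$selected)
  expect_identical(h1$objective, h2$objective)
  expect_gte(h1$objective, exact$objective - 1e-12)
  expect_equal(h1$solver, "heuristic")
  # k = |candidates| is trivially exact
  hall <- solve_teitz_bart(inst$dm, k = 9, weights = inst$weights, seed = 1)
  expect_equal(hall$objective,
               pmedian_objective(inst$dm, rownames(inst$dm), inst$weights))
})

test_that("compare_scenarios reports the two headline metrics", {
  nb <- tiny_neighborhoods()
  base <- data.frame(id = c("N1", "N2", "N3"), facility_id = "F",
                     one_way_km = 1, trips = 1,
                     per_trip_cost_usd = 1,
                     total_cost_usd = c(2, 4, 6))
  alt <- base
  alt$total_cost_usd <- c(1.5, 2, 4.5)  # mean 4 -> 8/3
  cmp <- compare_scenarios(base, alt, nb, class_edges = c(2, 6))
  expect_equal(cmp$mean_cost_reduction_pct, (4 - 8 / 3) / 4 * 100)
  # cheapest class (0,2]: base holds N1 (pop 100); alt adds N2 (pop 300)
  expect_equal(cmp$cheapest_class_population_change_pct, 300)
  ident <- compare_scenarios(base, base, nb, class_edges = c(2, 6))
  expect_equal(ident$mean_cost_reduction_pct, 0)
  expect_equal(ident$cheapest_class_population_change_pct, 0)
  expect_error(compare_scenarios(base, alt[1:2, ], nb),
               class = "vectorops_structural_error")
})
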