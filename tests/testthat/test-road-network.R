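test_that("build_network validates structure and derives Euclidean lengths", {
  net <- build_network(
    data.frame(id = c("a", "b"), x = c(0, 1000), y = c(0, 0)),
    data.frame(from = "a", to = "b"))
  expect_equal(net$edges$length_km, 1)
  expect_equal(attr(net, "n_components"), 1)

  sq <- unit_square_net()
  expect_equal(nrow(sq$nodes), 4)
  expect_equal(nrow(sq$edges), 5)

  expect_error(
    build_network(data.frame(id = "a", x = 0, y = 0),
                  data.frame(from = "a", to = "Z")),
    class = "vectorops_structural_error")
  expect_error(
    build_network(data.frame(id = c("a", "b"), x = c(0, 1), y = 0),
                  data.frame(from = "a", to = "b", length_km = -2)),
    class = "vectorops_validation_error")
})

test_that("snap_point attaches at the nearest edge projection", {
  net <- build_network(
    data.frame(id = c("a", "b"), x = c(0, 1000), y = c(0, 0)),
    data.frame(from = "a", to = "b"))

  res <- snap_point(net, c(400, 100), "p")
  expect_true(res$snap$reachable)
  expect_equal(res$snap$offset_m, 100)
  vn <- res$network$nodes[res$network$nodes$id == "pt_p", ]
  expect_equal(c(vn$x, vn$y), c(400, 0))
  # split edges sum to the host edge length
  expect_equal(sum(res$network$edges$length_km), 1)

  # oracle: densely sample every edge point, offset must match the minimum
  t <- seq(0, 1, length.out = 20001)
  oracle <- min(sqrt((400 - t * 1000)^2 + 100^2))
  expect_equal(res$snap$offset_m, oracle, tolerance = 1e-6)

  # exactly on a node: reuse the node, no split
  on_node <- snap_point(net, c(0, 0), "q")
  expect_equal(on_node$snap$node_id, "a")
  expect_equal(on_node$snap$offset_m, 0)
  expect_equal(nrow(on_node$network$edges), 1)

  # beyond tolerance: flagged, network untouched
  far <- snap_point(net, c(500, 600), "r", snap_config(500))
  expect_false(far$snap$reachable)
  expect_identical(far$network$edges, net$edges)

  empty <- build_network(data.frame(id = character(0), x = numeric(0),
                                    y = numeric(0)),
                         data.frame(from = character(0), to = character(0),
                                    length_km = numeric(0)))
  expect_error(snap_point(empty, c(0, 0)), class = "vectorops_structural_error")
})

test_that("snapping preserves pre-existing pairwise distances", {
  set.seed(42)
  for (rep in 1:5) {
    net <- rand_net(15)
    ids <- net$nodes$id
    before <- distance_matrix(net, ids, ids)
    pt <- c(runif(1, 0, 5000), runif(1, 0, 5000))
    res <- snap_point(net, pt, paste0("s", rep), snap_config(1e6))
    after <- distance_matrix(res$network, ids, ids)
    expect_equal(after, before, tolerance = 1e-9)
  }
})

test_that("shortest_path returns minimal routes with stated conventions", {
  sq <- unit_square_net()
  r <- shortest_path(sq, "A", "C")
  expect_equal(r$length_km, 1.5)          # diagonal beats 2.0 via B
  expect_equal(r$node_sequence, c("A", "C"))

  same <- shortest_path(sq, "B", "B")
  expect_equal(same$length_km, 0)
  expect_equal(same$node_sequence, "B")

  # reversal invariance of length
  expect_equal(shortest_path(sq, "D", "B")$length_km,
               shortest_path(sq, "B", "D")$length_km)

  # equal-length tie broken by lexicographically smallest node sequence:
  # two 2 km routes B->A->D and B->C->D
  no_diag <- build_network(sq$nodes,
                           sq$edges[sq$edges$length_km == 1, ])
  tie <- shortest_path(no_diag, "B", "D")
  expect_equal(tie$length_km, 2)
  expect_equal(tie$node_sequence, c("B", "A", "D"))

  # cross-component query is a "no route" result, not an error
  two_comp <- build_network(
    data.frame(id = c("a", "b", "c", "d"), x = c(0, 1, 10, 11) * 1000, y = 0),
    data.frame(from = c("a", "c"), to = c("b", "d"), length_km = 1))
  nr <- shortest_path(two_comp, "a", "c")
  expect_false(nr$reachable)
  expect_equal(nr$length_km, Inf)
})

test_that("shortest paths match the Floyd-Warshall oracle on random graphs", {
  set.seed(7)
  for (rep in 1:25) {
    net <- rand_net(sample(5:30, 1))
    ids <- net$nodes$id
    D <- fw_distances(net)
    dm <- distance_matrix(net, ids, ids)
    expect_equal(dm, D, tolerance = 1e-9)
    # spot-check the route extractor against the oracle too
    pick <- matrix(ids[sample(length(ids), 6, replace = TRUE)], ncol = 2)
    for (rr in seq_len(nrow(pick))) {
      rt <- shortest_path(net, pick[rr, 1], pick[rr, 2])
      expect_equal(rt$length_km, D[pick[rr, 1], pick[rr, 2]],
                   tolerance = 1e-9)
      if (rt$reachable && length(rt$node_sequence) > 1) {
        steps <- cbind(rt$node_sequence[-length(rt$node_sequence)],
                       rt$node_sequence[-1])
        key <- paste(pmin(steps[, 1], steps[, 2]),
                     pmax(steps[, 1], steps[, 2]))
        ekey <- paste(pmin(net$edges$from, net$edges$to),
                      pmax(net$edges$from, net$edges$to))
        expect_true(all(key %in% ekey))  # consecutive pairs are edges
      }
    }
  }
})

test_that("distance_matrix is symmetric, obeys the triangle inequality", {
  set.seed(99)
  net <- rand_net(20)
  ids <- net$nodes$id
  dm <- distance_matrix(net, ids, ids)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (k in seq_along(ids))
    expect_true(all(dm <= outer(dm[, k], dm[k, ], "+") + 1e-9))
  expect_error(distance_matrix(net, "nope", ids),
               class = "vectorops_structural_error")

  ln <- line_net(5)
  dm2 <- distance_matrix(ln, c("v0", "v4"), ln$nodes$id)
  expect_equal(unname(dm2["v0", ]), 0:4)
  expect_equal(unname(dm2["v4", ]), 4:0)
})
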