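test_that("the spatial embedding is a complete graph partitioned by group", {
  set.seed(3)
  g <- build_spatial_graph(clusters_config(n_nodes = 4L, n_groups = 2L))
  expect_identical(nrow(g$edges), 6L) # C(4, 2)
  expect_true(all(g$edges$length > 0))

  g31 <- build_spatial_graph(clusters_config())
  expect_length(g31$group, 31L)
  expect_identical(as.integer(table(g31$group)), c(8L, 8L, 8L, 7L))
  # vanishing spread: intra-group lengths collapse, inter-group ones do not
  tight <- build_spatial_graph(clusters_config(spread = 1e-6))
  intra <- tight$group[tight$edges$i] == tight$group[tight$edges$j]
  expect_lt(max(tight$edges$length[intra]), 1e-4)
  expect_gt(min(tight$edges$length[!intra]), 0.9)
})

test_that("temperature schedules span the reciprocal edge-length range", {
  g <- fake_spatial_graph(rbind(c(0, 0), c(0.5, 0), c(2.5, 0)),
                          edges = data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  # edge lengths are {0.5, 2.0}
  expect_equal(temperature_schedule(g, 2L), c(0.5, 2.0))
  expect_equal(temperature_schedule(g, 4L), c(0.5, 1.0, 1.5, 2.0))
  same <- fake_spatial_graph(rbind(c(0, 0), c(1, 0)),
                             edges = data.frame(i = 1L, j = 2L))
  expect_equal(temperature_schedule(same, 3L), rep(1, 3L))
  degenerate <- g
  degenerate$edges$length[1L] <- 0
  expect_error(temperature_schedule(degenerate, 3L), "zero-length")
})

test_that("annealing stops at the first step separating the groups", {
  coords <- rbind(c(0, 0), c(0, 0.1), c(0.05, 0.05),
                  c(1, 0), c(1, 0.1), c(0.95, 0.05))
  g <- fake_spatial_graph(coords, group = rep(1:2, each = 3L))
  sched <- temperature_schedule(g, 50L)
  out <- anneal_edges(g, sched, 2L)
  # oracle: brute-force the schedule on the fixed coordinates
  expected_step <- NA_integer_
  for (s in seq_along(sched)) {
    kept <- g$edges[g$edges$length < 1 / sched[s], ]
    ig <- igraph::graph_from_edgelist(as.matrix(kept[c("i", "j")]),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, 6L - igraph::vcount(ig))
    comp <- igraph::components(ig)
    if (comp$no == 2L && min(comp$csize) >= 2L) { expected_step <- s; break }
  }
  expect_identical(attr(out, "stop_step"), expected_step)
  expect_identical(length(unique(out$component)), 2L)
  # every surviving edge is intra-group
  expect_true(all(out$group[out$edges$i] == out$group[out$edges$j]))
  # an already-separated graph is returned unchanged at step 0
  pre <- out
  again <- anneal_edges(pre, sched, 2L)
  expect_identical(attr(again, "stop_step"), 0L)
  expect_identical(again$edges, pre$edges)
})

test_that("component count is monotone along the deletion schedule", {
  set.seed(11)
  g <- build_spatial_graph(clusters_config(n_nodes = 12L, n_groups = 3L,
                                           spread = 0.05))
  sched <- temperature_schedule(g, 40L)
  prev <- 1L
  for (s in seq_along(sched)) {
    kept <- g$edges[g$edges$length < 1 / sched[s], , drop = FALSE]
    memb <- motifemerge:::.component_membership(12L, kept)
    expect_gte(max(memb), prev)
    prev <- max(memb)
  }
})

test_that("topological ordering roots at the centroid and directs outward", {
  # path 1-2-3 whose node 1 sits nearest the centroid, so it is the root
  path <- fake_spatial_graph(rbind(c(2, 0), c(0, 0), c(6, 0)),
                             edges = data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  topo <- direct_and_order(path, 1:3)
  expect_identical(unname(topo$order), c(1L, 2L, 3L))
  expect_identical(topo$edges$from, c(1L, 2L))
  expect_identical(topo$edges$to, c(2L, 3L))

  star <- fake_spatial_graph(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, -1)),
                             edges = data.frame(i = rep(1L, 3L), j = 2:4))
  topo <- direct_and_order(star, 1:4)
  expect_identical(unname(topo$order), c(1L, 2L, 2L, 2L))
  expect_true(all(topo$edges$from == 1L)) # root has in-degree 0

  pair <- fake_spatial_graph(rbind(c(0, 0), c(1, 0)),
                             edges = data.frame(i = 1L, j = 2L))
  topo <- direct_and_order(pair, 1:2)
  expect_identical(unname(topo$order), c(1L, 2L))
  expect_identical(nrow(topo$edges), 1L)

  disconnected <- fake_spatial_graph(rbind(c(0, 0), c(1, 0), c(5, 5)),
                                     edges = data.frame(i = 1L, j = 2L))
  expect_error(direct_and_order(disconnected, 1:3), "disconnected")
})

test_that("cluster samples encode the selected group's topological order", {
  ds <- generate_clusters_dataset(clusters_config(n_samples = 10000L,
                                                  seed = 21))
  rows <- unique(ds$x)
  expect_identical(nrow(rows), 4L)
  groups <- attr(ds, "node_groups")
  for (r in seq_len(nrow(rows))) {
    active <- which(rows[r, ] != -1)
    expect_identical(length(unique(groups[active])), 1L)
    expect_setequal(active, which(groups == groups[active[1L]]))
    expect_identical(min(rows[r, active]), 1) # unique root at order 1
    expect_identical(sum(rows[r, active] == 1), 1L)
  }
  # uniform group selection within 3 binomial standard errors
  freq <- as.numeric(table(factor(ds$y, levels = 0:3))) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))
  # deterministic pattern per label
  for (lab in 0:3) {
    expect_identical(nrow(unique(ds$x[ds$y == lab, , drop = FALSE])), 1L)
  }
})

test_that("class patterns are exactly linearly separable", {
  ds <- generate_clusters_dataset(clusters_config(n_samples = 400L, seed = 8))
  pat <- unique(ds$x)
  X <- cbind(1, pat)
  for (cls in seq_len(nrow(pat))) {
    y <- ifelse(seq_len(nrow(pat)) == cls, 1, -1)
    # minimum-norm interpolating hyperplane through the 4 patterns
    w <- t(X) %*% solve(X %*% t(X), y)
    expect_true(all(sign(X %*% w) == y)) # one-vs-rest separation
  }
})

test_that("the clusters covariance is block structured", {
  ds <- generate_clusters_dataset(clusters_config(n_samples = 4000L,
                                                  seed = 31))
  contrast <- covariance_block_contrast(ds)
  expect_gt(contrast$within, contrast$between)
  # a constant dataset has an exactly zero covariance
  const <- motif_dataset(matrix(1, 5L, 3L), rep(0L, 5L))
  expect_true(all(covariance_matrix(const) == 0))
})
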