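# Independent oracles and fixture builders used across the suite.

# Erdos-Renyi style random simple digraph on n nodes (0-based ids).
random_digraph <- function(n, p = 0.3) {
  pairs <- expand.grid(from = seq_len(n) - 1L, to = seq_len(n) - 1L)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  motif_digraph(pairs[keep, , drop = FALSE], n_nodes = n)
}

# Random layered digraph: full bipartite stacks thinned to probability p.
random_layered_digraph <- function(sizes, p = 0.5) {
  offsets <- cumsum(c(0L, sizes))
  edges <- do.call(rbind, lapply(seq_len(length(sizes) - 1L), function(l) {
    expand.grid(from = offsets[l] + seq_len(sizes[l]) - 1L,
                to = offsets[l + 1L] + seq_len(sizes[l + 1L]) - 1L)
  }))
  edges <- edges[stats::runif(nrow(edges)) < p, , drop = FALSE]
  motif_digraph(edges, n_nodes = sum(sizes),
                layer = rep(seq_along(sizes), times = sizes))
}

# Brute-force census over all C(n, k) node subsets: keep weakly connected
# induced subgraphs, classify with canonical_code. Independent of ESU.
brute_force_census <- function(graph, k, colored = FALSE) {
  n <- graph$n_nodes
  if (n < k) return(stats::setNames(integer(), character()))
  A <- matrix(0L, n, n)
  if (nrow(graph$edges) > 0L) {
    A[cbind(graph$edges$from + 1L, graph$edges$to + 1L)] <-
      if (colored) c(mild = 1L, strong_positive = 2L,
                     strong_negative = 3L)[as.character(graph$edges$category)]
      else 1L
  }
  und <- (A != 0) | t(A != 0)
  counts <- new.env(parent = emptyenv())
  subsets <- utils::combn(n, k)
  for (col in seq_len(ncol(subsets))) {
    S <- subsets[, col]
    u <- und[S, S]
    # weak connectivity by reachability expansion from node 1
    reach <- c(TRUE, rep(FALSE, k - 1L))
    repeat {
      new <- (colSums(u[reach, , drop = FALSE]) > 0) & !reach
      if (!any(new)) break
      reach <- reach | new
    }
    if (!all(reach)) next
    m <- A[S, S]
    code <- if (colored) canonical_code((m != 0) + 0L, m)
            else canonical_code(m)
    key <- sprintf("%.0f", code)
    counts[[key]] <- if (is.null(counts[[key]])) 1L else counts[[key]] + 1L
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(kk) counts[[kk]], integer(1)), keys)
}

# Compare an ESU census against the brute-force oracle.
expect_census_matches_brute_force <- function(graph, k, colored = FALSE) {
  cen <- count_subgraphs(graph, k, colored = colored)
  oracle <- brute_force_census(graph, k, colored = colored)
  got <- stats::setNames(cen$count, sprintf("%.0f", cen$code))
  expect_identical(got[order(names(got))], oracle[order(names(oracle))])
  expect_identical(attr(cen, "total"), as.integer(sum(oracle)))
}

# Spatial-graph fixture with hand-chosen coordinates; complete edges unless
# an explicit edge table is given.
fake_spatial_graph <- function(coords, group = rep(1L, nrow(coords)),
                               edges = NULL) {
  coords <- as.matrix(coords)
  if (is.null(edges)) {
    pairs <- utils::combn(nrow(coords), 2L)
    edges <- data.frame(i = pairs[1L, ], j = pairs[2L, ])
  }
  edges$length <- sqrt(rowSums((coords[edges$i, , drop = FALSE] -
                                coords[edges$j, , drop = FALSE])^2))
  structure(list(coords = coords, group = as.integer(group), edges = edges),
            class = "spatial_graph")
}

# Hand-built single-layer parameter object holding the given weight matrix.
params_from_matrix <- function(w) {
  structure(list(W = list(w), b = list(numeric(ncol(w))),
                 layer_sizes = c(nrow(w), ncol(w))),
            class = "mlp_parameters")
}
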