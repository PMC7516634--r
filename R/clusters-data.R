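#' Configuration for the independent-clusters environment
#'
#' The independent-clusters generator embeds `n_nodes` points around
#' `n_groups` well-separated planar centers, connects them completely with
#' edges weighted by Euclidean length, then deletes long edges along a rising
#' temperature schedule until exactly `n_groups` disjoint, intra-connected
#' groups remain. Each group is directed by topological order from a root
#' node; a data sample selects one group and sets its nodes to their
#' topological order, all other features to -1, yielding a block-diagonal
#' covariance.
#'
#' @param n_nodes number of graph nodes = features (default 31, matching the
#'   depth-5 binary tree).
#' @param n_groups number of independent groups = classes (default 4).
#' @param max_schedule_steps number of equally spaced temperature steps made
#'   available to the annealing (default 500).
#' @param spread standard deviation of the Gaussian scatter of nodes around
#'   their group center, in units of the unit square (default 0.08).
#' @param n_samples number of samples a dataset draw produces.
#' @param seed optional integer seed for [generate_clusters_dataset()].
#' @return An object of class `clusters_config`.
#' @export
clusters_config <- function(n_nodes = 31L, n_groups = 4L,
                            max_schedule_steps = 500L, spread = 0.08,
                            n_samples = 4000L, seed = NULL) {
  n_nodes <- as.integer(n_nodes); n_groups <- as.integer(n_groups)
  if (n_groups < 2L) stop("`n_groups` must be >= 2")
  if (n_groups > n_nodes) stop("`n_groups` cannot exceed `n_nodes`")
  if (n_nodes < 2L * n_groups) stop("every group needs at least 2 nodes")
  if (spread <= 0) stop("`spread` must be positive")
  if (max_schedule_steps < 2L) stop("`max_schedule_steps` must be >= 2")
  if (n_samples < 1L) stop("`n_samples` must be positive")
  structure(list(n_nodes = n_nodes, n_groups = n_groups,
                 max_schedule_steps = as.integer(max_schedule_steps),
                 spread = spread, n_samples = as.integer(n_samples),
                 seed = seed),
            class = "clusters_config")
}

# group centers: unit-square corners for 4 groups, otherwise a circle
.group_centers <- function(n_groups) {
  if (n_groups == 4L) {
    matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  } else {
    th <- 2 * pi * (seq_len(n_groups) - 1L) / n_groups
    cbind(cos(th), sin(th))
  }
}

# near-even partition of n nodes into k groups, e.g. 31 into (8, 8, 8, 7)
.group_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Embed nodes around group centers and connect them completely
#'
#' @param config a [clusters_config()]. Uses the current RNG state; seed via
#'   `set.seed()` or use [generate_clusters_dataset()].
#' @return An object of class `spatial_graph`: node coordinates, per-node
#'   group assignment and the complete edge table with Euclidean lengths.
#' @export
build_spatial_graph <- function(config) {
  stopifnot(inherits(config, "clusters_config"))
  centers <- .group_centers(config$n_groups)
  sizes <- .group_sizes(config$n_nodes, config$n_groups)
  group <- rep(seq_len(config$n_groups), times = sizes)
  coords <- centers[group, , drop = FALSE] +
    matrix(stats::rnorm(2L * config$n_nodes, sd = config$spread), ncol = 2)
  pairs <- utils::combn(config$n_nodes, 2L)
  len <- sqrt((coords[pairs[1L, ], 1L] - coords[pairs[2L, ], 1L])^2 +
              (coords[pairs[1L, ], 2L] - coords[pairs[2L, ], 2L])^2)
  if (any(len == 0)) stop("degenerate geometry: coincident nodes")
  structure(list(coords = coords, group = group,
                 edges = data.frame(i = pairs[1L, ], j = pairs[2L, ],
                                    length = len)),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges, %d groups\n",
              nrow(x$coords), nrow(x$edges), length(unique(x$group))))
  invisible(x)
}

#' Rising temperature schedule for edge annealing
#'
#' Equally spaced temperatures from the reciprocal of the longest edge to the
#' reciprocal of the shortest edge. Unlike simulated annealing the
#' temperature rises: at temperature T every edge of length >= 1/T is
#' deleted, so later steps delete more.
#'
#' @param graph a [build_spatial_graph()] result.
#' @param n_steps number of schedule steps (>= 2).
#' @return Numeric vector of `n_steps` non-decreasing temperatures.
#' @export
temperature_schedule <- function(graph, n_steps) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (nrow(graph$edges) < 1L) stop("graph has no edges")
  if (n_steps < 2L) stop("`n_steps` must be >= 2")
  len <- graph$edges$length
  if (any(len <= 0)) stop("degenerate geometry: zero-length edge")
  seq(1 / max(len), 1 / min(len), length.out = n_steps)
}

.component_membership <- function(n_nodes, edges) {
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  igraph::components(g)$membership
}

#' Delete long edges until the groups disconnect
#'
#' Walks the schedule, at each temperature T deleting every edge of length
#' >= 1/T, and stops at the first step after which the surviving graph has
#' exactly `n_groups` connected components none of which is an isolated node.
#' Deletion is monotone, so the component count never decreases; if it jumps
#' past `n_groups`, or the schedule ends first, annealing fails and the
#' caller should retry with a new geometry seed.
#'
#' @param graph a [build_spatial_graph()] result.
#' @param schedule temperatures from [temperature_schedule()].
#' @param n_groups target number of components.
#' @return The input graph with its `edges` reduced to the survivors and an
#'   added `component` membership vector; attribute `"stop_step"` records the
#'   schedule step used (0 if the input already satisfied the target).
#' @export
anneal_edges <- function(graph, schedule, n_groups) {
  stopifnot(inherits(graph, "spatial_graph"))
  n <- nrow(graph$coords)
  check <- function(edges) {
    memb <- .component_membership(n, edges)
    sizes <- tabulate(memb)
    list(ok = max(memb) == n_groups && min(sizes[sizes > 0L]) >= 2L,
         overshoot = max(memb) > n_groups, memb = memb)
  }
  st <- check(graph$edges)
  if (st$ok) {
    graph$component <- st$memb
    attr(graph, "stop_step") <- 0L
    return(graph)
  }
  for (s in seq_along(schedule)) {
    keep <- graph$edges$length < 1 / schedule[s]
    edges <- graph$edges[keep, , drop = FALSE]
    st <- check(edges)
    if (st$ok) {
      graph$edges <- edges
      graph$component <- st$memb
      attr(graph, "stop_step") <- s
      return(graph)
    }
    if (st$overshoot) break
  }
  stop("annealing failed: schedule never produced ", n_groups,
       " non-singleton components")
}

#' Direct a group subgraph by topological order
#'
#' The designated root (the group node closest to the group centroid) gets
#' topological order 1; every other node gets 1 plus its unweighted graph
#' distance from the root. Each edge is directed from its lower-order
#' endpoint to its higher-order endpoint, ties broken from lower to higher
#' node id, so the root is the unique node with no incoming connection.
#'
#' @param graph an annealed [build_spatial_graph()] result.
#' @param members integer ids of the group's nodes.
#' @return A list with `order` (named integer vector of topological orders)
#'   and `edges` (directed `from`/`to` data frame in original node ids).
#' @export
direct_and_order <- function(graph, members) {
  stopifnot(inherits(graph, "spatial_graph"))
  sub <- graph$edges[graph$edges$i %in% members & graph$edges$j %in% members, ,
                     drop = FALSE]
  g <- igraph::make_empty_graph(n = length(members), directed = FALSE)
  if (nrow(sub) > 0L) {
    g <- igraph::add_edges(g, rbind(match(sub$i, members),
                                    match(sub$j, members)))
  }
  comp <- igraph::components(g)
  if (comp$no != 1L) stop("group subgraph is disconnected")
  centroid <- colMeans(graph$coords[members, , drop = FALSE])
  d2 <- rowSums((graph$coords[members, , drop = FALSE] -
                 matrix(centroid, length(members), 2, byrow = TRUE))^2)
  root_local <- which.min(d2)
  dist <- as.integer(igraph::distances(g, v = root_local)[1L, ])
  ord <- dist + 1L
  names(ord) <- as.character(members)
  from_local <- match(sub$i, members); to_local <- match(sub$j, members)
  swap <- ord[to_local] < ord[from_local] |
    (ord[to_local] == ord[from_local] & sub$j < sub$i)
  list(order = ord,
       edges = data.frame(from = ifelse(swap, sub$j, sub$i),
                          to   = ifelse(swap, sub$i, sub$j)))
}

#' Generate an independent-clusters dataset
#'
#' Runs the full pipeline: spatial embedding, temperature schedule, edge
#' annealing, per-group topological ordering, then sampling. Each sample
#' selects a group uniformly at random; its features are -1 everywhere except
#' at the selected group's nodes, which carry their topological order. All
#' samples of a class are identical, so exactly `n_groups` distinct row
#' patterns exist and the classes are linearly separable by construction.
#' Annealing occasionally fails for an unlucky embedding; the generator then
#' retries with fresh geometry (up to 25 attempts).
#'
#' @param config a [clusters_config()].
#' @return A [motif_dataset()] with attributes `node_groups` (feature group
#'   ids), `spatial_graph` (the annealed graph) and `orders` (list of
#'   per-group topological orders).
#' @export
generate_clusters_dataset <- function(config = clusters_config()) {
  stopifnot(inherits(config, "clusters_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  annealed <- NULL
  for (attempt in seq_len(25L)) {
    graph <- build_spatial_graph(config)
    sched <- temperature_schedule(graph, config$max_schedule_steps)
    res <- try(anneal_edges(graph, sched, config$n_groups), silent = TRUE)
    if (inherits(res, "try-error")) next
    # components must coincide with the generative groups for the ordering
    agree <- all(vapply(split(res$component, res$group),
                        function(m) length(unique(m)) == 1L, logical(1))) &&
      length(unique(res$component)) == config$n_groups
    if (agree) { annealed <- res; break }
  }
  if (is.null(annealed)) {
    stop("annealing failed repeatedly; try a smaller `spread` or more steps")
  }
  groups <- sort(unique(annealed$group))
  patterns <- matrix(-1, nrow = config$n_groups, ncol = config$n_nodes)
  orders <- vector("list", config$n_groups)
  for (gix in seq_along(groups)) {
    members <- which(annealed$group == groups[gix])
    topo <- direct_and_order(annealed, members)
    orders[[gix]] <- topo
    patterns[gix, members] <- topo$order
  }
  labels <- sample.int(config$n_groups, config$n_samples, replace = TRUE) - 1L
  x <- patterns[labels + 1L, , drop = FALSE]
  ds <- motif_dataset(x, labels,
                      class_names = as.character(seq_len(config$n_groups) - 1L))
  attr(ds, "node_groups") <- annealed$group
  attr(ds, "spatial_graph") <- annealed
  attr(ds, "orders") <- orders
  ds
}
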