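#' Directed graph of retained connections
#'
#' Minimal container used by the motif miner: node ids are the integers
#' `0 .. n_nodes-1`, edges are directed and simple (no self-loops, no
#' duplicates). A layered graph additionally carries a per-node `layer`
#' index (1-based); its edges may only join consecutive layers, which is the
#' topology of a pruned multi-layer perceptron.
#'
#' @param edges data frame with integer columns `from` and `to` (0-based node
#'   ids) and optional `weight` (numeric) and `category` (one of `"mild"`,
#'   `"strong_positive"`, `"strong_negative"`).
#' @param n_nodes number of nodes; defaults to `max(id) + 1`.
#' @param layer optional integer vector of per-node layer indices.
#' @return An object of class `motif_digraph`.
#' @export
motif_digraph <- function(edges, n_nodes = NULL, layer = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges$from, edges$to))) {
      stop("duplicate edges are not allowed")
    }
    if (min(edges$from, edges$to) < 0L) stop("node ids must be >= 0")
  } else {
    edges <- data.frame(from = integer(), to = integer())
  }
  if (is.null(n_nodes)) {
    n_nodes <- if (nrow(edges) > 0L) max(edges$from, edges$to) + 1L else 0L
  }
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) > 0L && max(edges$from, edges$to) >= n_nodes) {
    stop("edge endpoint exceeds `n_nodes`")
  }
  if (!is.null(layer)) {
    layer <- as.integer(layer)
    if (length(layer) != n_nodes) stop("`layer` must have one entry per node")
    if (nrow(edges) > 0L &&
        any(layer[edges$to + 1L] != layer[edges$from + 1L] + 1L)) {
      stop("layered edges must join consecutive layers")
    }
  }
  structure(list(n_nodes = n_nodes, edges = edges, layer = layer),
            class = "motif_digraph")
}

#' @export
print.motif_digraph <- function(x, ...) {
  cat(sprintf("<motif_digraph> %d nodes, %d edges%s\n", x$n_nodes,
              nrow(x$edges),
              if (is.null(x$layer)) ""
              else sprintf(", %d layers", max(x$layer))))
  invisible(x)
}

#' Number of edges of a motif digraph
#' @param graph a [motif_digraph()].
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

.category_color <- c(mild = 0L, strong_positive = 1L, strong_negative = 2L)

#' Write an edge list (FANMOD dialect)
#'
#' One edge per line, whitespace-separated integer source and target, plus an
#' optional third integer column carrying the edge category as a color
#' (0 mild, 1 strong positive, 2 strong negative).
#'
#' @param graph a [motif_digraph()].
#' @param path file path.
#' @param colors write the category column (default: yes when categories are
#'   present).
#' @export
write_edge_list <- function(graph, path,
                            colors = !is.null(graph$edges$category)) {
  stopifnot(inherits(graph, "motif_digraph"))
  e <- graph$edges
  lines <- if (colors && !is.null(e$category)) {
    paste(e$from, e$to, .category_color[as.character(e$category)])
  } else {
    paste(e$from, e$to)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge list (FANMOD dialect)
#'
#' Accepts whitespace-separated integer `source target` lines with an
#' optional third color column, as written by [write_edge_list()].
#'
#' @param path file path.
#' @param layer optional per-node layer vector to reattach.
#' @return A [motif_digraph()].
#' @export
read_edge_list <- function(path, layer = NULL) {
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 2L) stop("edge list needs at least two integer columns")
  edges <- data.frame(from = as.integer(tab[[1L]]), to = as.integer(tab[[2L]]))
  if (ncol(tab) >= 3L) {
    rev_map <- names(.category_color)[match(as.integer(tab[[3L]]),
                                            .category_color)]
    if (anyNA(rev_map)) stop("unknown edge color; expected 0, 1 or 2")
    edges$category <- rev_map
  }
  motif_digraph(edges, layer = layer)
}

#' Convert to an igraph object
#'
#' Nodes keep their 0-based ids as the `name` attribute; `layer`, `weight`
#' and `category` travel as attributes when present.
#'
#' @param graph a [motif_digraph()].
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "motif_digraph"))
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = TRUE)
  igraph::V(g)$name <- as.character(seq_len(graph$n_nodes) - 1L)
  if (!is.null(graph$layer)) igraph::V(g)$layer <- graph$layer
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(graph$edges$from + 1L,
                                    graph$edges$to + 1L))
    if (!is.null(graph$edges$weight)) {
      igraph::E(g)$weight <- graph$edges$weight
    }
    if (!is.null(graph$edges$category)) {
      igraph::E(g)$category <- as.character(graph$edges$category)
    }
  }
  g
}

#' Export a graph as GraphML
#'
#' @param graph a [motif_digraph()].
#' @param path file path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
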