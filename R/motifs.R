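# ---- permutation machinery for exhaustive canonical labeling -------------

.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    cbind(rep.int(i, nrow(sub)), m)
  }))
}

# per k: all k! permutations and, for each, the linear indices that read the
# permuted adjacency matrix in row-major order
.perm_info <- function(k) {
  key <- as.character(k)
  info <- .perm_cache[[key]]
  if (!is.null(info)) return(info)
  perms <- .permutations(k)
  np <- nrow(perms)
  idx <- matrix(0L, np, k * k)
  q <- 0L
  for (r in seq_len(k)) {
    for (cc in seq_len(k)) {
      q <- q + 1L
      idx[, q] <- (perms[, cc] - 1L) * k + perms[, r]
    }
  }
  info <- list(perms = perms, idx = idx)
  .perm_cache[[key]] <- info
  info
}

.pack_codes <- function(M, info, base) {
  k <- nrow(M)
  pow <- base^((k * k - 1L):0L)
  vals <- matrix(as.numeric(M)[as.vector(info$idx)], nrow = nrow(info$idx))
  as.numeric(vals %*% pow)
}

#' Canonical code of a small directed (optionally edge-colored) graph
#'
#' The code is the minimum, over all node permutations, of the row-major
#' reading of the permuted adjacency matrix interpreted as a base-2 number
#' (base-4 when edge colors are present, each cell holding 0 = no edge or the
#' color 1-3). Two subgraphs receive the same code exactly when they are
#' isomorphic (color-respecting when colors are given). With at most 5 nodes
#' there are at most 120 permutations, so the minimization is exhaustive and
#' exact.
#'
#' @param adjacency square 0/1 integer matrix (no self-loops).
#' @param colors optional square integer matrix of edge colors in 1..3 on the
#'   edges (ignored elsewhere).
#' @return Numeric scalar code.
#' @export
canonical_code <- function(adjacency, colors = NULL) {
  adjacency <- as.matrix(adjacency)
  k <- nrow(adjacency)
  if (k != ncol(adjacency)) stop("adjacency must be square")
  if (k > 7L) stop("exhaustive canonical labeling is limited to small graphs")
  M <- if (is.null(colors)) (adjacency != 0) + 0L
       else (adjacency != 0) * as.matrix(colors)
  base <- if (is.null(colors)) 2 else 4
  min(.pack_codes(M, .perm_info(k), base))
}

# canonical code + canonical row-major pattern string (+ skeleton code when
# colored); cached by the identity-order packing of the cell matrix
.canon_cache <- new.env(parent = emptyenv())

.canonical_full <- function(M, base) {
  k <- nrow(M)
  info <- .perm_info(k)
  codes <- .pack_codes(M, info, base)
  best <- which.min(codes)
  p <- info$perms[best, ]
  Mp <- M[p, p, drop = FALSE]
  pattern <- paste(as.vector(t(Mp)), collapse = "")
  skel <- if (base == 4) min(.pack_codes((M != 0) + 0L, info, 2)) else codes[best]
  list(code = codes[best], pattern = pattern, skeleton = skel)
}

.canonical_cached <- function(M, base) {
  k <- nrow(M)
  pow <- base^((k * k - 1L):0L)
  key <- paste0(base, "_", k, "_",
                sprintf("%.0f", sum(as.numeric(t(M)) * pow)))
  hit <- .canon_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- .canonical_full(M, base)
  .canon_cache[[key]] <- res
  res
}

# ---- ESU enumeration ------------------------------------------------------

.undirected_neighbors <- function(n, edges) {
  if (nrow(edges) == 0L) return(rep(list(integer()), n))
  a <- c(edges$from, edges$to) + 1L
  b <- c(edges$to, edges$from) + 1L
  nb <- split(b, factor(a, levels = seq_len(n)))
  lapply(nb, function(x) sort.int(unique(x)))
}

.category_code <- c(mild = 1L, strong_positive = 2L, strong_negative = 3L)

#' Census of connected induced k-node subgraphs
#'
#' Enumerates every weakly connected induced `k`-node subgraph exactly once
#' using the ESU algorithm (ordered extension over exclusive neighborhoods)
#' and classifies each occurrence by its exhaustive [canonical_code()]. When
#' `colored = TRUE` the edge categories take part in the classification, so
#' two subgraphs with the same skeleton but different strong/mild edge
#' patterns count as different motif classes.
#'
#' @param graph a [motif_digraph()].
#' @param k subgraph size, 3 to 5.
#' @param colored classify up to color-respecting isomorphism (requires edge
#'   categories).
#' @return An object of class `motif_census`: a data frame with columns
#'   `code`, `skeleton_code`, `adjacency` (canonical row-major cell string)
#'   and `count`, sorted by code; attributes `k`, `colored`, `total` and
#'   `n_nodes`.
#' @export
count_subgraphs <- function(graph, k, colored = FALSE) {
  stopifnot(inherits(graph, "motif_digraph"))
  k <- as.integer(k)
  if (k < 3L || k > 5L) stop("`k` must be 3, 4 or 5")
  if (colored && is.null(graph$edges$category)) {
    stop("`colored = TRUE` requires edge categories")
  }
  n <- graph$n_nodes
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  total <- 0L
  if (n >= k && nrow(graph$edges) > 0L) {
    base <- if (colored) 4 else 2
    M <- matrix(0L, n, n)
    ij <- cbind(graph$edges$from + 1L, graph$edges$to + 1L)
    M[ij] <- if (colored) .category_code[as.character(graph$edges$category)]
             else 1L
    nb <- .undirected_neighbors(n, graph$edges)
    visit <- function(sub) {
      m <- M[sub, sub, drop = FALSE]
      res <- .canonical_cached(m, base)
      ckey <- sprintf("%.0f", res$code)
      prev <- counts[[ckey]]
      if (is.null(prev)) {
        counts[[ckey]] <- 1L
        meta[[ckey]] <- res
      } else {
        counts[[ckey]] <- prev + 1L
      }
      total <<- total + 1L
    }
    extend <- function(sub, ext, v) {
      if (length(sub) == k) {
        visit(sub)
        return(invisible(NULL))
      }
      closed <- c(sub, unlist(nb[sub], use.names = FALSE))
      while (length(ext) > 0L) {
        w <- ext[1L]
        ext <- ext[-1L]
        cand <- nb[[w]]
        cand <- cand[cand > v & !(cand %in% closed)]
        extend(c(sub, w), c(ext, cand), v)
      }
      invisible(NULL)
    }
    for (v in seq_len(n)) {
      ext0 <- nb[[v]]
      ext0 <- ext0[ext0 > v]
      if (length(ext0) > 0L || k == 1L) extend(v, ext0, v)
    }
  }
  keys <- ls(counts)
  df <- if (length(keys) == 0L) {
    data.frame(code = numeric(), skeleton_code = numeric(),
               adjacency = character(), count = integer())
  } else {
    data.frame(code = vapply(keys, function(kk) meta[[kk]]$code, numeric(1)),
               skeleton_code = vapply(keys, function(kk) meta[[kk]]$skeleton,
                                      numeric(1)),
               adjacency = vapply(keys, function(kk) meta[[kk]]$pattern,
                                  character(1)),
               count = vapply(keys, function(kk) counts[[kk]], integer(1)))
  }
  df <- df[order(df$code), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("motif_census", "data.frame"),
            k = k, colored = colored, total = total, n_nodes = n)
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("<motif_census> k=%d, %d classes, %d subgraphs%s\n",
              attr(x, "k"), nrow(x), attr(x, "total"),
              if (attr(x, "colored")) " (colored)" else ""))
  NextMethod()
}
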