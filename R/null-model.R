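#' Null-model configuration
#'
#' Randomized replicas are produced by degree-preserving double-edge swaps.
#' In `layer_preserving` mode a swap is also rejected when it would create an
#' edge that does not join consecutive layers, so replicas of a pruned MLP
#' graph remain valid MLP topologies; `global` mode only forbids self-loops
#' and duplicates (the classical switching null model).
#'
#' @param n_replicas ensemble size (>= 2 for a defined standard deviation;
#'   default 1000).
#' @param swaps_per_edge attempted swaps per edge (default 3).
#' @param mode `"layer_preserving"` or `"global"`.
#' @param seed optional integer seed for the ensemble.
#' @return An object of class `null_model_config`.
#' @export
null_model_config <- function(n_replicas = 1000L, swaps_per_edge = 3L,
                              mode = c("layer_preserving", "global"),
                              seed = NULL) {
  mode <- match.arg(mode)
  if (n_replicas < 2L) stop("`n_replicas` must be >= 2")
  if (swaps_per_edge < 0L) stop("`swaps_per_edge` must be >= 0")
  structure(list(n_replicas = as.integer(n_replicas),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 mode = mode, seed = seed),
            class = "null_model_config")
}

#' Degree-preserving switch randomization
#'
#' Performs `swaps_per_edge * n_edges` attempted double-edge swaps
#' `(a->b, c->d) => (a->d, c->b)`. A swap is rejected when it would create a
#' self-loop or a duplicate edge, or (in layer-preserving mode on a layered
#' graph) an edge not joining consecutive layers. Every node keeps its in-
#' and out-degree exactly. Edge weights and categories travel with the
#' source half of the swap.
#'
#' @param graph a [motif_digraph()].
#' @param config a [null_model_config()] (its `n_replicas` is ignored here).
#' @return A randomized [motif_digraph()] with the same degree sequences.
#' @export
switch_randomize <- function(graph, config = null_model_config()) {
  stopifnot(inherits(graph, "motif_digraph"),
            inherits(config, "null_model_config"))
  edges <- graph$edges
  nE <- nrow(edges)
  if (nE < 2L) return(graph)
  from <- edges$from
  to <- edges$to
  n <- graph$n_nodes
  keys <- from * n + to
  layered <- identical(config$mode, "layer_preserving") &&
    !is.null(graph$layer)
  lay <- graph$layer
  attempts <- config$swaps_per_edge * nE
  if (attempts > 0L) {
    pick_i <- sample.int(nE, attempts, replace = TRUE)
    pick_j <- sample.int(nE, attempts, replace = TRUE)
    for (t in seq_len(attempts)) {
      i <- pick_i[t]; j <- pick_j[t]
      if (i == j) next
      a <- from[i]; b <- to[i]; cc <- from[j]; d <- to[j]
      if (a == d || cc == b) next # self-loop
      if (layered && (lay[d + 1L] != lay[a + 1L] + 1L ||
                      lay[b + 1L] != lay[cc + 1L] + 1L)) next
      k1 <- a * n + d; k2 <- cc * n + b
      if (any(keys == k1) || any(keys == k2)) next # duplicate (or no-op)
      to[i] <- d; to[j] <- b
      keys[i] <- k1; keys[j] <- k2
    }
  }
  edges$to <- to
  out <- graph
  out$edges <- edges
  out
}

#' Null-ensemble motif statistics
#'
#' Enumerates the census of each of `n_replicas` independent randomizations
#' of `graph` and returns, per motif class seen in any replica, the ensemble
#' mean and sample standard deviation of its count (a class absent from a
#' replica counts 0 there).
#'
#' @param graph a [motif_digraph()].
#' @param k subgraph size.
#' @param config a [null_model_config()].
#' @param colored classify up to color-respecting isomorphism.
#' @return Data frame with columns `code`, `skeleton_code`, `adjacency`,
#'   `mean_random`, `sd_random`; attributes `k`, `colored`, `n_replicas`.
#' @export
null_census_ensemble <- function(graph, k, config = null_model_config(),
                                 colored = FALSE) {
  stopifnot(inherits(config, "null_model_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  R <- config$n_replicas
  sum1 <- new.env(parent = emptyenv())
  sum2 <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (r in seq_len(R)) {
    rep_graph <- switch_randomize(graph, config)
    cen <- count_subgraphs(rep_graph, k, colored = colored)
    for (row in seq_len(nrow(cen))) {
      ckey <- sprintf("%.0f", cen$code[row])
      cnt <- as.numeric(cen$count[row])
      if (is.null(sum1[[ckey]])) {
        sum1[[ckey]] <- cnt
        sum2[[ckey]] <- cnt^2
        meta[[ckey]] <- cen[row, c("code", "skeleton_code", "adjacency")]
      } else {
        sum1[[ckey]] <- sum1[[ckey]] + cnt
        sum2[[ckey]] <- sum2[[ckey]] + cnt^2
      }
    }
  }
  keys <- ls(sum1)
  df <- if (length(keys) == 0L) {
    data.frame(code = numeric(), skeleton_code = numeric(),
               adjacency = character(), mean_random = numeric(),
               sd_random = numeric())
  } else {
    m <- vapply(keys, function(kk) sum1[[kk]] / R, numeric(1))
    ss <- vapply(keys, function(kk) sum2[[kk]], numeric(1))
    # sample sd over the R replica counts, zeros included
    var_ <- pmax((ss - R * m^2) / (R - 1), 0)
    info <- do.call(rbind, lapply(keys, function(kk) meta[[kk]]))
    data.frame(code = info$code, skeleton_code = info$skeleton_code,
               adjacency = info$adjacency, mean_random = m,
               sd_random = sqrt(var_))
  }
  df <- df[order(df$code), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, k = as.integer(k), colored = colored, n_replicas = R)
}

#' Z-score significance profile
#'
#' Combines a real-graph census with a null ensemble into the per-class
#' Z-score `(N_real - <N_random>) / sd_random`. Classes whose ensemble
#' standard deviation is zero have an undefined score (`NA`); classes seen
#' only in replicas are retained with `n_real = 0`, classes seen only in the
#' real graph with ensemble mean and sd 0 (hence undefined score). Profiles
#' are not normalized.
#'
#' @param census a `motif_census` from [count_subgraphs()] of the real graph.
#' @param ensemble the matching [null_census_ensemble()].
#' @return An object of class `significance_profile`: a data frame with
#'   columns `code`, `skeleton_code`, `adjacency`, `n_real`, `mean_random`,
#'   `sd_random`, `z`.
#' @export
z_scores <- function(census, ensemble) {
  stopifnot(inherits(census, "motif_census"))
  if (!identical(attr(census, "k"), attr(ensemble, "k"))) {
    stop("census and ensemble were computed at different k")
  }
  real <- data.frame(code = census$code, skeleton_code = census$skeleton_code,
                     adjacency = census$adjacency, n_real = census$count)
  null <- as.data.frame(ensemble)
  merged <- merge(real, null, by = "code", all = TRUE, sort = TRUE)
  merged$n_real[is.na(merged$n_real)] <- 0L
  merged$mean_random[is.na(merged$mean_random)] <- 0
  merged$sd_random[is.na(merged$sd_random)] <- 0
  merged$skeleton_code <- ifelse(is.na(merged$skeleton_code.x),
                                 merged$skeleton_code.y,
                                 merged$skeleton_code.x)
  merged$adjacency <- ifelse(is.na(merged$adjacency.x), merged$adjacency.y,
                             merged$adjacency.x)
  merged$z <- ifelse(merged$sd_random > 0,
                     (merged$n_real - merged$mean_random) / merged$sd_random,
                     NA_real_)
  out <- merged[c("code", "skeleton_code", "adjacency", "n_real",
                  "mean_random", "sd_random", "z")]
  structure(out, class = c("significance_profile", "data.frame"),
            k = attr(census, "k"), colored = attr(census, "colored"),
            n_replicas = attr(ensemble, "n_replicas"))
}

#' @export
print.significance_profile <- function(x, ...) {
  cat(sprintf("<significance_profile> k=%d, %d classes (%d with defined Z)\n",
              attr(x, "k"), nrow(x), sum(!is.na(x$z))))
  NextMethod()
}

#' One-call motif significance analysis
#'
#' Census of the real graph, null ensemble, and Z-scores in one step.
#'
#' @param graph a [motif_digraph()].
#' @param k subgraph size (3-5).
#' @param config a [null_model_config()].
#' @param colored classify up to color-respecting isomorphism.
#' @return A [z_scores()] significance profile.
#' @export
motif_significance <- function(graph, k, config = null_model_config(),
                               colored = FALSE) {
  census <- count_subgraphs(graph, k, colored = colored)
  ens <- null_census_ensemble(graph, k, config, colored = colored)
  z_scores(census, ens)
}

#' Z-score change between two significance profiles
#'
#' Per motif class, the difference `z_after - z_before`; classes undefined on
#' either side are reported with an `NA` delta.
#'
#' @param before,after [z_scores()] profiles computed at the same `k` with
#'   the same null configuration.
#' @return Data frame with columns `code`, `adjacency`, `z_before`,
#'   `z_after`, `delta`.
#' @export
profile_delta <- function(before, after) {
  stopifnot(inherits(before, "significance_profile"),
            inherits(after, "significance_profile"))
  if (!identical(attr(before, "k"), attr(after, "k"))) {
    stop("profiles were computed at different k")
  }
  b <- data.frame(code = before$code, adjacency = before$adjacency,
                  z_before = before$z)
  a <- data.frame(code = after$code, adjacency = after$adjacency,
                  z_after = after$z)
  merged <- merge(b, a, by = "code", all = TRUE, sort = TRUE)
  merged$adjacency <- ifelse(is.na(merged$adjacency.x), merged$adjacency.y,
                             merged$adjacency.x)
  merged$delta <- merged$z_after - merged$z_before
  merged[c("code", "adjacency", "z_before", "z_after", "delta")]
}

#' Rank motif classes by significance
#'
#' In a colored analysis, classes sharing an uncolored skeleton form an
#' isomorphic group; `most_significant` keeps the group member of maximum
#' absolute Z, `most_typical` the member whose Z is closest to the group
#' mean. Selected classes are ranked by decreasing absolute Z (ties broken
#' by ascending code). Classes with undefined Z are dropped.
#'
#' @param profile a [z_scores()] significance profile.
#' @param n number of classes to return (default all).
#' @param mode `"most_significant"` or `"most_typical"`.
#' @return The selected rows of the profile, ranked.
#' @export
top_motifs <- function(profile, n = Inf,
                       mode = c("most_significant", "most_typical")) {
  stopifnot(inherits(profile, "significance_profile"))
  mode <- match.arg(mode)
  df <- profile[!is.na(profile$z), , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  pick <- unlist(lapply(split(seq_len(nrow(df)), df$skeleton_code),
                        function(rows) {
    zz <- df$z[rows]
    if (mode == "most_significant") {
      rows[which.max(abs(zz))]
    } else {
      rows[which.min(abs(zz - mean(zz)))]
    }
  }), use.names = FALSE)
  sel <- df[pick, , drop = FALSE]
  sel <- sel[order(-abs(sel$z), sel$code), , drop = FALSE]
  utils::head(sel, n)
}
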