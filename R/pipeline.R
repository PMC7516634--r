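#' Experiment configuration
#'
#' Bundles every stage of the motif-emergence experiment: the two synthetic
#' environments, the architecture, training, pruning, the null model and the
#' motif sizes. The global `seed` determines all stochastic stages (data
#' generation, initialization, batching, null replicas), so a rerun with the
#' same configuration is reproducible.
#'
#' @param tree a [tree_config()].
#' @param clusters a [clusters_config()].
#' @param arch architecture preset name or [mlp_architecture()].
#' @param train a [train_config()] (its `init_scheme` and `seed` are
#'   overridden per cell).
#' @param prune a [prune_config()]; the same pruning is applied to the
#'   initial and the trained snapshot so significance deltas are comparable.
#' @param null a [null_model_config()].
#' @param motif_sizes subgraph sizes to mine (subset of 3:5).
#' @param init_schemes initialization schemes forming the grid.
#' @param colored classify motifs with edge categories.
#' @param seed global integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(tree = tree_config(),
                              clusters = clusters_config(),
                              arch = "240120",
                              train = train_config(),
                              prune = prune_config(),
                              null = null_model_config(),
                              motif_sizes = c(4L, 5L),
                              init_schemes = c("normal", "orthogonal",
                                               "glorot"),
                              colored = FALSE,
                              seed = 240120L) {
  if (!inherits(arch, "mlp_architecture")) arch <- mlp_architecture(arch)
  motif_sizes <- as.integer(motif_sizes)
  if (!all(motif_sizes %in% 3:5)) stop("`motif_sizes` must lie in 3..5")
  init_schemes <- match.arg(init_schemes,
                            c("normal", "orthogonal", "glorot"),
                            several.ok = TRUE)
  structure(list(tree = tree, clusters = clusters, arch = arch,
                 train = train, prune = prune, null = null,
                 motif_sizes = motif_sizes, init_schemes = init_schemes,
                 colored = isTRUE(colored), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Recognized blocks: `data` (keys `depth`, `epsilon`, `distinction_level`,
#' `n_nodes`, `n_groups`, `spread`, `n_samples`, `seed`), `train`
#' (`learning_rate`, `decay`, `momentum`, `batch_size`, `max_epochs`),
#' `prune` (`cutoff`, `strong_multiplier`), `null_model` (`n_replicas`,
#' `swaps_per_edge`, `mode`; the block is named `null_model` because a bare
#' `null` key is a YAML null), and top-level `arch`, `motif_sizes`,
#' `init_schemes`, `colored`, `seed`. Missing keys keep package defaults.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, keys) {
    b <- y[[block]]
    if (is.null(b)) list() else b[intersect(names(b), keys)]
  }
  d <- take("data", c("depth", "epsilon", "distinction_level", "n_samples",
                      "seed"))
  cl <- take("data", c("n_nodes", "n_groups", "spread", "n_samples", "seed"))
  args <- list(
    tree = do.call(tree_config, d),
    clusters = do.call(clusters_config, cl),
    train = do.call(train_config,
                    take("train", c("learning_rate", "decay", "momentum",
                                    "batch_size", "max_epochs"))),
    prune = do.call(prune_config, take("prune", c("cutoff",
                                                  "strong_multiplier"))),
    null = do.call(null_model_config,
                   take("null_model", c("n_replicas", "swaps_per_edge",
                                        "mode"))))
  for (k in c("arch", "motif_sizes", "init_schemes", "colored", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(experiment_config, args)
}

#' Absolute-weight summary of retained weights
#'
#' Mean and standard deviation of the absolute values of the retained
#' (non-negligible) weights before and after learning, the statistic used to
#' show that learning pushes surviving weights further into the tails.
#'
#' @param before,after numeric vectors of retained weights.
#' @return Data frame with rows `before` and `after` and columns `phase`,
#'   `n`, `mean_abs`, `sd_abs`.
#' @export
weight_statistics <- function(before, after) {
  if (length(before) == 0L || length(after) == 0L) {
    stop("retained weight sets must be non-empty")
  }
  data.frame(phase = c("before", "after"),
             n = c(length(before), length(after)),
             mean_abs = c(mean(abs(before)), mean(abs(after))),
             sd_abs = c(stats::sd(abs(before)), stats::sd(abs(after))))
}

.derived_seed <- function(base, offset) {
  as.integer((as.numeric(base) * 97 + offset) %% 2147483629)
}

.run_cell <- function(dataset, dataset_name, scheme, config, cell_seed) {
  tc <- config$train
  tc$init_scheme <- scheme
  tc$seed <- cell_seed
  fit <- mlp_train(config$arch, dataset, tc)
  g_before <- model_to_graph(fit$initial, config$prune)
  g_after <- model_to_graph(fit$final, config$prune)
  profiles <- list()
  deltas <- list()
  for (k in config$motif_sizes) {
    nc <- config$null
    nc$seed <- .derived_seed(cell_seed, k)
    p_before <- motif_significance(g_before, k, nc, colored = config$colored)
    nc$seed <- .derived_seed(cell_seed, k + 100L)
    p_after <- motif_significance(g_after, k, nc, colored = config$colored)
    kk <- as.character(k)
    profiles[[kk]] <- list(before = p_before, after = p_after)
    deltas[[kk]] <- profile_delta(p_before, p_after)
  }
  stats <- weight_statistics(g_before$edges$weight, g_after$edges$weight)
  list(dataset = dataset_name, init = scheme, failed = FALSE,
       epochs_to_perfect = fit$epochs_to_perfect,
       max_accuracy = max(fit$history$accuracy),
       history = fit$history, train = fit,
       graph_before = g_before, graph_after = g_after,
       weight_stats = stats, profiles = profiles, deltas = deltas)
}

#' Run the full motif-emergence experiment grid
#'
#' Executes, for each (dataset, initialization) cell: data generation,
#' parameter initialization (snapshot), training, pruning and graph
#' extraction of the initial and trained models, motif mining at each
#' requested size, significance profiles against the null ensemble, and
#' before/after profile deltas. A failing stage marks its cell as failed
#' (with the error message) and the grid continues. Everything is
#' deterministic given `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, CSV tables, FANMOD edge
#'   lists, GraphML graphs and a JSON summary are written there.
#' @return An object of class `experiment_report`: a list with `cells` (one
#'   entry per grid cell) and `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  tree_cfg <- config$tree
  tree_cfg$seed <- .derived_seed(config$seed, 1L)
  clusters_cfg <- config$clusters
  clusters_cfg$seed <- .derived_seed(config$seed, 2L)
  datasets <- list(tree = generate_tree_dataset(tree_cfg),
                   clusters = generate_clusters_dataset(clusters_cfg))
  cells <- list()
  cell_ix <- 0L
  for (ds_name in names(datasets)) {
    for (scheme in config$init_schemes) {
      cell_ix <- cell_ix + 1L
      cell_seed <- .derived_seed(config$seed, 10L + cell_ix)
      key <- paste(ds_name, scheme, sep = "_")
      cells[[key]] <- tryCatch(
        .run_cell(datasets[[ds_name]], ds_name, scheme, config, cell_seed),
        error = function(e) list(dataset = ds_name, init = scheme,
                                 failed = TRUE,
                                 error = conditionMessage(e)))
    }
  }
  report <- structure(list(cells = cells, config = config,
                           datasets = datasets),
                      class = "experiment_report")
  if (!is.null(out_dir)) write_experiment_report(report, out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d cells (arch %s)\n", length(x$cells),
              x$config$arch$name))
  for (key in names(x$cells)) {
    cell <- x$cells[[key]]
    if (isTRUE(cell$failed)) {
      cat(sprintf("  %-20s FAILED: %s\n", key, cell$error))
    } else {
      cat(sprintf(
        "  %-20s acc %.3f, perfect@%s, |w| %.3f -> %.3f (%d -> %d edges)\n",
        key, cell$max_accuracy,
        ifelse(is.na(cell$epochs_to_perfect), "never",
               cell$epochs_to_perfect),
        cell$weight_stats$mean_abs[1L], cell$weight_stats$mean_abs[2L],
        n_edges(cell$graph_before), n_edges(cell$graph_after)))
    }
  }
  invisible(x)
}

#' Write the artifacts of an experiment report
#'
#' Per cell: before/after FANMOD edge lists and GraphML graphs, per-size
#' significance-profile and delta CSVs, and the accuracy trace CSV. At the
#' top level: a weight-statistics table mirroring the (initialization x
#' dataset) layout, a convergence table, and a JSON summary.
#'
#' @param report an [run_experiment()] report.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_experiment_report <- function(report, out_dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wstats <- list()
  conv <- list()
  for (key in names(report$cells)) {
    cell <- report$cells[[key]]
    if (isTRUE(cell$failed)) next
    cdir <- file.path(out_dir, key)
    dir.create(cdir, showWarnings = FALSE)
    write_edge_list(cell$graph_before, file.path(cdir, "graph_before.txt"))
    write_edge_list(cell$graph_after, file.path(cdir, "graph_after.txt"))
    write_graphml(cell$graph_before, file.path(cdir, "graph_before.graphml"))
    write_graphml(cell$graph_after, file.path(cdir, "graph_after.graphml"))
    utils::write.csv(cell$history, file.path(cdir, "history.csv"),
                     row.names = FALSE)
    for (kk in names(cell$profiles)) {
      pb <- cell$profiles[[kk]]
      utils::write.csv(as.data.frame(pb$before),
                       file.path(cdir, sprintf("profile_k%s_before.csv", kk)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(pb$after),
                       file.path(cdir, sprintf("profile_k%s_after.csv", kk)),
                       row.names = FALSE)
      utils::write.csv(cell$deltas[[kk]],
                       file.path(cdir, sprintf("delta_k%s.csv", kk)),
                       row.names = FALSE)
    }
    ws <- cell$weight_stats
    ws$dataset <- cell$dataset
    ws$init <- cell$init
    wstats[[key]] <- ws
    conv[[key]] <- data.frame(dataset = cell$dataset, init = cell$init,
                              epochs_to_perfect = cell$epochs_to_perfect,
                              max_accuracy = cell$max_accuracy)
  }
  if (length(wstats) > 0L) {
    utils::write.csv(do.call(rbind, wstats),
                     file.path(out_dir, "weight_statistics.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, conv),
                     file.path(out_dir, "convergence.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    arch = report$config$arch$name,
    seed = report$config$seed,
    cells = lapply(report$cells, function(cell) {
      if (isTRUE(cell$failed)) {
        list(dataset = cell$dataset, init = cell$init, failed = TRUE,
             error = cell$error)
      } else {
        list(dataset = cell$dataset, init = cell$init, failed = FALSE,
             epochs_to_perfect = cell$epochs_to_perfect,
             max_accuracy = cell$max_accuracy,
             edges_before = n_edges(cell$graph_before),
             edges_after = n_edges(cell$graph_after),
             mean_abs_before = cell$weight_stats$mean_abs[1L],
             mean_abs_after = cell$weight_stats$mean_abs[2L])
      }
    }))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare convergence speed across seeds
#'
#' Aggregates `epochs_to_perfect` over several experiment reports (one per
#' seed) and reports the median per (dataset, initialization) cell, plus
#' whether the Normal scheme is the slowest on each dataset. Cells that never
#' reached accuracy 1.0 are censored at the epoch budget. With fewer than 3
#' seeds the ordering is emitted with a low-confidence flag.
#'
#' @param reports list of [run_experiment()] reports.
#' @return A list with `table` (data frame of medians), `normal_slowest`
#'   (named logical per dataset, `NA` on ties) and `low_confidence`.
#' @export
compare_convergence <- function(reports) {
  stopifnot(length(reports) >= 1L)
  rows <- list()
  for (rep_ix in seq_along(reports)) {
    rep_ <- reports[[rep_ix]]
    budget <- rep_$config$train$max_epochs
    for (cell in rep_$cells) {
      if (isTRUE(cell$failed)) next
      e <- cell$epochs_to_perfect
      rows[[length(rows) + 1L]] <-
        data.frame(seed_run = rep_ix, dataset = cell$dataset,
                   init = cell$init, censored = is.na(e),
                   epochs = ifelse(is.na(e), budget, e))
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(epochs ~ dataset + init, data = long,
                          FUN = stats::median)
  names(agg)[names(agg) == "epochs"] <- "median_epochs"
  agg$n_seeds <- stats::aggregate(epochs ~ dataset + init, data = long,
                                  FUN = length)$epochs
  agg$n_censored <- stats::aggregate(censored ~ dataset + init, data = long,
                                     FUN = sum)$censored
  normal_slowest <- vapply(split(agg, agg$dataset), function(d) {
    mn <- d$median_epochs[d$init == "normal"]
    others <- d$median_epochs[d$init != "normal"]
    if (length(mn) == 0L || length(others) == 0L) return(NA)
    if (mn > max(others)) TRUE else if (mn < max(others)) FALSE else NA
  }, logical(1))
  list(table = agg, normal_slowest = normal_slowest,
       low_confidence = min(agg$n_seeds) < 3L)
}
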