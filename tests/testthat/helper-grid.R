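# The full (dataset x initialization) training grid at study scale is needed
# by several end-to-end checks; compute it once per test run and cache it.
.grid_cache <- new.env(parent = emptyenv())

study_grid <- function() {
  if (!is.null(.grid_cache$grid)) return(.grid_cache$grid)
  datasets <- list(
    tree = generate_tree_dataset(tree_config(n_samples = 4000L,
                                             seed = 240120L)),
    clusters = generate_clusters_dataset(clusters_config(n_samples = 4000L,
                                                         seed = 250120L)))
  grid <- list()
  cell_seed <- 0L
  for (ds_name in names(datasets)) {
    for (scheme in c("normal", "orthogonal", "glorot")) {
      cell_seed <- cell_seed + 1L
      fit <- mlp_train(mlp_architecture("240120"), datasets[[ds_name]],
                       train_config(init_scheme = scheme,
                                    seed = 1800L + cell_seed))
      grid[[paste(ds_name, scheme, sep = "_")]] <-
        list(dataset = ds_name, scheme = scheme, fit = fit,
             graph_before = model_to_graph(fit$initial),
             graph_after = model_to_graph(fit$final))
    }
  }
  .grid_cache$grid <- grid
  grid
}
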