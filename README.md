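# motifemerge

Network science describes complex systems through *network motifs*: small
patterns of interconnection (feed-forward chains, bifans, diamonds) that
occur significantly more often than in randomized networks, and that in
biological transduction networks act as functional building blocks. A
multi-layer perceptron begins as a stack of fully connected bipartite
graphs — maximally boring topology. `motifemerge` measures whether, and
how, *learning* sculpts motif structure into such a network: it trains
small ReLU/softmax perceptrons on two synthetic environments with
controlled covariance structure, discards near-zero weights, and scores
the motif content of the surviving directed graph before and after
training.

The package is aimed at researchers studying the structure of learned
neural networks with network-science tools, and implements the full
pipeline from scratch:

* **Synthetic environments** — a hierarchical binary-tree generator
  (31 features, 4 classes with analytic probabilities
  (0.35, 0.15, 0.35, 0.15) at flip probability ε = 0.3) and an
  independent-clusters generator (block-diagonal covariance via annealed
  edge deletion and per-group topological ordering).
* **MLP trainer** — mini-batch SGD with Nesterov momentum 0.6, learning
  rate 0.01, inverse-time decay 1e-6; Normal, Orthogonal and Glorot
  initializations; exact backpropagation (finite-difference verified).
* **Graph extraction** — a Gaussian density pruning rule: fit
  `N(mu, sigma^2)` to the pooled weights and exclude the band
  `|w - mu| <= sigma * sqrt(2 ln(1/c))`; retained edges are categorized
  strong-positive / strong-negative / mild.
* **Motif miner** — exact ESU enumeration of weakly connected induced
  k-node subgraphs (k = 3–5), exhaustive canonical labeling (optionally
  edge-colored), degree-preserving switch-randomized null ensembles
  (layer-preserving or global), and non-normalized significance scores

  `Z = (N_real − <N_random>) / sigma_random`.

* **Pipeline** — the 2 × 3 (environment × initialization) experiment grid
  with before/after significance profiles, profile deltas and plain-text
  artifacts, fully reproducible from one seed.

## Worked example

```r
library(motifemerge)

ds <- generate_tree_dataset(tree_config(n_samples = 4000, seed = 11))
ds
#> <motif_dataset> 4000 samples x 31 features, 4 classes
#> label counts: 0=1378, 1=608, 2=1436, 3=578

fit <- mlp_train(mlp_architecture("240120"), ds,
                 train_config(init_scheme = "normal", seed = 7))
fit
#> <mlp_train_result> 200 epochs, final accuracy 1.000, perfect at epoch 3

g_before <- model_to_graph(fit$initial)
g_after  <- model_to_graph(fit$final)
g_after
#> <motif_digraph> 65 nodes, 69 edges, 4 layers

weight_statistics(g_before$edges$weight, g_after$edges$weight)
#>    phase  n  mean_abs     sd_abs
#> 1 before 82 0.2039920 0.03177753
#> 2  after 69 0.5123529 0.17805540

prof <- motif_significance(g_after, k = 4,
                           null_model_config(n_replicas = 200, seed = 99))
top_motifs(prof, n = 3)
#>   code skeleton_code        adjacency n_real mean_random sd_random         z
#> 4   76            76 0000000001001100    226     242.150  8.130067 -1.986453
#> 3   74            74 0000000001001010    102     111.815  5.341670 -1.837440
#> 5  204           204 0000000011001100     79      74.330  2.556124  1.826985
```

Reading the output: the class frequencies match the analytic tree mix
(0.35/0.15 split per root sign); training reaches perfect accuracy at
epoch 3 and the mean absolute retained weight grows from 0.204 (the
calibrated reference value for Normal initialization) to 0.512 — learning
pushes the surviving weights into the tails. In the significance profile,
`adjacency` is the canonical 4 × 4 adjacency matrix row-major (code 204 is
the bifan: two sources each feeding both targets), `n_real` the count in the
trained graph, and `z` its distance from the 200-replica degree-preserving
null in standard deviations. Scores near |Z| ≈ 2 are typical for a single
short training run; classes whose counts are fixed by the degree sequences
(pure fans) have `sd_random = 0` and are excluded.

The full grid, with artifacts written to disk:

```r
report <- run_experiment(experiment_config(seed = 240120), out_dir = "out")
report
```

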