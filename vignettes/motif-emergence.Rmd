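---
title: "How network motifs emerge in small multi-layer perceptrons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How network motifs emerge in small multi-layer perceptrons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifemerge)
```

## The question

Biological signalling networks are famously built from *network motifs*:
small patterns of interconnection (bifans, diamonds, feed-forward chains)
that occur far more often than in degree-matched random networks. A
multi-layer perceptron (MLP) starts life as the opposite of that — a stack
of fully connected bipartite graphs with no interesting local structure at
all. `motifemerge` asks whether learning *creates* such structure: after
training, if we discard the near-zero weights and look at the surviving
directed graph of strong connections, which 3-, 4- and 5-node motifs are
over- or under-represented relative to a randomized null model, and how does
that *significance profile* differ from the one implied by the random
initialization?

The package implements the entire chain needed to answer this
reproducibly: two synthetic learning environments with controlled
covariance structure, a from-scratch MLP trainer, a density-based pruning
rule, exact subgraph enumeration with exhaustive canonical labeling, and
Z-score profiles against switch-randomized null ensembles.

## The two learning environments

Both environments produce 31 features and 4 classes, so the same network
can be trained on either and differences in the emergent topology can be
attributed to the statistics of the data.

### Hierarchical binary tree

A complete binary tree of depth $D$ ($N = 2^D - 1$ nodes, stored as a
linear array; depth 5 gives the 31 features) is filled with $\pm 1$ values
by diffusion. The root is a fair coin. A $+1$ root promotes its left child
deterministically; a $-1$ root promotes its right child. Below the root,
every $+1$ node passes $+1$ to its left child when a uniform draw exceeds
the flip probability $\varepsilon$ (default 0.3), otherwise to its right
child; everything inside a $-1$ subtree stays $-1$. A sample therefore
contains exactly one $+1$ node per level — a single "lit path" down the
tree — and features of nearby nodes are strongly correlated, giving a
nested, hierarchical covariance matrix.

Classes are defined by the identity of the lit path down to level
`distinction_level + 1`. At the default distinction level 2 this is the
root sign together with the flip outcome at the unique level-2 $+1$ node,
enumerated as (+1/no-flip, +1/flip, −1/no-flip, −1/flip). The class
probabilities are then analytic:
$\left(\tfrac{1-\varepsilon}{2}, \tfrac{\varepsilon}{2},
\tfrac{1-\varepsilon}{2}, \tfrac{\varepsilon}{2}\right)$, i.e.
(0.35, 0.15, 0.35, 0.15) at $\varepsilon = 0.3$. The test suite checks the
empirical frequencies against these values within three binomial standard
errors.

### Independent clusters

The second environment is engineered to have a block-diagonal covariance:
groups of features depend on each other and on nothing else. 31 nodes are
scattered (Gaussian, `spread` = 0.08) around 4 well-separated planar
centers — the corners of the unit square — and connected completely, each
edge weighted by its Euclidean length. Group sizes are the near-even split
(8, 8, 8, 7). A rising temperature schedule
$T_0 = (\max_e e)^{-1} \le \dots \le T_f = (\min_e e)^{-1}$, equally
spaced, is then walked: at each step all edges of length $\ge 1/T$ are
deleted. Deletion is monotone, so the number of connected components never
decreases; we stop at the first step at which exactly `n_groups`
components remain and none is an isolated node. Because the schedule is a
grid, an unlucky embedding can jump from too few components straight past
the target; the generator then simply retries with fresh geometry (the
spread default makes this rare).

Each surviving group is directed by *topological order*: the node nearest
the group centroid is the root (order 1, in-degree 0), every other node
gets one plus its unweighted graph distance from the root, and each edge
points from lower to higher order (ties: lower node id to higher). A data
sample picks a group uniformly at random and sets the features of that
group's nodes to their topological order, all other features to $-1$.
All samples of a class are identical, so the task is trivially linearly
separable — deliberately so: the interest is in the topology the network
develops, not in the difficulty of the task.

### What the generators do and do not emulate

The generators reproduce the *covariance structure* of the two
environments (nested vs. block-diagonal) and the exact class counts. They
do not add observation noise, class imbalance beyond the analytic mix, or
any of the nuisance structure of real data sets; a pass on these
environments therefore shows that the pipeline detects topology changes
driven by clean statistical structure, not that it would behave identically
on noisy real-world data.

## The network and its training

The architecture presets mirror the three studied networks (the preset
name doubles as the reproducibility seed): `"240120"` = 31-20-10-4,
`"250120"` = 31-20-20-4, `"180112"` = 31-30-30-4, all with rectified-linear
hidden units and a softmax output, trained by minimizing categorical
cross-entropy (the standard pairing with a softmax read-out).

The optimizer is mini-batch stochastic gradient descent with Nesterov
momentum 0.6, initial learning rate 0.01 and inverse-time decay
$\eta_t = 0.01/(1 + 10^{-6} t)$ per update $t$. Batch size 32 and an epoch
budget of 200 are package defaults; on 4,000 samples of either environment
every initialization reaches training accuracy 1.0 within a handful of
epochs, so the budget is generous. By default the trainer spends the full
budget (`stop_at_perfect = FALSE`): the before/after weight comparison
assumes a fully trained model, and convergence speed is recorded separately
as `epochs_to_perfect`. Backpropagation is exact; the test suite verifies
every gradient against central finite differences to a relative $10^{-5}$.

Three initialization schemes are compared:

* **Normal** — i.i.d. $\mathcal N(0, 0.1^2)$. The 0.1 is a standard
  deviation: this is the only reading consistent with the pruning
  calibration below (with $\sigma \approx 0.32$ the retained-tail mean
  could not be as small as 0.206).
* **Orthogonal** — the semi-orthogonal factor of a Gaussian draw (QR with
  sign correction, i.e. Haar-distributed), giving $W W^\top = I$ for wide
  matrices.
* **Glorot (Xavier)** — i.i.d. Gaussian with variance
  $\sigma^2 = k/(n_{in} + n_{out})$; the gain defaults to $k = 2$, the
  rectifier-appropriate choice.

Empirically (and asserted as a median-over-seeds property in the tests) the
Normal scheme is the slowest to reach perfect accuracy; the wider
orthogonal and Glorot draws start with a sharper initial motif landscape
and converge in fewer epochs. With batch-size 32 on 4,000 samples all
schemes converge within one to three epochs, so the ordering is asserted on
medians over ten seeds rather than on the shape of long learning curves.

## From weights to a graph: density pruning

Retaining all 860 connections of the 31-20-10-4 network would make motif
counts meaningless (every possible layered pattern is present). The package
instead fits a Gaussian $p(w)$ to the pooled weights (maximum likelihood:
sample mean, $n$-denominator standard deviation; pooled because the
histogram of all connection weights is fitted as one population) and
excludes the high-density band

$$\{\, w : p(w) \ge c \cdot \max_w p(w) \,\}
  \iff |w - \mu| \le \sigma\sqrt{2\ln(1/c)} .$$

The greater the cutoff $c$, the smaller the exclusion region. The default
$c$ is not arbitrary: `calibrate_cutoff()` solves the truncated half-normal
mean equation $E(|w| \,\colon\, |w| > t) = 0.206$ for $w \sim \mathcal
N(0, 0.1^2)$ — the reference retained-weight mean for Normal-initialized
networks — giving $t \approx 1.64\,\sigma$, i.e. $c \approx 0.26$. A
simulation check of this closed form is part of the test suite, and the
seed-11 demo run reproduces a retained mean of 0.204 before training.

Retained weights become directed edges (input layer toward output, node
ids contiguous by layer: inputs 0–30, first hidden layer 31–50, …), each
categorized as *strong positive* ($w > \mu + 2\sigma$), *strong negative*
($w < \mu - 2\sigma$) or *mild* otherwise; the $2\sigma$ multiplier is a
conventional notion of "strong" and is configurable. Biases are activation
thresholds, not connections, and take no part in the graph. The same
pruning configuration is applied to the initialization snapshot and to the
trained model, so before/after profile deltas compare like with like.

## Motif mining

`count_subgraphs()` enumerates every weakly connected induced $k$-node
subgraph ($k = 3,4,5$) exactly once with the ESU algorithm (ordered
extension over exclusive neighborhoods). Each occurrence is classified by
an exhaustive canonical code: the minimum, over all $k! \le 120$ node
permutations, of the row-major adjacency matrix read as a base-2 integer —
base-4 when the analysis is *colored*, with each cell holding 0 (absent) or
the edge category. Exhaustive minimization makes the code provably
isomorphism-complete at these sizes; no heuristic canonical-labeling is
involved. The test suite cross-checks the full census against a brute-force
all-subsets oracle and, independently, against `igraph`'s triad machinery.

Null ensembles are built by degree-preserving double-edge swaps
$(a \to b, c \to d) \Rightarrow (a \to d, c \to b)$, rejecting self-loops
and duplicates, with 3 attempted swaps per edge and 1000 replicas by
default. Two switching modes are provided because the choice materially
affects the scores:

* `layer_preserving` (default) — swaps may not create an edge between
  non-consecutive layers, so every replica is itself a valid MLP topology;
* `global` — classical unconstrained switching.

Edge categories and weights travel with the source half of each swap,
which approximately preserves per-node color-degrees.

The significance of class $i$ is the non-normalized Z-score

$$Z_i = \frac{N^{real}_i - \langle N^{rand}_i \rangle}{\sigma^{rand}_i},$$

with the ensemble mean and sample standard deviation taken over all
replicas, counting 0 for replicas lacking the class. Classes with
$\sigma^{rand}_i = 0$ have no defined score and are excluded from profiles
and deltas. Two degeneracies of this kind are worth knowing about:

* On a layered graph, *every* 3-node class count is a function of the
  degree sequences alone (fan-out $\sum_v \binom{d^{out}_v}{2}$, fan-in
  $\sum_v \binom{d^{in}_v}{2}$, chain $\sum_v d^{in}_v d^{out}_v$), so
  layer-preserving ensembles at $k = 3$ have zero spread everywhere.
  Meaningful profiles on MLP graphs start at $k = 4$.
* A handful of 4- and 5-node classes (pure fans and their unions) are
  likewise degree-determined and appear with `sd_random = 0`.

`profile_delta()` subtracts before-training from after-training scores per
class, and `top_motifs()` ranks classes by $|Z|$; in a colored analysis,
classes sharing an uncolored skeleton form a group from which either the
most significant member (largest $|Z|$) or the most typical one (closest
to the group mean) is reported.

## The experiment grid

`run_experiment()` wires the stages together over the 2 (environments) × 3
(initializations) grid for one architecture (default `"240120"`): generate,
initialize (snapshot), train, prune both snapshots, mine each requested
motif size, score both graphs against their null ensembles, and difference
the profiles. A failing stage marks only its cell as failed. All artifacts
can be written as plain-text tables (CSV profiles and deltas, FANMOD-style
edge lists, GraphML, a JSON summary), and a rerun with the same seed is
byte-identical. Configurations can also be read from YAML
(`read_experiment_config()`; the null-model block is spelled `null_model:`
because a bare `null` key is the YAML null scalar).

Directional findings the test suite asserts on this grid:

* every cell reaches training accuracy 1.0 within the budget;
* the mean absolute retained weight increases through learning in every
  cell (learning pushes surviving weights into the tails);
* the Normal scheme has the largest median epochs-to-perfect on the tree
  environment.

## Numerical choices and degenerate inputs

* Temperature schedules with all edge lengths equal are constant
  ($T_0 = T_f$); a zero-length edge is a degenerate-geometry error.
* Annealing that exhausts its schedule (or overshoots the target component
  count) is an error at the `anneal_edges()` level; the dataset generator
  retries with new geometry up to 25 times.
* Softmax is computed with the row-max subtracted; cross-entropy clips
  probabilities at $10^{-300}$; a non-finite loss aborts training with the
  epoch in the message.
* Prediction ties resolve to the lowest class index (`max.col`,
  `ties.method = "first"`); an all-zero network on balanced labels scores
  exactly 0.25.
* A pruning cutoff that empties the graph is a warning, not an error.
* Canonical codes fit exactly in doubles ($2^{25}$ uncolored, $4^{25} <
  2^{53}$ colored) and are cached per adjacency pattern, which makes
  repeated ensemble censuses cheap.
* All derived seeds are kept below $2^{31}$.

## Problem sizes

Dataset defaults are 4,000 samples per environment — large enough for
stable class frequencies, small enough for desk-scale runs; the full
training grid completes in about a minute on one CPU. The null-ensemble
default is 1000 replicas, matching common practice for motif significance;
the bundled examples and the test suite pass smaller ensembles (8–200
replicas) explicitly so the whole suite runs in minutes. Exhaustive ESU
enumeration is intended for graphs up to roughly a thousand edges;
sampling-based enumeration and $k \ge 6$ are out of scope.

## Known limitations

* The specific motif identities emerging from a given training run depend
  on the null-model mode, the colored/uncolored choice and the ensemble
  size; the package surfaces all three as configuration rather than fixing
  a canonical setting, and treats published motif rankings as qualitative.
* Convergence on these noiseless environments is so fast (1–3 epochs) that
  learning-curve *shapes* carry little information; only the ordering of
  schemes is asserted.
* Only feed-forward fully connected architectures are supported — no
  convolutional, recurrent or bidirectional variants.
* The linear-separability of the clusters environment means the networks
  never need their full capacity; emergent motifs on harder tasks may
  differ.
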