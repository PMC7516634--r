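#' Configuration for the binary-tree environment
#'
#' The binary-tree generator produces feature vectors in `{-1, +1}` with a
#' hierarchical covariance structure. A complete binary tree of `depth` levels
#' is stored as a linear array (children of 0-based node `i` at `2i+1` and
#' `2i+2`), giving `2^depth - 1` features. The root is sampled uniformly from
#' `{-1, +1}` and its value diffuses down the branches: at each `+1` node one
#' child inherits `+1`, the other (and its whole progeny) is set to `-1`, with
#' the inheriting side flipped with probability `epsilon`.
#'
#' @param depth integer number of tree levels, at least 2 (and at least
#'   `distinction_level + 1` so class labels are defined).
#' @param epsilon flip probability in `[0, 1]`; smaller values make the `+1`
#'   path more predictable. Default 0.3.
#' @param distinction_level tree level whose `+1`-path identity defines the
#'   class; level 2 yields four classes.
#' @param n_samples number of samples a dataset draw produces.
#' @param seed optional integer seed for [generate_tree_dataset()].
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(depth = 5L, epsilon = 0.3, distinction_level = 2L,
                        n_samples = 4000L, seed = NULL) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 2L) stop("`depth` must be an integer >= 2")
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must lie in [0, 1]")
  distinction_level <- as.integer(distinction_level)
  if (distinction_level < 1L) stop("`distinction_level` must be >= 1")
  if (depth < distinction_level + 1L) {
    stop("`depth` must be at least `distinction_level` + 1")
  }
  if (n_samples < 1L) stop("`n_samples` must be positive")
  structure(list(depth = depth, epsilon = epsilon,
                 distinction_level = distinction_level,
                 n_samples = as.integer(n_samples), seed = seed),
            class = "tree_config")
}

#' Draw one binary-tree feature vector
#'
#' Samples the root uniformly from `{-1, +1}` and diffuses the `+1` value
#' down the tree. The root's `+1` child is deterministic (root `+1` promotes
#' the left child, root `-1` the right child); below the root, each `+1` node
#' passes `+1` to its left child when a uniform draw `p` exceeds `epsilon`,
#' otherwise to its right child. Every node inside a `-1` subtree is `-1`.
#'
#' @param config a [tree_config()].
#' @return Integer vector of length `2^depth - 1` with values in `{-1, +1}`,
#'   in linear-array order (root first).
#' @export
generate_tree_sample <- function(config) {
  stopifnot(inherits(config, "tree_config"))
  D <- config$depth
  n <- 2L^D - 1L
  v <- rep(-1L, n)
  v[1L] <- if (stats::runif(1) < 0.5) 1L else -1L
  # root's +1 child is deterministic; 1-based children of i are 2i, 2i+1
  if (v[1L] == 1L) v[2L] <- 1L else v[3L] <- 1L
  if (D > 2L) {
    n_internal <- 2L^(D - 1L) - 1L
    for (i in 2L:n_internal) {
      if (v[i] == 1L) {
        p <- stats::runif(1)
        if (p > config$epsilon) v[2L * i] <- 1L else v[2L * i + 1L] <- 1L
      }
    }
  }
  v
}

# level (1-based) of each 1-based linear-array index
.tree_levels <- function(n) floor(log2(seq_len(n))) + 1L

#' Class label of a binary-tree sample
#'
#' The class is the identity of the `+1` path down to level
#' `distinction_level + 1`: the root sign together with the flip outcomes at
#' the `+1` nodes of levels `2 .. distinction_level`. Encoded as a binary
#' index with the root-sign bit most significant (`+1` before `-1`, no-flip
#' before flip), so distinction level 2 enumerates the four classes as
#' (+1/no-flip, +1/flip, -1/no-flip, -1/flip) = 0..3.
#'
#' @param features an integer vector as produced by [generate_tree_sample()].
#' @param distinction_level integer level of distinction (default 2).
#' @return Integer class label in `[0, 2^distinction_level)`.
#' @export
tree_class_label <- function(features, distinction_level = 2L) {
  n <- length(features)
  D <- as.integer(round(log2(n + 1)))
  if (2L^D - 1L != n) stop("feature length is not 2^D - 1 for integer D")
  if (D < distinction_level + 1L) {
    stop("sample too shallow for this distinction level")
  }
  lv <- .tree_levels(n)
  # validity: exactly one +1 node on every level below the root
  for (l in 2L:D) {
    if (sum(features[lv == l] == 1L) != 1L) {
      stop("malformed sample: each level below the root must carry exactly one +1")
    }
  }
  bits <- integer(distinction_level)
  bits[1L] <- if (features[1L] == 1L) 0L else 1L
  node <- which(lv == 2L & features == 1L) # unique level-2 +1 node
  if (distinction_level >= 2L) {
    for (j in 2L:distinction_level) {
      left <- 2L * node
      bits[j] <- if (features[left] == 1L) 0L else 1L # no-flip = left child +1
      node <- if (bits[j] == 0L) left else left + 1L
    }
  }
  as.integer(sum(bits * 2L^((distinction_level:1L) - 1L)))
}

#' Generate a binary-tree dataset
#'
#' Draws `n_samples` independent tree samples and labels them with
#' [tree_class_label()]. At the default distinction level 2 and
#' `epsilon = 0.3` the class frequencies converge to
#' (0.35, 0.15, 0.35, 0.15): the root sign contributes a factor 1/2 and the
#' level-2 flip outcome factors `1 - epsilon` and `epsilon`.
#'
#' @param config a [tree_config()].
#' @return A [motif_dataset()] with `2^depth - 1` features.
#' @export
generate_tree_dataset <- function(config = tree_config()) {
  stopifnot(inherits(config, "tree_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_feat <- 2L^config$depth - 1L
  x <- matrix(0L, nrow = config$n_samples, ncol = n_feat)
  y <- integer(config$n_samples)
  for (s in seq_len(config$n_samples)) {
    v <- generate_tree_sample(config)
    x[s, ] <- v
    y[s] <- tree_class_label(v, config$distinction_level)
  }
  n_classes <- 2L^config$distinction_level
  motif_dataset(x, y, class_names = as.character(seq_len(n_classes) - 1L))
}

#' Expected class frequencies for the binary-tree environment
#'
#' Closed-form class probabilities at distinction level 2: each root sign has
#' probability 1/2 and the level-2 node passes `+1` left with probability
#' `1 - epsilon`.
#'
#' @param epsilon flip probability.
#' @return Numeric vector of length 4 summing to 1, ordered as the labels of
#'   [tree_class_label()].
#' @export
tree_class_probabilities <- function(epsilon = 0.3) {
  c(0.5 * (1 - epsilon), 0.5 * epsilon, 0.5 * (1 - epsilon), 0.5 * epsilon)
}
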