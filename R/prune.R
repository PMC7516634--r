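#' Pruning configuration
#'
#' Negligible weights are identified by fitting a Normal density `p(w)` to
#' the pooled weight histogram and excluding the high-density band
#' `{w : p(w) >= c * max_w p(w)}`. The greater the cutoff `c`, the smaller
#' the exclusion region. Retained weights are categorized as strongly
#' positive/negative when they lie more than `strong_multiplier` fitted
#' standard deviations from the fitted mean, and mild otherwise.
#'
#' @param cutoff density cutoff `c` in `(0, 1)`. The default 0.26 is
#'   calibrated with [calibrate_cutoff()] so that, for Normal-initialized
#'   weights of standard deviation 0.1, the mean absolute retained weight is
#'   0.206.
#' @param strong_multiplier category boundary in units of the fitted sigma
#'   (default 2).
#' @return An object of class `prune_config`.
#' @export
prune_config <- function(cutoff = 0.26, strong_multiplier = 2) {
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must lie in (0, 1)")
  if (strong_multiplier < 0) stop("`strong_multiplier` must be >= 0")
  structure(list(cutoff = cutoff, strong_multiplier = strong_multiplier),
            class = "prune_config")
}

#' Fit a Normal distribution to pooled weights
#'
#' Maximum-likelihood Gaussian fit (sample mean and the n-denominator
#' standard deviation) over all connection weights pooled across layers.
#'
#' @param weights numeric vector with at least two distinct values.
#' @return List with `mu` and `sigma`.
#' @export
fit_gaussian <- function(weights) {
  if (length(weights) < 2L || length(unique(weights)) < 2L) {
    stop("degenerate fit: need at least two distinct weights")
  }
  mu <- mean(weights)
  list(mu = mu, sigma = sqrt(mean((weights - mu)^2)))
}

#' Half-width of the density exclusion zone
#'
#' For a fitted `N(mu, sigma^2)` density, the set where the density is at
#' least `c` times its peak is the band `|w - mu| <= sigma * sqrt(2 ln(1/c))`;
#' this returns that half-width. As `c -> 1` the band shrinks to nothing.
#'
#' @param sigma fitted standard deviation.
#' @param cutoff density cutoff `c` in `(0, 1)`.
#' @return Non-negative numeric half-width.
#' @export
exclusion_halfwidth <- function(sigma, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must lie in (0, 1)")
  if (sigma <= 0) stop("degenerate fit: sigma must be positive")
  sigma * sqrt(2 * log(1 / cutoff))
}

#' Calibrate the density cutoff from a target retained mean
#'
#' Solves the truncated half-normal mean equation
#' `E(|w| : |w| > t) = target_mean` for the threshold `t` when
#' `w ~ N(0, sigma^2)`, then converts `t` to the density cutoff
#' `c = exp(-(t/sigma)^2 / 2)`. With `sigma = 0.1` and target 0.206 this
#' yields `c` of about 0.26 (threshold about 1.64 sigma), the package
#' default.
#'
#' @param target_mean desired mean absolute retained weight.
#' @param sigma weight standard deviation.
#' @return The density cutoff `c`.
#' @export
calibrate_cutoff <- function(target_mean = 0.206, sigma = 0.1) {
  if (target_mean <= sigma * sqrt(2 / pi)) {
    stop("`target_mean` must exceed the untruncated mean absolute weight")
  }
  mills <- function(z) stats::dnorm(z) / (1 - stats::pnorm(z))
  z <- stats::uniroot(function(z) sigma * mills(z) - target_mean,
                      c(1e-9, 10), tol = 1e-12)$root
  exp(-z^2 / 2)
}

#' Categorize a retained weight
#'
#' @param weight numeric weight value(s).
#' @param mu,sigma fitted Gaussian parameters.
#' @param strong_multiplier boundary in sigma units.
#' @return Character vector: `"strong_positive"`, `"strong_negative"` or
#'   `"mild"`.
#' @export
categorize_weight <- function(weight, mu, sigma, strong_multiplier = 2) {
  ifelse(weight > mu + strong_multiplier * sigma, "strong_positive",
         ifelse(weight < mu - strong_multiplier * sigma, "strong_negative",
                "mild"))
}

# pooled weights + global node id offsets for an mlp_parameters object
.weight_records <- function(params) {
  sizes <- params$layer_sizes
  offsets <- cumsum(c(0L, sizes))
  recs <- lapply(seq_along(params$W), function(l) {
    w <- params$W[[l]]
    idx <- which(array(TRUE, dim(w)), arr.ind = TRUE)
    data.frame(layer = l,
               from = offsets[l] + idx[, 1L] - 1L,
               to = offsets[l + 1L] + idx[, 2L] - 1L,
               weight = w[idx])
  })
  do.call(rbind, recs)
}

#' Prune negligible weights
#'
#' Pools all connection weights (biases are not connections and take no part
#' in the graph), fits a Gaussian, and retains exactly the weights outside
#' the density exclusion zone of [exclusion_halfwidth()]. Each retained
#' weight is categorized relative to the fit.
#'
#' @param params an `mlp_parameters` object.
#' @param config a [prune_config()].
#' @return Data frame of retained weights with columns `layer`, `from`, `to`
#'   (global 0-based node ids, contiguous by layer), `weight`, `category`;
#'   attributes `fit` (the Gaussian fit) and `halfwidth`. Zero rows (with a
#'   warning) when everything is excluded.
#' @export
prune_weights <- function(params, config = prune_config()) {
  stopifnot(inherits(params, "mlp_parameters"),
            inherits(config, "prune_config"))
  recs <- .weight_records(params)
  fit <- fit_gaussian(recs$weight)
  hw <- exclusion_halfwidth(fit$sigma, config$cutoff)
  keep <- abs(recs$weight - fit$mu) > hw
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("pruning retained no weights (empty graph)")
  } else {
    out$category <- categorize_weight(out$weight, fit$mu, fit$sigma,
                                      config$strong_multiplier)
  }
  attr(out, "fit") <- fit
  attr(out, "halfwidth") <- hw
  out
}

#' Extract the layered connection graph of a model
#'
#' Prunes the parameters with [prune_weights()] and assembles the survivors
#' into a layered directed graph: node ids are assigned contiguously by
#' layer (for the 31-20-10-4 preset, inputs are nodes 0..30, the first
#' hidden layer 31..50, and so on), every edge is oriented from input toward
#' output and spans consecutive layers.
#'
#' @param params an `mlp_parameters` object.
#' @param config a [prune_config()].
#' @return A [motif_digraph()] with `layer` set; attributes `fit` and
#'   `halfwidth` as in [prune_weights()].
#' @export
model_to_graph <- function(params, config = prune_config()) {
  retained <- prune_weights(params, config)
  sizes <- params$layer_sizes
  layer <- rep(seq_along(sizes), times = sizes)
  cols <- intersect(c("from", "to", "weight", "category"), names(retained))
  g <- motif_digraph(retained[cols], n_nodes = sum(sizes), layer = layer)
  attr(g, "fit") <- attr(retained, "fit")
  attr(g, "halfwidth") <- attr(retained, "halfwidth")
  g
}
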