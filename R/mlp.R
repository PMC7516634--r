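#' Multi-layer perceptron architecture
#'
#' Fully connected feed-forward classifier: ReLU hidden layers, softmax
#' output. Three named presets are provided (the name doubles as the
#' reproducibility seed of the preset): `"240120"` = 31-20-10-4,
#' `"250120"` = 31-20-20-4, `"180112"` = 31-30-30-4.
#'
#' @param layer_sizes integer vector of unit counts, input first, output
#'   last; or a preset name.
#' @param name optional label for the architecture.
#' @return An object of class `mlp_architecture`.
#' @export
mlp_architecture <- function(layer_sizes = "240120", name = NULL) {
  presets <- list("240120" = c(31L, 20L, 10L, 4L),
                  "250120" = c(31L, 20L, 20L, 4L),
                  "180112" = c(31L, 30L, 30L, 4L))
  if (is.character(layer_sizes)) {
    if (!layer_sizes %in% names(presets)) {
      stop("unknown architecture preset: ", layer_sizes)
    }
    if (is.null(name)) name <- layer_sizes
    layer_sizes <- presets[[layer_sizes]]
  }
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("`layer_sizes` needs >= 2 positive entries")
  }
  structure(list(layer_sizes = layer_sizes,
                 name = if (is.null(name)) paste(layer_sizes, collapse = "-")
                        else name),
            class = "mlp_architecture")
}

#' @export
print.mlp_architecture <- function(x, ...) {
  cat(sprintf("<mlp_architecture> %s: %s (ReLU hidden, softmax output)\n",
              x$name, paste(x$layer_sizes, collapse = "-")))
  invisible(x)
}

#' Gaussian weight initialization
#'
#' Entries i.i.d. `N(0, sd^2)` with the conventional small scale `sd = 0.1`.
#'
#' @param n_rows,n_cols matrix shape (fan-in by fan-out).
#' @param sd standard deviation (default 0.1).
#' @return Numeric `n_rows x n_cols` matrix.
#' @export
init_normal <- function(n_rows, n_cols, sd = 0.1) {
  matrix(stats::rnorm(n_rows * n_cols, mean = 0, sd = sd), n_rows, n_cols)
}

#' Orthogonal weight initialization
#'
#' Orthonormal factorization (QR with sign correction) of a standard Gaussian
#' draw. For an `n x m` result with `n <= m` the rows are orthonormal
#' (`W W^T = I_n`); with `n > m` the columns are.
#'
#' @param n_rows,n_cols matrix shape.
#' @return Numeric `n_rows x n_cols` semi-orthogonal matrix.
#' @export
init_orthogonal <- function(n_rows, n_cols) {
  big <- max(n_rows, n_cols); small <- min(n_rows, n_cols)
  a <- matrix(stats::rnorm(big * small), big, small)
  qr_ <- qr(a)
  q <- qr.Q(qr_)
  # fix the sign ambiguity so the draw is the Haar measure
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- sweep(q, 2L, d, `*`)
  if (n_rows <= n_cols) t(q) else q
}

#' Glorot (Xavier) weight initialization
#'
#' Entries i.i.d. Gaussian with mean 0 and variance `k / (fan_in + fan_out)`.
#' The gain `k` depends on the activation; `k = 2` is appropriate for the
#' rectifier.
#'
#' @param fan_in,fan_out numbers of incoming and outgoing connections.
#' @param k gain (default 2).
#' @return Numeric `fan_in x fan_out` matrix.
#' @export
init_glorot <- function(fan_in, fan_out, k = 2) {
  if (fan_in < 1L || fan_out < 1L) stop("fans must be >= 1")
  if (k <= 0) stop("`k` must be positive")
  matrix(stats::rnorm(fan_in * fan_out, mean = 0,
                      sd = sqrt(k / (fan_in + fan_out))),
         fan_in, fan_out)
}

#' Initialize MLP parameters
#'
#' Builds per-layer weight matrices (fan-in by fan-out) under one of the
#' three schemes and zero biases.
#'
#' @param arch an [mlp_architecture()].
#' @param scheme one of `"normal"`, `"orthogonal"`, `"glorot"`.
#' @param seed optional integer seed.
#' @return An object of class `mlp_parameters`: lists `W` and `b`.
#' @export
mlp_init <- function(arch, scheme = c("normal", "orthogonal", "glorot"),
                     seed = NULL) {
  stopifnot(inherits(arch, "mlp_architecture"))
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  sizes <- arch$layer_sizes
  n_lay <- length(sizes) - 1L
  W <- vector("list", n_lay); b <- vector("list", n_lay)
  for (l in seq_len(n_lay)) {
    W[[l]] <- switch(scheme,
      normal     = init_normal(sizes[l], sizes[l + 1L]),
      orthogonal = init_orthogonal(sizes[l], sizes[l + 1L]),
      glorot     = init_glorot(sizes[l], sizes[l + 1L]))
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, layer_sizes = sizes, scheme = scheme),
            class = "mlp_parameters")
}

#' @export
print.mlp_parameters <- function(x, ...) {
  cat(sprintf("<mlp_parameters> %s, %d weights (%s init)\n",
              paste(x$layer_sizes, collapse = "-"),
              sum(vapply(x$W, length, integer(1))),
              if (is.null(x$scheme)) "?" else x$scheme))
  invisible(x)
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass
#'
#' Propagates a batch through the network: hidden layers apply the rectifier
#' elementwise, the output layer applies a row-wise softmax, so each output
#' row sums to 1.
#'
#' @param params an `mlp_parameters` object.
#' @param x numeric matrix, one sample per row (width = input size).
#' @return List of per-layer activation matrices, input first, class
#'   probabilities last.
#' @export
mlp_forward <- function(params, x) {
  stopifnot(inherits(params, "mlp_parameters"))
  x <- as.matrix(x)
  if (ncol(x) != params$layer_sizes[1L]) {
    stop("input width ", ncol(x), " does not match input layer size ",
         params$layer_sizes[1L])
  }
  n_lay <- length(params$W)
  acts <- vector("list", n_lay + 1L)
  acts[[1L]] <- x
  a <- x
  for (l in seq_len(n_lay)) {
    z <- a %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(a), length(params$b[[l]]), byrow = TRUE)
    a <- if (l < n_lay) pmax(z, 0) else .softmax(z)
    acts[[l + 1L]] <- a
  }
  acts
}

#' Loss and parameter gradients by backpropagation
#'
#' Mean categorical cross-entropy over the batch and its exact gradients with
#' respect to every weight matrix and bias vector.
#'
#' @param params an `mlp_parameters` object.
#' @param x batch matrix, one sample per row.
#' @param y integer labels in `[0, n_classes)`.
#' @return List with `loss`, `dW` (list of matrices) and `db` (list of
#'   vectors).
#' @export
mlp_gradient <- function(params, x, y) {
  n_lay <- length(params$W)
  m <- nrow(x)
  # forward with cached pre-relu masks
  acts <- vector("list", n_lay + 1L)
  acts[[1L]] <- x
  a <- x
  for (l in seq_len(n_lay)) {
    z <- a %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(a), length(params$b[[l]]), byrow = TRUE)
    a <- if (l < n_lay) pmax(z, 0) else .softmax(z)
    acts[[l + 1L]] <- a
  }
  p <- acts[[n_lay + 1L]]
  picked <- p[cbind(seq_len(m), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  onehot <- matrix(0, m, ncol(p))
  onehot[cbind(seq_len(m), y + 1L)] <- 1
  dW <- vector("list", n_lay); db <- vector("list", n_lay)
  dz <- (p - onehot) / m
  for (l in n_lay:1L) {
    dW[[l]] <- crossprod(acts[[l]], dz)
    db[[l]] <- colSums(dz)
    if (l > 1L) {
      da <- tcrossprod(dz, params$W[[l]])
      dz <- da * (acts[[l]] > 0) # relu mask
    }
  }
  list(loss = loss, dW = dW, db = db)
}

#' Training configuration
#'
#' Defaults follow the reference optimizer: stochastic (mini-batch) gradient
#' descent at learning rate 0.01 with inverse-time decay 1e-6 per update and
#' Nesterov momentum 0.6.
#'
#' @param learning_rate initial learning rate.
#' @param decay per-update inverse-time decay factor; the effective rate at
#'   update `t` is `learning_rate / (1 + decay * t)`.
#' @param momentum Nesterov momentum coefficient.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch budget.
#' @param init_scheme weight initialization scheme for [mlp_init()].
#' @param stop_at_perfect stop once training accuracy reaches 1.0. Off by
#'   default: the full epoch budget is spent, as in a fixed-budget training
#'   run, which is what the before/after weight comparison assumes. The
#'   convergence epoch is recorded either way.
#' @param seed optional integer seed covering initialization and batching.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, decay = 1e-6, momentum = 0.6,
                         batch_size = 32L, max_epochs = 200L,
                         init_scheme = c("normal", "orthogonal", "glorot"),
                         stop_at_perfect = FALSE, seed = NULL) {
  init_scheme <- match.arg(init_scheme)
  if (learning_rate < 0) stop("`learning_rate` must be >= 0")
  if (batch_size < 1L) stop("`batch_size` must be positive")
  if (max_epochs < 1L) stop("`max_epochs` must be positive")
  structure(list(learning_rate = learning_rate, decay = decay,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 init_scheme = init_scheme,
                 stop_at_perfect = isTRUE(stop_at_perfect), seed = seed),
            class = "train_config")
}

#' Classification accuracy
#'
#' Fraction of samples whose arg-max output equals the label; ties resolve to
#' the lowest class index.
#'
#' @param params an `mlp_parameters` object.
#' @param dataset a [motif_dataset()].
#' @return Fraction in `[0, 1]`.
#' @export
mlp_accuracy <- function(params, dataset) {
  stopifnot(inherits(dataset, "motif_dataset"))
  if (nrow(dataset$x) == 0L) stop("empty dataset")
  p <- mlp_forward(params, dataset$x)
  probs <- p[[length(p)]]
  pred <- max.col(probs, ties.method = "first") - 1L
  mean(pred == dataset$y)
}

#' Train a multi-layer perceptron
#'
#' Minimizes categorical cross-entropy by mini-batch gradient descent with
#' Nesterov momentum. The parameter update for each tensor is
#' `v <- mu * v - lr_t * g; p <- p + mu * v - lr_t * g` with `g` the batch
#' gradient and `lr_t` the decayed rate, the standard momentum-as-look-ahead
#' formulation. Snapshots of the initial and final parameters are retained so
#' the connectivity graph can be extracted before and after learning.
#'
#' @param arch an [mlp_architecture()] (or pre-built `mlp_parameters` to
#'   resume from).
#' @param dataset a [motif_dataset()]; feature count must match the input
#'   layer, labels must fit the output layer.
#' @param config a [train_config()].
#' @return An object of class `mlp_train_result`: `initial` and `final`
#'   parameter snapshots, a per-epoch `history` data frame (loss, accuracy)
#'   and `epochs_to_perfect` (first epoch with training accuracy 1.0, `NA` if
#'   never reached).
#' @export
mlp_train <- function(arch, dataset, config = train_config()) {
  stopifnot(inherits(dataset, "motif_dataset"),
            inherits(config, "train_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- if (inherits(arch, "mlp_parameters")) arch
            else mlp_init(arch, config$init_scheme)
  sizes <- params$layer_sizes
  if (ncol(dataset$x) != sizes[1L]) {
    stop("dataset features do not match the input layer")
  }
  if (max(dataset$y) + 1L > sizes[length(sizes)]) {
    stop("labels exceed the output layer size")
  }
  initial <- params
  n_lay <- length(params$W)
  vW <- lapply(params$W, function(w) array(0, dim(w)))
  vb <- lapply(params$b, function(b) numeric(length(b)))
  n <- nrow(dataset$x)
  mu <- config$momentum
  step <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  epochs_to_perfect <- NA_integer_
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      g <- mlp_gradient(params, dataset$x[idx, , drop = FALSE],
                        dataset$y[idx])
      if (!is.finite(g$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      lr <- config$learning_rate / (1 + config$decay * step)
      for (l in seq_len(n_lay)) {
        vW[[l]] <- mu * vW[[l]] - lr * g$dW[[l]]
        params$W[[l]] <- params$W[[l]] + mu * vW[[l]] - lr * g$dW[[l]]
        vb[[l]] <- mu * vb[[l]] - lr * g$db[[l]]
        params$b[[l]] <- params$b[[l]] + mu * vb[[l]] - lr * g$db[[l]]
      }
      step <- step + 1L
      epoch_loss <- epoch_loss + g$loss * length(idx)
    }
    acc <- mlp_accuracy(params, dataset)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss / n,
                                accuracy = acc))
    if (is.na(epochs_to_perfect) && acc >= 1) epochs_to_perfect <- epoch
    if (config$stop_at_perfect && acc >= 1) break
  }
  structure(list(initial = initial, final = params, history = history,
                 epochs_to_perfect = epochs_to_perfect,
                 config = config, arch_name =
                   if (inherits(arch, "mlp_architecture")) arch$name else NA),
            class = "mlp_train_result")
}

#' @export
print.mlp_train_result <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("<mlp_train_result> %d epochs, final accuracy %.3f, ",
                     "perfect at epoch %s\n"),
              nrow(x$history), last$accuracy,
              ifelse(is.na(x$epochs_to_perfect), "never",
                     x$epochs_to_perfect)))
  invisible(x)
}
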