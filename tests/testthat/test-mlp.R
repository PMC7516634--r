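test_that("initializers have the stated first and second moments", {
  set.seed(1)
  w <- init_normal(400L, 250L) # 1e5 draws
  expect_identical(dim(w), c(400L, 250L))
  expect_lt(abs(mean(w)), 3 * 0.1 / sqrt(1e5))
  expect_equal(sd(w), 0.1, tolerance = 0.02)

  # ~1e5 draws at fan-in 31, fan-out 20, gain 2: variance 2/51 = 0.0392
  draws <- as.numeric(replicate(162, init_glorot(31L, 20L)))
  expect_equal(stats::var(draws), 2 / 51, tolerance = 0.02)
  # gain 1 with unit fans: variance 1/2
  draws1 <- replicate(20000, init_glorot(1L, 1L, k = 1)[1L, 1L])
  expect_equal(stats::var(draws1), 0.5, tolerance = 0.05)
})

test_that("orthogonal initialization yields orthonormal rows or columns", {
  set.seed(2)
  w <- init_orthogonal(4L, 4L)
  expect_lt(max(abs(w %*% t(w) - diag(4L))), 1e-6)
  wide <- init_orthogonal(3L, 5L)
  expect_lt(max(abs(wide %*% t(wide) - diag(3L))), 1e-6)
  tall <- init_orthogonal(5L, 3L)
  expect_lt(max(abs(t(tall) %*% tall - diag(3L))), 1e-6)
  set.seed(77); a <- init_orthogonal(6L, 4L)
  set.seed(77); b <- init_orthogonal(6L, 4L)
  expect_identical(a, b)
})

test_that("the forward pass applies the rectifier and normalizes softmax", {
  arch <- mlp_architecture(c(3L, 2L, 4L))
  params <- mlp_init(arch, "normal", seed = 4)
  for (l in seq_along(params$W)) params$W[[l]][] <- 0
  acts <- mlp_forward(params, matrix(rnorm(12), 4L, 3L))
  expect_true(all(acts[[3L]] == 0.25)) # softmax of zeros is uniform
  # a negative pre-activation rectifies to zero
  params2 <- mlp_init(arch, "normal", seed = 4)
  params2$W[[1L]][] <- -1
  acts2 <- mlp_forward(params2, matrix(1, 1L, 3L))
  expect_true(all(acts2[[2L]] == 0))
  params3 <- mlp_init(mlp_architecture("240120"), "glorot", seed = 5)
  out <- mlp_forward(params3, matrix(rnorm(31 * 7), 7L, 31L))
  expect_equal(rowSums(out[[4L]]), rep(1, 7L), tolerance = 1e-12)
  expect_error(mlp_forward(params3, matrix(0, 2L, 5L)), "input width")
})

test_that("backpropagation matches central finite differences", {
  set.seed(6)
  for (trial in 1:3) {
    sizes <- c(sample(2:5, 1L), sample(2:4, 1L), sample(2:4, 1L))
    params <- mlp_init(mlp_architecture(sizes), "glorot")
    x <- matrix(rnorm(3L * sizes[1L]), 3L)
    y <- sample(0:(sizes[length(sizes)] - 1L), 3L, replace = TRUE)
    g <- mlp_gradient(params, x, y)
    h <- 1e-5
    for (l in seq_along(params$W)) {
      for (pos in sample(length(params$W[[l]]),
                         min(4L, length(params$W[[l]])))) {
        up <- params; up$W[[l]][pos] <- up$W[[l]][pos] + h
        dn <- params; dn$W[[l]][pos] <- dn$W[[l]][pos] - h
        fd <- (mlp_gradient(up, x, y)$loss - mlp_gradient(dn, x, y)$loss) /
          (2 * h)
        expect_equal(g$dW[[l]][pos], fd, tolerance = 1e-5)
      }
      up <- params; up$b[[l]][1L] <- up$b[[l]][1L] + h
      dn <- params; dn$b[[l]][1L] <- dn$b[[l]][1L] - h
      fd <- (mlp_gradient(up, x, y)$loss - mlp_gradient(dn, x, y)$loss) /
        (2 * h)
      expect_equal(g$db[[l]][1L], fd, tolerance = 1e-5)
    }
  }
})

test_that("a zero learning rate leaves the parameters untouched", {
  ds <- generate_tree_dataset(tree_config(n_samples = 64L, seed = 9))
  fit <- mlp_train(mlp_architecture("240120"), ds,
                   train_config(learning_rate = 0, max_epochs = 3L,
                                seed = 10))
  expect_identical(fit$initial$W, fit$final$W)
  expect_identical(fit$initial$b, fit$final$b)
})

test_that("full-batch plain gradient descent has non-increasing loss", {
  ds <- generate_clusters_dataset(clusters_config(n_samples = 128L,
                                                  seed = 12))
  fit <- mlp_train(mlp_architecture("240120"), ds,
                   train_config(momentum = 0, decay = 0, batch_size = 128L,
                                max_epochs = 40L, init_scheme = "glorot",
                                seed = 13))
  expect_true(all(diff(fit$history$loss) <= 1e-10))
})

test_that("accuracy uses argmax with ties resolved to the lowest class", {
  ds <- motif_dataset(matrix(0, 100L, 31L), rep(0:3, each = 25L))
  params <- mlp_init(mlp_architecture("240120"), "normal", seed = 14)
  for (l in seq_along(params$W)) params$W[[l]][] <- 0
  # uniform outputs predict class 0 everywhere: accuracy = share of class 0
  expect_identical(mlp_accuracy(params, ds), 0.25)
  expect_error(mlp_accuracy(params, motif_dataset(matrix(0, 0L, 31L),
                                                  integer())),
               "empty")
})

test_that("training reaches perfect accuracy on both environments", {
  tree <- generate_tree_dataset(tree_config(n_samples = 1000L, seed = 15))
  clus <- generate_clusters_dataset(clusters_config(n_samples = 1000L,
                                                    seed = 16))
  for (ds in list(tree, clus)) {
    fit <- mlp_train(mlp_architecture("240120"), ds,
                     train_config(init_scheme = "orthogonal", seed = 17,
                                  stop_at_perfect = TRUE))
    expect_identical(max(fit$history$accuracy), 1)
    expect_false(is.na(fit$epochs_to_perfect))
  }
})
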