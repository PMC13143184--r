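# The convolutional classifier: loss arithmetic, architecture bookkeeping,
# gradient correctness, training behavior, prediction contracts.

make_toy <- function(n_per = 30, len = 120, seed = 1) {
  # two trivially separable waveforms + small noise
  set.seed(seed)
  tt <- seq_len(len) / len
  x <- rbind(
    t(replicate(n_per, sin(2 * pi * 3 * tt) + rnorm(len, 0, 0.05))),
    t(replicate(n_per, sign(sin(2 * pi * 3 * tt)) + rnorm(len, 0, 0.05))))
  x <- (x - min(x)) / (max(x) - min(x))
  y <- rep(c("smooth", "square"), each = n_per)
  list(x = x, y = y)
}

test_that("cross-entropy matches closed forms", {
  perfect <- diag(4)
  expect_equal(cross_entropy_loss(perfect, perfect), 0, tolerance = 1e-10)
  uniform <- matrix(1 / 8, 3, 8)
  onehot <- diag(8)[c(1, 5, 8), ]
  expect_equal(cross_entropy_loss(uniform, onehot), log(8))
  # batch of 2 with probabilities 0.5 and 0.25 on the true classes
  prob <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  oh <- rbind(c(1, 0), c(1, 0))
  expect_equal(cross_entropy_loss(prob, oh), -(log(0.5) + log(0.25)) / 2)
  expect_gt(cross_entropy_loss(matrix(c(0, 1), 1), matrix(c(1, 0), 1)), 20)
})

test_that("the architecture's parameter count matches layer arithmetic", {
  toy <- make_toy(4)
  fit <- lkcnn(toy$x, toy$y, x_val = toy$x, y_val = toy$y, kernel_size = 8,
               epochs = 1, patience = 1, seed = 1)
  # independent oracle: layer-by-layer count for input 120, k = 8, C = 2
  L1 <- (120 - 8) %/% 2 + 1; L2 <- L1 %/% 2
  L3 <- (L2 - 8) %/% 2 + 1; L4 <- L3 %/% 2
  oracle <- (8 * 1 * 16 + 16) + (8 * 16 * 32 + 32) +
    (L4 * 32 * 64 + 64) + (64 * 32 + 32) + (32 * 2 + 2)
  expect_equal(n_parameters(fit), oracle)

  # the published architecture at k = 28 on 1000-point inputs
  ns <- asNamespace("castate")
  dims <- ns$.lkcnn_dims(1000L, 28L, 8L)
  par <- ns$.lkcnn_init(dims)
  expect_equal(sum(vapply(par, length, numeric(1))),
               (28 * 16 + 16) + (28 * 16 * 32 + 32) +
                 (54 * 32 * 64 + 64) + (64 * 32 + 32) + (32 * 8 + 8))
  expect_error(ns$.lkcnn_dims(1000L, 300L, 8L), "too large")
})

test_that("backpropagation matches finite-difference gradients", {
  ns <- asNamespace("castate")
  set.seed(3)
  dims <- ns$.lkcnn_dims(64L, 6L, 3L)
  par <- ns$.lkcnn_init(dims)
  X <- matrix(runif(4 * 64), 4, 64)
  Y <- diag(3)[sample(1:3, 4, TRUE), ]
  loss_fn <- function(p) {
    cross_entropy_loss(ns$.lkcnn_forward(p, X, dims)$prob, Y)
  }
  fwd <- ns$.lkcnn_forward(par, X, dims, training = TRUE, dropout_rate = 0)
  g <- ns$.lkcnn_backward(par, X, Y, fwd, dims)
  for (nm in names(par)) {
    ii <- sample(length(par[[nm]]), min(4, length(par[[nm]])))
    for (i in ii) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + 1e-6
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - 1e-6
      num <- (loss_fn(pp) - loss_fn(pm)) / 2e-6
      expect_equal(g[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("softmax output rows always sum to one", {
  toy <- make_toy(3)
  fit <- lkcnn(toy$x, toy$y, x_val = toy$x, y_val = toy$y, kernel_size = 8,
               epochs = 1, patience = 1, seed = 1)
  prob <- predict(fit, toy$x, type = "prob")
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-9)
  expect_true(all(prob >= 0))
})

test_that("training solves a separable toy problem and is deterministic", {
  toy <- make_toy(30)
  idx_val <- c(1:6, 31:36)
  fit <- lkcnn(toy$x[-idx_val, ], toy$y[-idx_val],
               x_val = toy$x[idx_val, ], y_val = toy$y[idx_val],
               kernel_size = 8, lr = 1e-3, epochs = 40, patience = 40,
               seed = 2)
  expect_equal(max(fit$record$val_accuracy), 1.0)
  pred <- predict(fit, toy$x[idx_val, ])
  expect_equal(as.character(pred), toy$y[idx_val])

  # duplicated inputs get identical predictions (deterministic inference)
  p2 <- predict(fit, toy$x[c(1, 1), ], type = "prob")
  expect_identical(p2[1, ], p2[2, ])

  # full determinism under a fixed seed
  fit2 <- lkcnn(toy$x[-idx_val, ], toy$y[-idx_val],
                x_val = toy$x[idx_val, ], y_val = toy$y[idx_val],
                kernel_size = 8, lr = 1e-3, epochs = 5, patience = 5,
                seed = 7)
  fit3 <- lkcnn(toy$x[-idx_val, ], toy$y[-idx_val],
                x_val = toy$x[idx_val, ], y_val = toy$y[idx_val],
                kernel_size = 8, lr = 1e-3, epochs = 5, patience = 5,
                seed = 7)
  expect_identical(fit2$record, fit3$record)
  expect_identical(fit2$par, fit3$par)
})

test_that("early stopping honors a zero patience boundary", {
  toy <- make_toy(8)
  fit <- lkcnn(toy$x, toy$y, x_val = toy$x[1:4, ], y_val = toy$y[1:4],
               kernel_size = 8, epochs = 50, patience = 0, seed = 1)
  # stops right after the first epoch that fails to improve
  rec <- fit$record
  expect_lt(nrow(rec), 50)
  expect_equal(nrow(rec), attr(rec, "best_epoch") + 1L)
})

test_that("prediction validates the input length", {
  toy <- make_toy(3)
  fit <- lkcnn(toy$x, toy$y, x_val = toy$x, y_val = toy$y, kernel_size = 8,
               epochs = 1, patience = 1, seed = 1)
  expect_error(predict(fit, matrix(0, 2, 50)), "input length")
})
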