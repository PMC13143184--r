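# Large-kernel 1-D convolutional network, implemented directly on BLAS
# matrix products (im2col convolutions) with hand-written backpropagation
# and Adam. Single master seed drives initialization, shuffling and dropout,
# so training is bit-reproducible single-threaded.

# ---- layer primitives ------------------------------------------------------

.conv_colidx <- function(Lin, Cin, K, stride) {
  Lout <- (Lin - K) %/% stride + 1L
  if (Lout < 1) stop("kernel size too large for input length ", Lin)
  # gather index ordered (j, kk, c): the gathered B x (Lout*K*Cin) block is
  # then directly the (B*Lout) x (K*Cin) im2col matrix, no transpose needed
  j <- seq_len(Lout)
  idx <- outer((j - 1L) * stride, seq_len(K), "+")            # Lout x K
  as.integer(outer(as.vector(idx), (seq_len(Cin) - 1L) * Lin, "+"))
}

.conv1d_forward <- function(X, W, b, stride, colidx = NULL) {
  # X: array (B, Lin, Cin); W: (K*Cin) x F
  d <- dim(X)
  B <- d[1]; Lin <- d[2]; Cin <- d[3]
  K <- nrow(W) / Cin
  Lout <- (Lin - K) %/% stride + 1L
  if (Lout < 1) stop("kernel size too large for input length ", Lin)
  if (is.null(colidx)) colidx <- .conv_colidx(Lin, Cin, K, stride)
  Xmat <- X
  dim(Xmat) <- c(B, Lin * Cin)
  P <- .gather_cols_cpp(Xmat, colidx)
  dim(P) <- c(B * Lout, K * Cin)
  Z <- P %*% W
  Z <- Z + rep(b, each = nrow(Z))
  dim(Z) <- c(B, Lout, ncol(W))
  list(Y = Z, P = P, Lin = Lin, Cin = Cin,
       K = K, stride = stride, Lout = Lout)
}

.conv1d_backward <- function(cache, W, dY, colidx) {
  B <- dim(dY)[1]; Lout <- cache$Lout
  dZ <- dY
  dim(dZ) <- c(B * Lout, dim(dY)[3])
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dP <- tcrossprod(dZ, W)  # (B*Lout) x (K*Cin)
  # col2im: overlapping windows scatter-add back onto the source columns
  dim(dP) <- c(B, Lout * cache$K * cache$Cin)
  dXmat <- .scatter_cols_cpp(dP, colidx, cache$Lin * cache$Cin)
  dim(dXmat) <- c(B, cache$Lin, cache$Cin)
  list(dX = dXmat, dW = dW, db = db)
}

.maxpool2_forward <- function(X) {
  d <- dim(X)
  .maxpool2_fwd_cpp(X, d[1], d[2], d[3])
}

.maxpool2_backward <- function(cache, dY) {
  d <- dim(dY)
  .maxpool2_bwd_cpp(dY, cache$take1, d[1], cache$L, d[3])
}

.relu <- function(Z) list(Y = .relu_fwd_cpp(Z))

.dropout_mask <- function(dims, rate) {
  m <- .dropout_mask_cpp(prod(dims), rate)
  dim(m) <- dims
  m
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Categorical cross-entropy loss
#'
#' L = -(1/N) sum_i sum_j y_ij log(yhat_ij), with predicted probabilities
#' clipped at 1e-12 so a zero probability on the true class yields a large
#' finite loss rather than infinity.
#'
#' @param prob N x C matrix of predicted class probabilities (rows sum to 1).
#' @param onehot N x C one-hot ground truth matrix.
#' @return Mean cross-entropy (non-negative scalar).
#' @export
cross_entropy_loss <- function(prob, onehot) {
  stopifnot(all(dim(prob) == dim(onehot)))
  p <- pmax(prob, 1e-12)
  -sum(onehot * log(p)) / nrow(prob)
}

# ---- model construction ----------------------------------------------------

.lkcnn_dims <- function(input_length, k, n_classes,
                        filters = c(16L, 32L), dense = c(64L, 32L)) {
  L1 <- (input_length - k) %/% 2L + 1L
  L2 <- L1 %/% 2L
  if (L2 < k) stop("kernel size ", k, " too large for the post-pooling length ", L2)
  L3 <- (L2 - k) %/% 2L + 1L
  L4 <- L3 %/% 2L
  if (L4 < 1) stop("kernel size ", k, " leaves no features after pooling")
  list(L1 = L1, L2 = L2, L3 = L3, L4 = L4, flat = L4 * filters[2],
       filters = filters, dense = dense, n_classes = n_classes, k = k,
       input_length = input_length,
       colidx1 = .conv_colidx(input_length, 1L, k, 2L),
       colidx2 = .conv_colidx(L2, filters[1], k, 2L))
}

.glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.lkcnn_init <- function(dims) {
  k <- dims$k; F1 <- dims$filters[1]; F2 <- dims$filters[2]
  list(
    W1 = .glorot(k * 1, F1, k * 1, k * F1), b1 = rep(0, F1),
    W2 = .glorot(k * F1, F2, k * F1, k * F2), b2 = rep(0, F2),
    W3 = .glorot(dims$flat, dims$dense[1], dims$flat, dims$dense[1]),
    b3 = rep(0, dims$dense[1]),
    W4 = .glorot(dims$dense[1], dims$dense[2], dims$dense[1], dims$dense[2]),
    b4 = rep(0, dims$dense[2]),
    W5 = .glorot(dims$dense[2], dims$n_classes, dims$dense[2],
                 dims$n_classes),
    b5 = rep(0, dims$n_classes))
}

# forward pass; when training=TRUE, dropout masks are drawn from R's RNG and
# the caches needed by backprop are returned
.lkcnn_forward <- function(par, X, dims, training = FALSE,
                           dropout_rate = 0.5) {
  B <- nrow(X)
  Xa <- array(X, c(B, dims$input_length, 1L))
  c1 <- .conv1d_forward(Xa, par$W1, par$b1, 2L, dims$colidx1)
  r1 <- .relu(c1$Y)
  p1 <- .maxpool2_forward(r1$Y)
  c2 <- .conv1d_forward(p1$Y, par$W2, par$b2, 2L, dims$colidx2)
  r2 <- .relu(c2$Y)
  p2 <- .maxpool2_forward(r2$Y)
  Fl <- p2$Y
  m_conv <- NULL
  if (training) {
    m_conv <- .dropout_mask(dim(Fl), dropout_rate)
    Fl <- Fl * m_conv
  }
  dim(Fl) <- c(B, dims$flat)
  Z3 <- Fl %*% par$W3
  Z3 <- Z3 + rep(par$b3, each = B)
  r3 <- .relu(Z3)
  H3 <- r3$Y
  m_d <- NULL
  if (training) {
    m_d <- .dropout_mask(dim(H3), dropout_rate)
    H3 <- H3 * m_d
  }
  Z4 <- H3 %*% par$W4
  Z4 <- Z4 + rep(par$b4, each = B)
  r4 <- .relu(Z4)
  logits <- r4$Y %*% par$W5
  logits <- logits + rep(par$b5, each = B)
  prob <- .softmax(logits)
  list(prob = prob, logits = logits,
       cache = if (training) list(c1 = c1, r1 = r1, p1 = p1, c2 = c2,
                                  r2 = r2, p2 = p2, m_conv = m_conv,
                                  Fl = Fl, r3 = r3, m_d = m_d, H3 = H3,
                                  r4 = r4) else NULL)
}

.lkcnn_backward <- function(par, X, onehot, fwd, dims) {
  B <- nrow(X)
  ca <- fwd$cache
  dLogits <- (fwd$prob - onehot) / B
  g <- list()
  H4 <- ca$r4$Y
  g$W5 <- crossprod(H4, dLogits); g$b5 <- colSums(dLogits)
  dH4 <- .relu_bwd_cpp(dLogits %*% t(par$W5), ca$r4$Y)
  g$W4 <- crossprod(ca$H3, dH4); g$b4 <- colSums(dH4)
  dH3 <- dH4 %*% t(par$W4)
  if (!is.null(ca$m_d)) dH3 <- dH3 * ca$m_d
  dH3 <- .relu_bwd_cpp(dH3, ca$r3$Y)
  g$W3 <- crossprod(ca$Fl, dH3); g$b3 <- colSums(dH3)
  dA <- dH3 %*% t(par$W3)
  dim(dA) <- c(B, dims$L4, dims$filters[2])
  if (!is.null(ca$m_conv)) dA <- dA * ca$m_conv
  dP2 <- .maxpool2_backward(ca$p2, dA)
  dP2 <- .relu_bwd_cpp(dP2, ca$r2$Y)
  bk2 <- .conv1d_backward(ca$c2, par$W2, dP2, dims$colidx2)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  dP1 <- .maxpool2_backward(ca$p1, bk2$dX)
  dP1 <- .relu_bwd_cpp(dP1, ca$r1$Y)
  bk1 <- .conv1d_backward(ca$c1, par$W1, dP1, dims$colidx1)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

.adam_state <- function(par) {
  list(m = lapply(par, function(w) w * 0),
       v = lapply(par, function(w) w * 0), t = 0L)
}

.adam_update <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  st$t <- st$t + 1L
  upd <- .adam_step_cpp(par, grad[names(par)], st$m, st$v, st$t, lr, beta1,
                        beta2, eps)
  st$m <- upd$m
  st$v <- upd$v
  list(par = upd$par, st = st)
}

# ---- user-facing fit / predict --------------------------------------------

#' Fit the large-kernel 1-D convolutional classifier
#'
#' Architecture: conv(16 filters, kernel `kernel_size`, stride 2) -> max
#' pool(2) -> conv(32, `kernel_size`, stride 2) -> max pool(2) ->
#' dropout(0.5) -> flatten -> dense(64) -> dropout(0.5) -> dense(32) ->
#' softmax output; ReLU on all hidden layers, valid (unpadded)
#' convolutions. Trained with Adam on the categorical cross-entropy, early
#' stopping on validation accuracy with best-weights restoration. Inference
#' is deterministic (dropout active only during training).
#'
#' @param x numeric matrix of training series, one row per trajectory
#'   (typically 1000 columns from [prepare_input()]).
#' @param y factor (or character) of class labels, one per row of `x`.
#' @param x_val,y_val validation split used for early stopping.
#' @param kernel_size temporal receptive field `k` (samples).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 32).
#' @param epochs maximum epochs (default 2000).
#' @param patience epochs without validation-accuracy improvement before
#'   stopping (default 100).
#' @param dropout_rate dropout probability (default 0.5).
#' @param seed master seed for initialization, shuffling and dropout.
#' @param classes optional fixed class-level ordering.
#' @param verbose print per-epoch progress.
#' @return An object of class `lkcnn`: list with `par` (weights), `dims`,
#'   `classes`, `config`, and `record` (data frame of epoch, loss,
#'   validation accuracy; attribute `best_epoch`).
#' @seealso [predict.lkcnn()], [kernel_scan()]
#' @export
lkcnn <- function(x, y, x_val = NULL, y_val = NULL, kernel_size = 28,
                  lr = 1e-4, batch_size = 32, epochs = 2000, patience = 100,
                  dropout_rate = 0.5, seed = 1, classes = NULL,
                  verbose = FALSE) {
  x <- as.matrix(x)
  if (is.null(classes)) {
    classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  }
  y <- factor(as.character(y), levels = classes)
  if (anyNA(y)) stop("labels outside the class set")
  if (nrow(x) == 0) stop("empty training split")
  has_val <- !is.null(x_val) && nrow(as.matrix(x_val)) > 0
  if (!has_val) stop("a non-empty validation split is required for early stopping")
  x_val <- as.matrix(x_val)
  y_val <- factor(as.character(y_val), levels = classes)
  dims <- .lkcnn_dims(ncol(x), kernel_size, length(classes))
  set.seed(seed)
  par <- .lkcnn_init(dims)
  st <- .adam_state(par)
  onehot_all <- diag(length(classes))[as.integer(y), , drop = FALSE]
  n <- nrow(x)
  best_acc <- -Inf
  best_par <- par
  best_epoch <- 0L
  rec <- vector("list", epochs)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- x[idx, , drop = FALSE]
      Yb <- onehot_all[idx, , drop = FALSE]
      fwd <- .lkcnn_forward(par, Xb, dims, training = TRUE,
                            dropout_rate = dropout_rate)
      ep_loss <- ep_loss + cross_entropy_loss(fwd$prob, Yb)
      grad <- .lkcnn_backward(par, Xb, Yb, fwd, dims)
      upd <- .adam_update(par, grad, st, lr)
      par <- upd$par
      st <- upd$st
      nb <- nb + 1L
    }
    val_prob <- .lkcnn_predict_prob(par, x_val, dims)
    val_acc <- mean(max.col(val_prob, ties.method = "first") ==
                      as.integer(y_val))
    rec[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nb,
                            val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %d loss %.4f val_acc %.4f", ep, ep_loss / nb,
                      val_acc))
    }
    if (val_acc > best_acc) {  # strict: ties keep the earliest epoch
      best_acc <- val_acc
      best_par <- par
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > patience) break
    }
  }
  record <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  attr(record, "best_epoch") <- best_epoch
  structure(list(par = best_par, dims = dims, classes = classes,
                 config = list(kernel_size = kernel_size, lr = lr,
                               batch_size = batch_size, epochs = epochs,
                               patience = patience,
                               dropout_rate = dropout_rate, seed = seed),
                 record = record),
            class = "lkcnn")
}

.lkcnn_predict_prob <- function(par, x, dims, chunk = 512L) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, dims$n_classes)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out[idx, ] <- .lkcnn_forward(par, x[idx, , drop = FALSE], dims,
                                 training = FALSE)$prob
  }
  out
}

#' Predict regimes with a fitted LKCNN
#'
#' @param object an `lkcnn` fit.
#' @param x matrix of series with the training input length.
#' @param type `"class"` for hard labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return Factor of predicted classes, or a probability matrix with one
#'   row per series (rows sum to 1).
#' @export
predict.lkcnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$dims$input_length) {
    stop("input length ", ncol(x), " does not match the model's ",
         object$dims$input_length)
  }
  prob <- .lkcnn_predict_prob(object$par, x, object$dims)
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' Number of trainable parameters
#'
#' @param object an `lkcnn` fit.
#' @return Total count of weights and biases.
#' @export
n_parameters <- function(object) {
  sum(vapply(object$par, length, numeric(1)))
}

#' @export
print.lkcnn <- function(x, ...) {
  cat(sprintf("LKCNN classifier: k = %d, %d classes, %d parameters\n",
              x$config$kernel_size, length(x$classes), n_parameters(x)))
  cat(sprintf("trained %d epochs; best validation accuracy %.4f at epoch %d\n",
              nrow(x$record), max(x$record$val_accuracy),
              attr(x$record, "best_epoch")))
  invisible(x)
}

#' @export
summary.lkcnn <- function(object, ...) {
  d <- object$dims
  cat("Large-kernel 1-D CNN\n")
  cat(sprintf("  input: %d samples\n", d$input_length))
  cat(sprintf("  conv1: 16 filters, kernel %d, stride 2 -> %d | pool2 -> %d\n",
              d$k, d$L1, d$L2))
  cat(sprintf("  conv2: 32 filters, kernel %d, stride 2 -> %d | pool2 -> %d\n",
              d$k, d$L3, d$L4))
  cat(sprintf("  flatten %d -> dense 64 -> dense 32 -> %d classes\n",
              d$flat, d$n_classes))
  cat(sprintf("  parameters: %d\n", n_parameters(object)))
  cat(sprintf("  config: lr %g, batch %d, dropout %g, patience %d, seed %d\n",
              object$config$lr, object$config$batch_size,
              object$config$dropout_rate, object$config$patience,
              object$config$seed))
  invisible(object)
}

#' @export
plot.lkcnn <- function(x, ...) {
  rec <- x$record
  graphics::par(mfrow = c(1, 2))
  graphics::plot(rec$epoch, rec$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(rec$epoch, rec$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", ylim = c(0, 1), ...)
  graphics::abline(v = attr(rec, "best_epoch"), lty = 2)
  graphics::par(mfrow = c(1, 1))
}

# ---- dataset-level convenience and the kernel scan -------------------------

.dataset_splits <- function(dataset) {
  man <- dataset$manifest
  if (all(is.na(man$split))) stop("dataset has no splits; run split_dataset()")
  list(train = which(man$split == "train"),
       val = which(man$split == "val"),
       test = which(man$split == "test"))
}

#' Fit an LKCNN on a labeled dataset
#'
#' Convenience wrapper extracting the train/validation splits of a
#' [build_dataset()] manifest and fitting [lkcnn()] on the prepared series.
#'
#' @param dataset a split `ca_dataset`.
#' @param ... passed to [lkcnn()].
#' @return An `lkcnn` fit.
#' @export
fit_lkcnn <- function(dataset, ...) {
  sp <- .dataset_splits(dataset)
  man <- dataset$manifest
  lkcnn(dataset$series[sp$train, , drop = FALSE], man$class[sp$train],
        x_val = dataset$series[sp$val, , drop = FALSE],
        y_val = man$class[sp$val], classes = regime_levels(), ...)
}

#' Kernel-size scan
#'
#' Trains one LKCNN per (kernel size, seed) pair and evaluates test accuracy
#' under a protocol: `"noiseless"` tests on the V = Inf test split,
#' `"noisy"` on the test split restricted to `noisy_levels`.
#'
#' @param dataset a split `ca_dataset`.
#' @param k_values integer kernel sizes.
#' @param seeds integer training seeds (the same set for every k).
#' @param protocol `"noiseless"` or `"noisy"`.
#' @param noisy_levels system sizes forming the noisy test set
#'   (default `c(1e6, 1e5)`).
#' @param ... passed to [lkcnn()].
#' @return Data frame with one row per (k, seed) and accuracy, plus a
#'   `summary` attribute with mean and sd per k.
#' @export
kernel_scan <- function(dataset, k_values, seeds, protocol = c("noiseless",
                                                               "noisy"),
                        noisy_levels = c(1e6, 1e5), ...) {
  protocol <- match.arg(protocol)
  sp <- .dataset_splits(dataset)
  man <- dataset$manifest
  test_idx <- sp$test
  test_idx <- if (protocol == "noiseless") {
    test_idx[is.infinite(man$V[test_idx])]
  } else {
    test_idx[man$V[test_idx] %in% noisy_levels]
  }
  if (length(test_idx) == 0) stop("empty test set under this protocol")
  rows <- list()
  for (k in k_values) {
    for (s in seeds) {
      fit <- fit_lkcnn(dataset, kernel_size = k, seed = s, ...)
      pred <- predict(fit, dataset$series[test_idx, , drop = FALSE])
      acc <- mean(as.character(pred) == man$class[test_idx])
      rows[[length(rows) + 1]] <- data.frame(k = k, seed = s,
                                             accuracy = acc)
    }
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$k), function(d) {
    data.frame(k = d$k[1], mean_accuracy = mean(d$accuracy),
               sd_accuracy = stats::sd(d$accuracy))
  }))
  attr(out, "summary") <- smry[order(smry$k), ]
  out
}
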