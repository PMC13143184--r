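# Conventional baselines on FFT features (linear-kernel SVM, random forest)
# and the impulsive-noise robustness experiment.

#' FFT magnitude features
#'
#' Magnitudes of the first `n_bins` non-negative-frequency bins of the
#' discrete Fourier transform (DC included), compressed with log(1 + .).
#' A fixed-length spectral signature of dominant frequency content and
#' harmonic structure for conventional classifiers.
#'
#' @param series numeric vector (one trajectory) or matrix (rows).
#' @param n_bins number of bins kept (default 128).
#' @return Feature vector, or matrix with one row per series.
#' @export
fft_features <- function(series, n_bins = 128) {
  if (is.matrix(series)) {
    out <- t(apply(series, 1, fft_features, n_bins = n_bins))
    colnames(out) <- paste0("f", seq_len(n_bins) - 1)
    return(out)
  }
  v <- as.numeric(series)
  if (any(!is.finite(v))) stop("non-finite values in series")
  if (length(v) < n_bins) stop("series shorter than n_bins")
  sp <- Mod(stats::fft(v))[seq_len(n_bins)]
  log1p(sp)
}

#' Fit a conventional baseline classifier
#'
#' A maximum-margin linear support vector machine (`e1071::svm`, linear
#' kernel) or a bagged decision-tree ensemble
#' (`randomForest::randomForest`, 500 trees) on fixed-length feature
#' vectors. Hyperparameters stay at widely accepted defaults.
#'
#' @param kind `"linear_svm"` or `"random_forest"`.
#' @param features numeric feature matrix (rows = samples).
#' @param labels class labels, one per row; at least 2 classes.
#' @param seed RNG seed (tree bootstraps; SVM fitting is deterministic).
#' @param ... passed to the underlying fitter.
#' @return A `ca_baseline`: list with the fitted model, `kind` and class
#'   levels; supports `predict`.
#' @export
fit_baseline <- function(kind = c("linear_svm", "random_forest"), features,
                         labels, seed = 1, ...) {
  kind <- match.arg(kind)
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  features <- as.matrix(features)
  set.seed(seed)
  model <- switch(kind,
    linear_svm = e1071::svm(features, y, kernel = "linear", scale = TRUE,
                            ...),
    random_forest = randomForest::randomForest(features, y, ntree = 500,
                                               ...))
  structure(list(model = model, kind = kind, classes = levels(y),
                 seed = seed),
            class = "ca_baseline")
}

#' @export
predict.ca_baseline <- function(object, x, ...) {
  stats::predict(object$model, as.matrix(x))
}

#' @export
print.ca_baseline <- function(x, ...) {
  cat(sprintf("baseline classifier: %s, %d classes\n", x$kind,
              length(x$classes)))
  invisible(x)
}

#' Corrupt a series with sparse large-amplitude impulses
#'
#' Adds spikes at `round(density * length)` distinct random positions; each
#' spike magnitude is drawn uniformly from `amp_range` times the series'
#' amplitude range, with sign per `sign`. All other positions are
#' bit-identical to the input. Emulates outlier artifacts of fluorescence
#' imaging.
#'
#' @param series numeric vector or matrix (rows corrupted independently).
#' @param density fraction of positions corrupted, in (0, 1\].
#' @param amp_range length-2 range of spike magnitudes in units of the
#'   series range (default `c(2, 5)`).
#' @param sign `"positive"`, `"negative"` or `"both"`.
#' @param seed RNG seed.
#' @return Corrupted copy of `series`.
#' @export
corrupt_with_impulses <- function(series, density = 0.01,
                                  amp_range = c(2, 5),
                                  sign = c("positive", "negative", "both"),
                                  seed = 1) {
  sign <- match.arg(sign)
  if (density <= 0) stop("density must be positive when corruption is requested")
  set.seed(seed)
  corrupt_one <- function(v) {
    n <- length(v)
    k <- max(1L, round(density * n))
    pos <- sample.int(n, k)
    rng <- max(v) - min(v)
    mag <- stats::runif(k, amp_range[1], amp_range[2]) * rng
    s <- switch(sign, positive = 1, negative = -1,
                both = base::sample(c(-1, 1), k, replace = TRUE))
    v[pos] <- v[pos] + s * mag
    v
  }
  if (is.matrix(series)) {
    t(apply(series, 1, corrupt_one))
  } else {
    corrupt_one(series)
  }
}

#' Impulsive-noise robustness experiment
#'
#' Evaluates each model on an uncorrupted test set and on an
#' impulse-corrupted copy, and reports the accuracy drop (percentage
#' points). The LKCNN consumes the corrupted series directly; FFT-feature
#' baselines re-extract features from the corrupted series.
#'
#' @param models named list of fitted classifiers (`lkcnn` and/or
#'   `ca_baseline`).
#' @param series test series matrix.
#' @param truth true labels for `series`.
#' @param density,amp_range,sign,seed corruption settings; see
#'   [corrupt_with_impulses()].
#' @param n_bins FFT feature length for baselines.
#' @return Data frame: `model`, `accuracy` (uncorrupted, %),
#'   `accuracy_corrupted` (%), `drop` (percentage points).
#' @export
robustness_experiment <- function(models, series, truth, density = 0.01,
                                  amp_range = c(2, 5), sign = "positive",
                                  seed = 1, n_bins = 128) {
  truth <- as.character(truth)
  # a zero-spike request is the identity corruption: every drop is exactly 0
  corrupted <- if (density > 0) {
    corrupt_with_impulses(series, density = density, amp_range = amp_range,
                          sign = sign, seed = seed)
  } else {
    series
  }
  eval_model <- function(model, x) {
    inp <- if (inherits(model, "ca_baseline")) fft_features(x, n_bins) else x
    mean(as.character(predict(model, inp)) == truth)
  }
  rows <- lapply(names(models), function(nm) {
    a0 <- 100 * eval_model(models[[nm]], series)
    a1 <- 100 * eval_model(models[[nm]], corrupted)
    data.frame(model = nm, accuracy = a0, accuracy_corrupted = a1,
               drop = a0 - a1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
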