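# Classification metrics: confusion matrices, micro accuracy, per-class
# precision/recall/F1, macro diagonal average, cumulative-noise curves, and
# the cycle-to-cycle amplitude-variability analysis of period-2 errors.

#' Confusion matrix
#'
#' Counts with rows = true labels and columns = predicted labels, in a fixed
#' label order.
#'
#' @param truth,predicted equal-length label vectors.
#' @param labels label ordering; defaults to [regime_levels()] when all
#'   labels belong to it, else the sorted union.
#' @return A `ca_confusion`: integer matrix of counts with class
#'   `ca_confusion`.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (is.null(labels)) {
    labels <- if (all(c(truth, predicted) %in% regime_levels())) {
      regime_levels()
    } else {
      sort(unique(c(truth, predicted)))
    }
  }
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = labels),
              factor(predicted, levels = labels))
  out <- matrix(as.integer(cm), nrow = length(labels),
                dimnames = list(true = labels, predicted = labels))
  structure(out, class = c("ca_confusion", "matrix"))
}

#' @export
print.ca_confusion <- function(x, percent = FALSE, ...) {
  if (percent) {
    print(round(row_percentages(x), 1))
  } else {
    print(unclass(x))
  }
  invisible(x)
}

#' Row-normalized percentage view
#'
#' @param cm a [confusion_matrix()].
#' @return Matrix of row percentages (each row sums to 100; all-zero rows
#'   stay zero).
#' @export
row_percentages <- function(cm) {
  rs <- rowSums(cm)
  out <- 100 * sweep(unclass(cm), 1, pmax(rs, 1), "/")
  out[rs == 0, ] <- 0
  out
}

#' Overall (micro) classification accuracy
#'
#' Fraction of samples whose predicted label exactly matches the true label:
#' sum_i N_iC / (sum_i N_iC + sum_i N_iM).
#'
#' @param cm a [confusion_matrix()].
#' @return Accuracy in \[0, 1\].
#' @export
accuracy_micro <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(unclass(cm))) / total
}

#' Macro average of per-class diagonal percentages
#'
#' Mean of the row-normalized confusion-matrix diagonal (per-class
#' accuracies). Coincides with [accuracy_micro()] exactly on class-balanced
#' test sets; the two are reported side by side because both conventions
#' appear as an "overall" figure.
#'
#' @param cm a [confusion_matrix()].
#' @return Mean per-class accuracy in \[0, 1\] over classes with at least
#'   one true sample.
#' @export
accuracy_macro <- function(cm) {
  rs <- rowSums(cm)
  keep <- rs > 0
  if (!any(keep)) stop("empty confusion matrix")
  mean(diag(unclass(cm))[keep] / rs[keep])
}

#' Per-class precision, recall and F1
#'
#' precision_i = N_iC / (N_iC + N_iFP), recall_i = N_iC / (N_iC + N_iM),
#' F1_i = 2 P R / (P + R), where N_iC are the diagonal counts, N_iM the
#' off-diagonal row sums (false negatives) and N_iFP the off-diagonal
#' column sums (false positives). Zero denominators yield `NA` (undefined),
#' never a silent 0.
#'
#' @param cm a [confusion_matrix()].
#' @return Data frame with one row per class: `class`, `precision`,
#'   `recall`, `f1`, plus attributes `micro_accuracy` and `macro_diag`.
#' @export
class_metrics <- function(cm) {
  m <- unclass(cm)
  nc <- diag(m)
  fp <- colSums(m) - nc
  fn <- rowSums(m) - nc
  precision <- ifelse(nc + fp > 0, nc / (nc + fp), NA_real_)
  recall <- ifelse(nc + fn > 0, nc / (nc + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  out <- data.frame(class = rownames(m), precision = precision,
                    recall = recall, f1 = f1, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "micro_accuracy") <- accuracy_micro(cm)
  attr(out, "macro_diag") <- accuracy_macro(cm)
  out
}

#' F1 score from precision and recall
#'
#' Harmonic mean 2PR/(P + R); `NA` when both are zero or either is `NA`.
#'
#' @param precision,recall values in \[0, 1\].
#' @return F1 in \[0, 1\] (vectorized).
#' @export
f1_score <- function(precision, recall) {
  ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Accuracy versus cumulative noise level
#'
#' Evaluates a trained model on nested test sets: the set at level V
#' contains all test trajectories with noise up to that level (every system
#' size from Inf down to V, inclusive), mimicking deployment on a broadening
#' mix of conditions.
#'
#' @param model an `lkcnn` fit (or any object with a matching `predict`
#'   method returning class labels).
#' @param dataset a split `ca_dataset` whose test split spans the levels.
#' @param levels system sizes in decreasing order (Inf first); default the
#'   dataset's levels sorted decreasingly.
#' @return Data frame: `V`, `n` (cumulative test-set size), `accuracy`.
#' @export
cumulative_noise_curve <- function(model, dataset, levels = NULL) {
  sp <- .dataset_splits(dataset)
  man <- dataset$manifest
  if (is.null(levels)) levels <- sort(unique(man$V), decreasing = TRUE)
  missing_lv <- setdiff(levels, unique(man$V[sp$test]))
  if (length(missing_lv)) {
    stop("test split has no trajectories at level(s): ",
         paste(missing_lv, collapse = ", "))
  }
  rows <- lapply(seq_along(levels), function(i) {
    lv <- levels[seq_len(i)]
    idx <- sp$test[man$V[sp$test] %in% lv]
    pred <- predict(model, dataset$series[idx, , drop = FALSE])
    data.frame(V = levels[i], n = length(idx),
               accuracy = mean(as.character(pred) == man$class[idx]))
  })
  do.call(rbind, rows)
}

#' Cycle-to-cycle amplitude variability of period-2 trajectories
#'
#' For each period-2-labeled trajectory, consecutive peak pairs form one
#' cycle; the per-cycle larger ("local maximum") and smaller ("local
#' minimum") peak amplitudes are collected, and their standard deviations
#' across cycles, normalized by the trajectory's full amplitude range, are
#' paired with whether the model misclassified it. A strict alternation has
#' near-zero variability on both axes; high variability marks the
#' trajectories whose alternating amplitude pattern is least regular over
#' the finite window.
#'
#' @param series matrix of prepared trajectories (rows), labeled period-2.
#' @param predicted predicted labels for the same rows.
#' @param min_peaks trajectories with fewer peaks are excluded (warning).
#' @return Data frame: `row`, `min_variability`, `max_variability`,
#'   `misclassified`.
#' @export
amplitude_variability <- function(series, predicted, min_peaks = 4) {
  predicted <- as.character(predicted)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(series))) {
    v <- series[i, ]
    traj <- data.frame(time = seq_along(v), x = v)
    pk <- extract_peaks(traj)
    if (length(pk$amplitudes) < min_peaks ||
        length(pk$troughs) < min_peaks - 1) {
      skipped <- skipped + 1L
      next
    }
    rng <- max(v) - min(v)
    a <- pk$amplitudes
    n_cyc <- length(a) %/% 2
    a <- a[seq_len(2 * n_cyc)]
    odd <- a[seq(1, 2 * n_cyc, 2)]
    even <- a[seq(2, 2 * n_cyc, 2)]
    rows[[length(rows) + 1]] <- data.frame(
      row = i,
      min_variability = stats::sd(pmin(odd, even)) / rng,
      max_variability = stats::sd(pmax(odd, even)) / rng,
      misclassified = predicted[i] != "period2")
  }
  if (skipped > 0) {
    warning(skipped, " trajectories excluded (fewer than ", min_peaks,
            " peaks)")
  }
  do.call(rbind, rows)
}

#' Confusion-matrix heatmap
#'
#' @param cm a [confusion_matrix()].
#' @param main plot title.
#' @return Invisibly, the row-percentage matrix plotted.
#' @export
plot_confusion <- function(cm, main = "confusion matrix (%)") {
  pm <- row_percentages(cm)
  n <- nrow(pm)
  graphics::image(seq_len(n), seq_len(n), t(pm[n:1, ]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = main)
  graphics::axis(1, at = seq_len(n), labels = colnames(pm), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(pm)), las = 2,
                 cex.axis = 0.7)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    graphics::text(j, n + 1 - i, sprintf("%.1f", pm[i, j]), cex = 0.6)
  }
  invisible(pm)
}
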