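# Reproduction driver: wires data generation, training, baselines and the
# robustness experiment into one seeded benchmark suite, plus a small
# per-experiment front end.

#' Run the full desk-scale benchmark suite
#'
#' One seeded end-to-end pass over the study design: build a balanced
#' 8-class dataset across the standard system-size levels, split it
#' stratified by (class, level), train the kernel-28 LKCNN with early
#' stopping, fit the FFT-feature linear SVM and random forest on the same
#' training split, and evaluate everything on the held-out test split —
#' noiseless subset, combined multi-level set, cumulative-noise curve, and
#' the impulsive-corruption robustness table.
#'
#' Desk-scale defaults (documented in the methods vignette) keep the suite
#' tractable on one CPU: 100 parameter points per class (70 train / 12
#' validation / 18 test per level), Euler-Maruyama step 1e-4 min, at most
#' 200 training epochs with patience 30.
#'
#' @param seed master seed driving data generation, splits, training and
#'   corruption.
#' @param levels system sizes (default `c(Inf, 1e8, 1e7, 1e6, 1e5)`).
#' @param n_per_class parameter points per class per level.
#' @param split_fractions train/val/test fractions.
#' @param kernel_size LKCNN temporal receptive field (default 28).
#' @param epochs,patience training schedule.
#' @param dt Euler-Maruyama step (min).
#' @param impulse_density,impulse_amp impulsive-corruption settings.
#' @param verbose print progress.
#' @return A `ca_benchmark` list: `dataset`, `model`, `baselines`,
#'   `metrics` (named numeric vector of the headline percentages),
#'   `confusions`, `robustness` (data frame), `cumulative` (data frame).
#' @export
benchmark_suite <- function(seed = 1, levels = c(Inf, 1e8, 1e7, 1e6, 1e5),
                            n_per_class = 100,
                            split_fractions = c(70, 12, 18) / 100,
                            kernel_size = 28, epochs = 200, patience = 30,
                            dt = 1e-4, impulse_density = 0.01,
                            impulse_amp = c(2, 5), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (n_per_class > 300 || epochs > 600) {
    message("configuration exceeds the desk-scale budget ",
            "(full-scale runs take hours to days on one CPU)")
  }
  say("building dataset (%d/class x %d levels)...", n_per_class,
      length(levels))
  ds <- build_dataset(levels = levels, n_per_class = n_per_class,
                      seed = seed, dt = dt)
  ds <- split_dataset(ds, split_fractions, seed = seed)
  sp <- .dataset_splits(ds)
  man <- ds$manifest
  say("training LKCNN (k = %d)...", kernel_size)
  model <- fit_lkcnn(ds, kernel_size = kernel_size, epochs = epochs,
                     patience = patience, seed = seed)
  say("fitting baselines...")
  feats_train <- fft_features(ds$series[sp$train, , drop = FALSE])
  svm_fit <- fit_baseline("linear_svm", feats_train, man$class[sp$train],
                          seed = seed)
  rf_fit <- fit_baseline("random_forest", feats_train, man$class[sp$train],
                         seed = seed)

  test_all <- sp$test
  test_noiseless <- test_all[is.infinite(man$V[test_all])]
  eval_on <- function(model, idx, fft = FALSE) {
    x <- ds$series[idx, , drop = FALSE]
    if (fft) x <- fft_features(x)
    confusion_matrix(man$class[idx], as.character(predict(model, x)))
  }
  cm_noiseless <- eval_on(model, test_noiseless)
  cm_all <- eval_on(model, test_all)
  cm_rf_noiseless <- eval_on(rf_fit, test_noiseless, fft = TRUE)
  cm_svm_noiseless <- eval_on(svm_fit, test_noiseless, fft = TRUE)
  cm_rf_all <- eval_on(rf_fit, test_all, fft = TRUE)
  cm_svm_all <- eval_on(svm_fit, test_all, fft = TRUE)

  say("robustness experiment...")
  rob <- robustness_experiment(
    list(lkcnn = model, random_forest = rf_fit, linear_svm = svm_fit),
    ds$series[test_noiseless, , drop = FALSE], man$class[test_noiseless],
    density = impulse_density, amp_range = impulse_amp, seed = seed)

  cum <- cumulative_noise_curve(model, ds)

  metrics <- c(
    lkcnn_noiseless_micro = 100 * accuracy_micro(cm_noiseless),
    lkcnn_noiseless_macro = 100 * accuracy_macro(cm_noiseless),
    lkcnn_noisy_micro = 100 * accuracy_micro(cm_all),
    lkcnn_noisy_macro = 100 * accuracy_macro(cm_all),
    rf_noiseless = 100 * accuracy_micro(cm_rf_noiseless),
    svm_noiseless = 100 * accuracy_micro(cm_svm_noiseless),
    rf_noisy = 100 * accuracy_micro(cm_rf_all),
    svm_noisy = 100 * accuracy_micro(cm_svm_all),
    lkcnn_drop = rob$drop[rob$model == "lkcnn"],
    rf_drop = rob$drop[rob$model == "random_forest"],
    svm_drop = rob$drop[rob$model == "linear_svm"])

  structure(list(dataset = ds, model = model,
                 baselines = list(linear_svm = svm_fit,
                                  random_forest = rf_fit),
                 metrics = metrics,
                 confusions = list(noiseless = cm_noiseless, all = cm_all,
                                   rf_noiseless = cm_rf_noiseless,
                                   svm_noiseless = cm_svm_noiseless,
                                   rf_all = cm_rf_all,
                                   svm_all = cm_svm_all),
                 robustness = rob, cumulative = cum, seed = seed),
            class = "ca_benchmark")
}

#' @export
print.ca_benchmark <- function(x, ...) {
  cat("desk-scale benchmark suite (seed", x$seed, ")\n")
  print(round(x$metrics, 2))
  invisible(x)
}

#' Run a single named experiment
#'
#' Front end over [benchmark_suite()] and the scan/curve helpers, emitting
#' metric tables (and a config snapshot) to an output directory.
#'
#' @param experiment one of `"noiseless_eval"`, `"noisy_eval"`,
#'   `"baselines"`, `"robustness"`, `"cumulative_curve"`, `"kernel_scan"`.
#' @param seed master seed.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param suite an existing `ca_benchmark` to reuse (avoids regenerating
#'   data and retraining); built on demand when `NULL`.
#' @param k_values,scan_seeds kernel-scan settings.
#' @param ... passed to [benchmark_suite()] when a suite must be built.
#' @return The experiment's result table(s), invisibly when written.
#' @export
run_experiment <- function(experiment = c("noiseless_eval", "noisy_eval",
                                          "baselines", "robustness",
                                          "cumulative_curve",
                                          "kernel_scan"),
                           seed = 1, out_dir = NULL, suite = NULL,
                           k_values = c(8, 28, 80), scan_seeds = 1:3, ...) {
  experiment <- match.arg(experiment)
  if (is.null(suite) && experiment != "kernel_scan") {
    suite <- benchmark_suite(seed = seed, ...)
  }
  out <- switch(experiment,
    noiseless_eval = list(
      metrics = class_metrics(suite$confusions$noiseless),
      confusion = suite$confusions$noiseless),
    noisy_eval = list(
      metrics = class_metrics(suite$confusions$all),
      confusion = suite$confusions$all),
    baselines = list(table = data.frame(
      model = c("random_forest", "linear_svm"),
      noiseless = suite$metrics[c("rf_noiseless", "svm_noiseless")],
      noisy = suite$metrics[c("rf_noisy", "svm_noisy")])),
    robustness = list(table = suite$robustness),
    cumulative_curve = list(table = suite$cumulative),
    kernel_scan = {
      if (is.null(suite)) suite <- benchmark_suite(seed = seed, ...)
      list(table = kernel_scan(suite$dataset, k_values, scan_seeds,
                               protocol = "noisy"))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      obj <- out[[nm]]
      if (is.data.frame(obj)) {
        utils::write.csv(obj, file.path(out_dir,
                                        paste0(experiment, "_", nm, ".csv")),
                         row.names = FALSE)
      } else if (inherits(obj, "ca_confusion")) {
        utils::write.csv(as.data.frame(unclass(obj)),
                         file.path(out_dir,
                                   paste0(experiment, "_", nm, ".csv")))
      }
    }
    jsonlite::write_json(list(experiment = experiment, seed = seed,
                              timestamp = format(Sys.time())),
                         file.path(out_dir,
                                   paste0(experiment, "_config.json")),
                         auto_unbox = TRUE)
  }
  out
}
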