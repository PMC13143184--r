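# Labeled synthetic datasets over the canonical parameter regions and
# system-size (noise) levels.

# regions admissible for each class, in round-robin preference order
.class_regions <- function(label) {
  switch(label,
         steady_state = c("region1", "region2", "region3"),
         oscillatory = c("region1", "region2", "region3"),
         bursting = "region1",
         period2 = "region2", period3 = "region2", period4 = "region2",
         chaotic = "region2",
         quasiperiodic = "region3",
         stop("unknown regime label: ", label))
}

#' Create a label cache for parameter sampling
#'
#' A shared cache of labeled (beta, eps) points per region. Every labeler
#' call made while searching for one regime also seeds the pools of the
#' regimes it happened to find, so a dataset build labels each parameter
#' point at most once.
#'
#' @return An environment used by [sample_region_parameters()] and
#'   [build_dataset()].
#' @export
new_label_cache <- function() {
  e <- new.env(parent = emptyenv())
  for (r in names(.region_ranges)) {
    e[[r]] <- data.frame(beta = numeric(0), eps = numeric(0),
                         label = character(0), used = logical(0),
                         stringsAsFactors = FALSE)
  }
  e
}

.label_point <- function(region, beta, eps, label_args) {
  p <- ca_params(beta = beta, eps = eps, region = region)
  out <- tryCatch(do.call(label_regime, c(list(params = p), label_args)),
                  error = function(e) list(label = "undetermined"))
  out$label
}

#' Sample parameters that realize a target regime
#'
#' Draws (beta, eps) from the region's printed ranges and keeps points whose
#' deterministic dynamics the labeler assigns to `target_label` (rejection
#' sampling). Regimes occupying thin parameter slivers (period-3/4, chaos)
#' are additionally searched with local Gaussian proposals around previously
#' accepted points; every proposal is still verified by the labeler, so
#' accepted points are never unlabeled extrapolations.
#'
#' @param region `"region1"`, `"region2"` or `"region3"`.
#' @param target_label one of [regime_levels()]; must be admissible for the
#'   region.
#' @param n number of parameter points wanted.
#' @param cache a [new_label_cache()]; pass one cache across calls to share
#'   labeling work.
#' @param max_labelings labeler-call budget before giving up.
#' @param label_args list of overrides passed to [label_regime()].
#' @return List of `ca_params` objects of length `n`. Consumes R's RNG
#'   stream (seed with `set.seed` for reproducibility).
#' @export
sample_region_parameters <- function(region, target_label, n = 1,
                                     cache = new_label_cache(),
                                     max_labelings = 4000,
                                     label_args = list()) {
  region <- match.arg(region, names(.region_ranges))
  if (!target_label %in% .region_classes[[region]]) {
    stop("regime '", target_label, "' is not admissible for ", region)
  }
  rr <- .region_ranges[[region]]
  span_b <- diff(rr$beta)
  span_e <- diff(rr$eps)
  pool <- cache[[region]]
  spent <- 0L
  take <- function(pool) which(pool$label == target_label & !pool$used)
  while (length(take(pool)) < n) {
    if (spent >= max_labelings) {
      stop(sprintf(
        "rejection budget (%d labelings) exhausted for %s / %s",
        max_labelings, region, target_label))
    }
    hits <- which(pool$label == target_label)
    local_ok <- length(hits) >= 1
    use_local <- local_ok && stats::runif(1) < 0.7
    if (use_local) {
      anchor <- pool[sample(hits, 1), ]
      beta <- min(max(anchor$beta + stats::rnorm(1, 0, 0.02 * span_b),
                      rr$beta[1]), rr$beta[2])
      eps <- min(max(anchor$eps + stats::rnorm(1, 0, 0.02 * span_e),
                     rr$eps[1]), rr$eps[2])
    } else {
      beta <- stats::runif(1, rr$beta[1], rr$beta[2])
      eps <- stats::runif(1, rr$eps[1], rr$eps[2])
    }
    lab <- .label_point(region, beta, eps, label_args)
    spent <- spent + 1L
    pool <- rbind(pool, data.frame(beta = beta, eps = eps, label = lab,
                                   used = FALSE, stringsAsFactors = FALSE))
  }
  idx <- take(pool)[seq_len(n)]
  pool$used[idx] <- TRUE
  cache[[region]] <- pool
  lapply(idx, function(i) {
    ca_params(beta = pool$beta[i], eps = pool$eps[i], region = region)
  })
}

#' Normalize a trajectory to the classifier's input form
#'
#' Linear interpolation of the cytosolic Ca2+ series onto `n_points`
#' uniformly spaced times over its span, then per-trajectory min-max
#' normalization to \[0, 1\]. A constant series maps to all zeros.
#'
#' @param traj a `ca_trajectory`, or a numeric vector already on a uniform
#'   grid.
#' @param n_points output length (default 1000).
#' @return Numeric vector of length `n_points` in \[0, 1\].
#' @export
prepare_input <- function(traj, n_points = 1000) {
  if (inherits(traj, "ca_trajectory") || is.data.frame(traj)) {
    tt <- traj$time
    v <- traj$x
  } else {
    v <- as.numeric(traj)
    tt <- seq_along(v)
  }
  if (length(v) < 2) stop("need at least 2 samples")
  if (any(!is.finite(v))) stop("non-finite values in trajectory")
  out <- stats::approx(tt, v, xout = seq(tt[1], tt[length(tt)],
                                         length.out = n_points))$y
  rng <- max(out) - min(out)
  if (rng <= 0) return(rep(0, n_points))
  (out - min(out)) / rng
}

#' Build a labeled multi-noise-level dataset
#'
#' For every regime class, samples `n_per_class` parameter points from the
#' class's admissible regions (round-robin when several regions produce it)
#' and simulates one trajectory per point at every system size in `levels`
#' (the deterministic path for `V = Inf`). A noisy trajectory inherits the
#' regime label of its noiseless twin at the same parameter point.
#'
#' @param levels numeric vector of system sizes, e.g.
#'   `c(Inf, 1e8, 1e7, 1e6, 1e5)`.
#' @param n_per_class trajectories per class per level.
#' @param seed master seed; the build is reproducible given
#'   (`levels`, `n_per_class`, `seed`).
#' @param classes regime classes to include (default all eight).
#' @param duration,burn_in,sample_interval simulation window (min).
#' @param dt Euler-Maruyama step for the noisy levels (min).
#' @param dt_det RK4 step for the deterministic level and labeling (min).
#' @param cache optional shared [new_label_cache()].
#' @param max_labelings labeler budget per (region, class) request.
#' @return A `ca_dataset`: list with `manifest` (data frame: `id`, `class`,
#'   `region`, `beta`, `eps`, `V`, `seed`, `split`) and `series` (matrix,
#'   one normalized 1000-point row per manifest entry).
#' @export
build_dataset <- function(levels, n_per_class, seed = 1,
                          classes = regime_levels(), duration = 120,
                          burn_in = 20, sample_interval = 0.1, dt = 1e-4,
                          dt_det = 1e-3, cache = new_label_cache(),
                          max_labelings = 4000) {
  stopifnot(n_per_class >= 1, length(levels) >= 1)
  set.seed(seed)
  label_args <- list(duration = duration, burn_in = burn_in, dt = dt_det)
  # sample parameter points per class, round-robin over admissible regions
  points <- list()
  for (cl in classes) {
    regs <- .class_regions(cl)
    quota <- diff(round(seq(0, n_per_class, length.out = length(regs) + 1)))
    ps <- list()
    for (k in seq_along(regs)) {
      if (quota[k] == 0) next
      ps <- c(ps, sample_region_parameters(regs[k], cl, quota[k],
                                           cache = cache,
                                           max_labelings = max_labelings,
                                           label_args = label_args))
    }
    points[[cl]] <- ps
  }
  n_points_out <- 1000L
  n_rows <- length(classes) * n_per_class * length(levels)
  series <- matrix(NA_real_, n_rows, n_points_out)
  man <- vector("list", n_rows)
  row <- 0L
  traj_seeds <- sample.int(.Machine$integer.max,
                           length(classes) * n_per_class * length(levels))
  sidx <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      p <- points[[cl]][[i]]
      init <- default_init(p)
      det_traj <- NULL
      for (V in levels) {
        row <- row + 1L
        sidx <- sidx + 1L
        tseed <- traj_seeds[sidx]
        if (is.infinite(V)) {
          if (is.null(det_traj)) {
            det_traj <- integrate_deterministic(
              p, init = init, duration = duration, dt = dt_det,
              sample_interval = sample_interval, record_from = burn_in)
          }
          traj <- det_traj
        } else {
          traj <- simulate_cle(p, V = V, init = init, duration = duration,
                               burn_in = burn_in, dt = dt,
                               sample_interval = sample_interval,
                               seed = tseed)
        }
        series[row, ] <- prepare_input(traj, n_points_out)
        man[[row]] <- data.frame(
          id = row, class = cl, region = attr(p, "region"),
          beta = unclass(p)[["beta"]], eps = unclass(p)[["eps"]], V = V,
          seed = if (is.infinite(V)) NA_integer_ else tseed,
          split = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, man)
  structure(list(manifest = manifest, series = series,
                 levels = levels, n_per_class = n_per_class, seed = seed),
            class = "ca_dataset")
}

#' @export
print.ca_dataset <- function(x, ...) {
  cat(sprintf("ca_dataset: %d trajectories (%d classes x %d/class x %d levels)\n",
              nrow(x$manifest), length(unique(x$manifest$class)),
              x$n_per_class, length(x$levels)))
  print(table(x$manifest$class, x$manifest$V))
  invisible(x)
}

#' Assign stratified train/validation/test splits
#'
#' Splits the manifest by (`class`, `V`) stratum so class balance holds
#' exactly within each level and split; disjoint and reproducible.
#'
#' @param dataset a `ca_dataset`.
#' @param fractions length-3 non-negative vector summing to 1 for
#'   train/val/test.
#' @param seed split seed.
#' @return The dataset with `manifest$split` filled in.
#' @export
split_dataset <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions >= 0))
  set.seed(seed)
  man <- dataset$manifest
  man$split <- NA_character_
  strata <- split(seq_len(nrow(man)), list(man$class, man$V), drop = TRUE)
  for (idx in strata) {
    m <- length(idx)
    n_tr <- round(fractions[1] * m)
    n_va <- round(fractions[2] * m)
    if (n_tr + n_va > m) n_va <- m - n_tr
    if (fractions[2] > 0 && n_va == 0 && m - n_tr > 0) n_va <- 1
    if (fractions[1] > 0 && n_tr == 0) {
      stop("a (class, V) stratum is too small to split")
    }
    perm <- sample(idx)
    man$split[perm[seq_len(n_tr)]] <- "train"
    if (n_va > 0) man$split[perm[n_tr + seq_len(n_va)]] <- "val"
    if (m - n_tr - n_va > 0) {
      man$split[perm[(n_tr + n_va + 1):m]] <- "test"
    }
  }
  dataset$manifest <- man
  dataset
}

#' Subset a dataset
#'
#' @param dataset a `ca_dataset`.
#' @param idx row indices or a logical vector over manifest rows.
#' @return A `ca_dataset` restricted to the selected entries.
#' @export
subset_dataset <- function(dataset, idx) {
  dataset$manifest <- dataset$manifest[idx, , drop = FALSE]
  dataset$series <- dataset$series[idx, , drop = FALSE]
  dataset
}

#' Write / read a dataset as plain-text files
#'
#' The manifest goes to `<stem>_manifest.json` and the series matrix to
#' `<stem>_series.csv` (one row per trajectory).
#'
#' @param dataset a `ca_dataset`.
#' @param stem output path stem.
#' @return `read_dataset` returns the `ca_dataset`; `write_dataset` the stem.
#' @export
write_dataset <- function(dataset, stem) {
  jsonlite::write_json(
    list(manifest = dataset$manifest, levels = dataset$levels,
         n_per_class = dataset$n_per_class, seed = dataset$seed),
    paste0(stem, "_manifest.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  utils::write.table(dataset$series, paste0(stem, "_series.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_manifest.json"),
                              simplifyVector = TRUE)
  man <- meta$manifest
  man$V[is.na(man$V)] <- Inf
  series <- as.matrix(utils::read.csv(paste0(stem, "_series.csv"),
                                      header = FALSE))
  dimnames(series) <- NULL
  structure(list(manifest = man, series = series,
                 levels = ifelse(is.na(meta$levels), Inf, meta$levels),
                 n_per_class = meta$n_per_class, seed = meta$seed),
            class = "ca_dataset")
}
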