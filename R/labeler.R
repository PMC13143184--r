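# Automatic ground-truth labeling of deterministic trajectories into the
# eight dynamical regimes. Noisy trajectories inherit the label of their
# noiseless twin (same parameters), on the premise that the deterministic
# organizational signature defines the regime.

#' Drop the transient head of a trajectory
#'
#' @param traj a `ca_trajectory`.
#' @param burn_in time (min) to discard from the start; must be shorter than
#'   the trajectory span.
#' @return The trailing sub-trajectory with provenance preserved.
#' @export
strip_transient <- function(traj, burn_in) {
  t0 <- traj$time[1]
  if (burn_in >= max(traj$time) - t0) {
    stop("burn_in must be shorter than the trajectory duration")
  }
  keep <- traj$time >= t0 + burn_in
  out <- traj[keep, , drop = FALSE]
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       attributes(traj)[c("class", "params", "V", "dt",
                                          "seed")])
  out
}

# indices of local maxima of v; plateaus take their first index
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  d <- diff(v)
  # collapse flat segments by carrying the last non-zero slope sign
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(diff(s) < 0) + 1L
}

# topographic prominence of peak at index i: height above the higher of the
# two basin minima, each basin bounded by the nearest strictly higher sample
# (or the signal edge)
.prominence <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1)]
    hi_l <- which(left > h)
    lmin <- if (length(hi_l)) min(v[(max(hi_l)):(i - 1)]) else
      if (i > 1) min(left) else h
    right <- v[(i + 1):length(v)]
    hi_r <- which(right > h)
    rmin <- if (length(hi_r)) min(v[(i + 1):(i + min(hi_r))]) else
      if (i < length(v)) min(right) else h
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Extract prominent peaks and troughs
#'
#' Local maxima with topographic prominence of at least `prominence_frac`
#' times the trajectory's amplitude range, and the minimum between each pair
#' of consecutive peaks.
#'
#' @param traj a `ca_trajectory` (or anything with `time` and `x` columns)
#'   of at least 3 samples.
#' @param prominence_frac minimum prominence as a fraction of the signal
#'   range (default 0.05).
#' @return A `peak_sequence`: list with `times`, `amplitudes` (peak heights,
#'   uM), `troughs` (inter-peak minima, length one less), and `intervals`
#'   (inter-peak times, min). Empty sequences are allowed.
#' @export
extract_peaks <- function(traj, prominence_frac = 0.05) {
  v <- traj$x
  tt <- traj$time
  stopifnot(length(v) >= 3)
  rng <- max(v) - min(v)
  idx <- .local_maxima(v)
  if (length(idx) && rng > 0) {
    prom <- .prominence(v, idx)
    idx <- idx[prom >= prominence_frac * rng]
  } else {
    idx <- integer(0)
  }
  troughs <- if (length(idx) >= 2) {
    vapply(seq_len(length(idx) - 1),
           function(k) min(v[idx[k]:idx[k + 1]]), numeric(1))
  } else {
    numeric(0)
  }
  # sub-sample refinement: a sharp spike's sampled height aliases with the
  # sampling grid, which would fake amplitude alternation; fit a parabola
  # through the three samples around each peak
  ref <- .refine_peaks(v, tt, idx)
  structure(list(times = ref$times, amplitudes = ref$amplitudes,
                 troughs = troughs, intervals = diff(ref$times)),
            class = "peak_sequence")
}

.refine_peaks <- function(v, tt, idx) {
  times <- tt[idx]
  amps <- v[idx]
  n <- length(v)
  inner <- which(idx > 1 & idx < n)
  for (k in inner) {
    i <- idx[k]
    y1 <- v[i - 1]; y2 <- v[i]; y3 <- v[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {  # strictly concave triple
      delta <- 0.5 * (y1 - y3) / den
      if (abs(delta) <= 1) {
        dt <- tt[i + 1] - tt[i]
        times[k] <- tt[i] + delta * dt
        amps[k] <- y2 - 0.25 * (y1 - y3) * delta
      }
    }
  }
  list(times = times, amplitudes = amps)
}

#' Periodicity order of a peak sequence
#'
#' Smallest q in 1..4 such that both the peak-amplitude and the inter-peak
#' interval sequences repeat with period q, within `rel_tol` of the
#' amplitude range (for amplitudes) or of the mean interval (for intervals);
#' `"aperiodic"` otherwise. Requires at least 8 peaks, else
#' `"undetermined"`.
#'
#' @param peaks a `peak_sequence` from [extract_peaks()].
#' @param rel_tol relative tolerance (default 0.05).
#' @param amp_range amplitude range used to scale the amplitude tolerance;
#'   defaults to the range of the peak/trough heights themselves.
#' @return One of `"1"`, `"2"`, `"3"`, `"4"`, `"aperiodic"`,
#'   `"undetermined"` (as character).
#' @export
classify_periodic_order <- function(peaks, rel_tol = 0.05,
                                    amp_range = NULL) {
  a <- peaks$amplitudes
  d <- peaks$intervals
  if (length(a) < 8) return("undetermined")
  if (is.null(amp_range)) {
    amp_range <- max(a) - min(c(a, peaks$troughs))
  }
  atol <- rel_tol * max(amp_range, 1e-12)
  dtol <- rel_tol * max(mean(d), 1e-12)
  periodic_q <- function(v, q, tol) {
    if (length(v) <= q) return(FALSE)
    all(abs(v[seq_len(length(v) - q)] - v[-seq_len(q)]) <= tol)
  }
  for (q in 1:4) {
    if (periodic_q(a, q, atol) && periodic_q(d, q, dtol)) {
      return(as.character(q))
    }
  }
  "aperiodic"
}

#' Detect bursting
#'
#' Bursting alternates active episodes (clusters of rapid spikes) with long
#' quiescent phases. Spikes are clustered by splitting the inter-spike
#' interval sequence at gaps at least `gap_factor` times the intra-burst
#' interval; the trajectory is called bursting when there are at least two
#' clusters of `min_spikes` spikes separated by such quiescent gaps.
#'
#' @param traj a transient-stripped `ca_trajectory`.
#' @param prominence_frac passed to [extract_peaks()].
#' @param gap_factor quiescent gaps must exceed this multiple of the
#'   intra-burst inter-spike interval (default 3).
#' @param min_spikes minimum spikes per burst (default 3).
#' @return List: `bursting` (logical), `plateau_fraction` (fraction of time
#'   in active phases), `silent_duration` (mean quiescent gap, min),
#'   `n_bursts`.
#' @export
detect_bursting <- function(traj, prominence_frac = 0.05, gap_factor = 3,
                            min_spikes = 3) {
  no <- list(bursting = FALSE, plateau_fraction = NA_real_,
             silent_duration = NA_real_, n_bursts = 0L)
  pk <- extract_peaks(traj, prominence_frac)
  if (length(pk$times) < 2 * min_spikes) return(no)
  isi <- pk$intervals
  # intra-burst scale: the lower part of the ISI distribution
  base <- stats::median(pmin(isi, stats::quantile(isi, 0.5)))
  gaps <- which(isi > gap_factor * base)
  if (length(gaps) < 1) return(no)
  bounds <- c(0, gaps, length(pk$times))
  sizes <- diff(bounds)
  if (sum(sizes >= min_spikes) < 2) return(no)
  # re-estimate the intra-burst interval from within-cluster ISIs only
  intra <- isi[-gaps]
  if (length(intra) == 0) return(no)
  intra_isi <- stats::median(intra)
  gap_durs <- isi[gaps]
  if (!all(gap_durs >= gap_factor * intra_isi)) return(no)
  span <- max(traj$time) - min(traj$time)
  list(bursting = TRUE,
       plateau_fraction = max(0, min(1, 1 - sum(gap_durs) / span)),
       silent_duration = mean(gap_durs),
       n_bursts = sum(sizes >= 1))
}

#' Largest Lyapunov exponent of the deterministic dynamics
#'
#' Benettin two-trajectory estimate: a reference orbit and a companion
#' displaced by `d0` are integrated side by side (RK4), the log separation
#' growth is accumulated and the companion renormalized back to distance
#' `d0` every `renorm_interval`.
#'
#' @param params a [ca_params()] record.
#' @param init initial state; default [default_init()].
#' @param dt RK4 step (min).
#' @param transient discarded lead-in (min).
#' @param horizon averaging time after the transient (min).
#' @param renorm_interval renormalization period (min).
#' @param d0 companion displacement (uM).
#' @return Estimated exponent (1/min): positive for expanding (chaotic)
#'   dynamics, near zero on a limit cycle or torus, negative toward a fixed
#'   point.
#' @export
largest_lyapunov <- function(params, init = NULL, dt = 1e-3, transient = 20,
                             horizon = 200, renorm_interval = 0.5,
                             d0 = 1e-8) {
  if (is.null(init)) init <- default_init(params)
  .benettin_lyap_cpp(.as_param_vec(params), as.numeric(init), dt, transient,
                     horizon, renorm_interval, d0)
}

# two incommensurate dominant frequencies in the spectrum?
.incommensurate_pair <- function(x, dt_sample, tol = 1e-2,
                                 min_rel_power = 0.05) {
  v <- x - mean(x)
  n <- length(v)
  sp <- Mod(stats::fft(v))[seq_len(floor(n / 2))]
  freq <- (seq_along(sp) - 1) / (n * dt_sample)
  sp[1] <- 0
  if (max(sp) <= 0) return(FALSE)
  idx <- .local_maxima(sp)
  idx <- idx[sp[idx] >= min_rel_power * max(sp)]
  if (length(idx) < 2) return(FALSE)
  idx <- idx[order(sp[idx], decreasing = TRUE)]
  f_dom <- freq[idx[1]]
  for (j in idx[-1]) {
    r <- max(freq[j], f_dom) / min(freq[j], f_dom)
    ratios <- outer(1:8, 1:8, "/")
    if (min(abs(r - ratios)) > tol) return(TRUE)
  }
  FALSE
}

#' Label the dynamical regime of a parameter point
#'
#' Runs the deterministic dynamics and applies a decision cascade:
#' steady state (post-burn-in amplitude range below `steady_band`), then
#' bursting, then periodicity order (1 is simple oscillatory, 2/3/4 the
#' multiple-periodicity classes), then chaos (largest Lyapunov exponent
#' above `chaos_threshold`) versus quasiperiodicity (near-neutral exponent
#' plus two incommensurate dominant spectral frequencies). Points the
#' cascade cannot resolve are returned as `"undetermined"` and should be
#' rejected, never force-labeled.
#'
#' @param params a [ca_params()] record.
#' @param init initial state; default [default_init()].
#' @param duration,burn_in,dt integration settings (min); the labeler
#'   samples densely (`sample_interval`) for reliable peak statistics.
#' @param sample_interval diagnostic sampling interval (min).
#' @param steady_band absolute amplitude band (uM) below which the
#'   trajectory is steady state.
#' @param prominence_frac,rel_tol peak prominence and periodicity
#'   tolerances (fractions of the amplitude range).
#' @param chaos_threshold Lyapunov threshold (1/min) for the chaotic label.
#' @return List: `label` (one of [regime_levels()] or `"undetermined"`),
#'   and diagnostics `amplitude_range`, `n_peaks`, `periodicity`,
#'   `lyapunov` (NA unless computed), `plateau_fraction`.
#' @export
label_regime <- function(params, init = NULL, duration = 120, burn_in = 20,
                         dt = 1e-3, sample_interval = 0.02,
                         steady_band = 0.02, prominence_frac = 0.05,
                         rel_tol = 0.05, chaos_threshold = 0.05) {
  if (is.null(init)) init <- default_init(params)
  traj <- integrate_deterministic(params, init = init, duration = duration,
                                  dt = dt,
                                  sample_interval = sample_interval,
                                  record_from = burn_in)
  rng <- max(traj$x) - min(traj$x)
  diag0 <- list(amplitude_range = rng, n_peaks = NA_integer_,
                periodicity = NA_character_, lyapunov = NA_real_,
                plateau_fraction = NA_real_)
  if (rng < steady_band) {
    return(c(list(label = "steady_state"), diag0))
  }
  bur <- detect_bursting(traj, prominence_frac)
  pk <- extract_peaks(traj, prominence_frac)
  diag0$n_peaks <- length(pk$times)
  diag0$plateau_fraction <- bur$plateau_fraction
  if (bur$bursting) {
    return(c(list(label = "bursting"), diag0))
  }
  per <- classify_periodic_order(pk, rel_tol, amp_range = rng)
  diag0$periodicity <- per
  if (per %in% c("1", "2", "3", "4")) {
    lab <- switch(per, "1" = "oscillatory", "2" = "period2",
                  "3" = "period3", "4" = "period4")
    return(c(list(label = lab), diag0))
  }
  if (per == "undetermined") {
    return(c(list(label = "undetermined"), diag0))
  }
  lam <- largest_lyapunov(params, init = init, dt = dt)
  diag0$lyapunov <- lam
  if (lam > chaos_threshold) {
    return(c(list(label = "chaotic"), diag0))
  }
  if (.incommensurate_pair(traj$x, sample_interval)) {
    return(c(list(label = "quasiperiodic"), diag0))
  }
  c(list(label = "undetermined"), diag0)
}

#' Tabular label report for a set of parameter points
#'
#' Runs [label_regime()] on each parameter record and collects parameters,
#' label and diagnostics into one data frame (optionally written as CSV).
#'
#' @param params_list list of [ca_params()] records.
#' @param path optional CSV output path.
#' @param ... passed to [label_regime()].
#' @return Data frame: `region`, `beta`, `eps`, `label`, `amplitude_range`,
#'   `n_peaks`, `periodicity`, `lyapunov`, `plateau_fraction`.
#' @export
label_report <- function(params_list, path = NULL, ...) {
  rows <- lapply(params_list, function(p) {
    out <- label_regime(p, ...)
    data.frame(region = attr(p, "region") %||% NA_character_,
               beta = unclass(p)[["beta"]], eps = unclass(p)[["eps"]],
               label = out$label, amplitude_range = out$amplitude_range,
               n_peaks = out$n_peaks, periodicity = out$periodicity,
               lyapunov = out$lyapunov,
               plateau_fraction = out$plateau_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Project the eight regimes onto the three experimental classes
#'
#' Experimental Ca2+ traces are curated into bursting, steady state and
#' "others"; every oscillatory/periodic/chaotic/quasiperiodic regime maps to
#' `"others"`.
#'
#' @param labels character vector of 8-class labels.
#' @return Factor with levels `bursting`, `steady_state`, `others`.
#' @export
project_3class <- function(labels) {
  out <- ifelse(labels %in% c("bursting", "steady_state"), labels, "others")
  factor(out, levels = c("bursting", "steady_state", "others"))
}
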