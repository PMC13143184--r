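# Synthetic signal fixtures (built in code) and shared slow objects.

# a spike train: one |sin| arch per cycle, cycle k scaled by amplitudes[k]
make_cycle_signal <- function(amplitudes, period = 2, dt = 0.01,
                              baseline = 0.1) {
  n_per <- round(period / dt)
  x <- unlist(lapply(amplitudes, function(a) {
    a * abs(sin(pi * seq(0, 1, length.out = n_per)))
  }))
  data.frame(time = seq_along(x) * dt, x = baseline + x)
}

# bursts of `spikes_per_burst` narrow spikes (isi apart), separated by
# silent gaps
make_burst_signal <- function(n_bursts = 6, spikes_per_burst = 4,
                              isi = 0.4, gap = 3, dt = 0.01,
                              spike_width = 0.1, amp = 1) {
  t_end <- n_bursts * (spikes_per_burst * isi + gap)
  tt <- seq(0, t_end, by = dt)
  x <- rep(0, length(tt))
  t0 <- 0.5
  for (b in seq_len(n_bursts)) {
    for (s in seq_len(spikes_per_burst)) {
      x <- x + amp * exp(-0.5 * ((tt - t0) / spike_width)^2)
      t0 <- t0 + isi
    }
    t0 <- t0 + gap - isi
  }
  data.frame(time = tt, x = x)
}

# canonical parameter points with known deterministic regimes (verified by
# the labeler's own diagnostics in test-labeler.R)
fixture_params <- function(which) {
  switch(which,
    steady = ca_params(beta = 0.65, eps = 5, region = "region1"),
    oscillatory = ca_params(beta = 0.42, eps = 1.5, region = "region1"),
    bursting = ca_params(beta = 0.30, eps = 3.0, region = "region1"),
    chaotic = ca_params(beta = 0.65, eps = 10, region = "region2"),
    steady3 = ca_params(beta = 0.0, eps = 2, region = "region3"),
    stop("unknown fixture"))
}

# one shared tiny split dataset for classifier-level unit tests (cheap:
# coarse CLE step, two levels); memoized across test files
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- build_dataset(levels = c(Inf, 1e5), n_per_class = 6, seed = 42,
                          dt = 1e-3)
      cache <<- split_dataset(ds, c(0.5, 0.25, 0.25), seed = 42)
    }
    cache
  }
})
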