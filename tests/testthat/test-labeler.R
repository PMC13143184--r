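# Regime labeling: transient stripping, peak extraction, periodicity order,
# burst detection, Lyapunov exponents, the full decision cascade.

test_that("strip_transient keeps the uniform tail", {
  tr <- data.frame(time = seq(0.1, 120, by = 0.1), x = 1)
  class(tr) <- c("ca_trajectory", "data.frame")
  out <- strip_transient(tr, 20)
  expect_equal(nrow(out), 1000)
  expect_true(all(out$time > 20))
  expect_equal(strip_transient(tr, 0)$x, tr$x)
  expect_error(strip_transient(tr, 200), "duration")
})

test_that("peak extraction recovers construction", {
  tt <- seq(0, 20, by = 0.01)
  sine <- data.frame(time = tt, x = sin(2 * pi * tt / 2))
  pk <- extract_peaks(sine)
  expect_equal(length(pk$times), 10)
  expect_true(all(abs(pk$intervals - 2) < 0.02))
  expect_true(all(abs(pk$amplitudes - 1) < 1e-3))

  flat <- data.frame(time = tt, x = rep(1, length(tt)))
  expect_length(extract_peaks(flat)$times, 0)

  abab <- make_cycle_signal(rep(c(1, 0.4), 10))
  pk2 <- extract_peaks(abab)
  expect_equal(length(pk2$times), 20)
  expect_true(all(abs(pk2$amplitudes[seq(1, 20, 2)] - 1.1) < 0.01))
  expect_true(all(abs(pk2$amplitudes[seq(2, 20, 2)] - 0.5) < 0.01))
  expect_true(all(pk2$amplitudes[-1] >= pk2$troughs))
})

test_that("periodicity order is the smallest repeating block", {
  order_of <- function(amps) {
    classify_periodic_order(extract_peaks(make_cycle_signal(amps)))
  }
  expect_equal(order_of(rep(1, 10)), "1")
  expect_equal(order_of(rep(c(1, 0.4), 8)), "2")
  expect_equal(order_of(rep(c(1, 0.6, 0.3), 6)), "3")
  expect_equal(order_of(rep(c(1, 0.7, 0.45, 0.2), 5)), "4")
  # logistic-map-driven amplitudes: chaotic, no period up to 4
  a <- numeric(16); a[1] <- 0.35
  for (i in 2:16) a[i] <- 3.99 * a[i - 1] * (1 - a[i - 1])
  expect_equal(order_of(0.2 + 0.8 * a), "aperiodic")
  # too few peaks
  expect_equal(classify_periodic_order(extract_peaks(
    make_cycle_signal(rep(1, 4)))), "undetermined")
})

test_that("burst detection separates bursts from tonic spiking", {
  expect_false(detect_bursting(
    data.frame(time = seq(0, 50, 0.01),
               x = sin(2 * pi * seq(0, 50, 0.01))))$bursting)
  expect_false(detect_bursting(
    data.frame(time = seq(0, 50, 0.01), x = rep(0.2, 5001)))$bursting)

  sig <- make_burst_signal(n_bursts = 6, spikes_per_burst = 4, isi = 0.4,
                           gap = 3)
  out <- detect_bursting(sig)
  expect_true(out$bursting)
  # active span per burst ~ 3 * isi out of (3 * isi + gap) per cycle
  expected_plateau <- 1 - 6 * (3 - 0.4) / max(sig$time)
  expect_equal(out$plateau_fraction, expected_plateau, tolerance = 0.15)
  expect_gt(out$silent_duration, 2)
})

test_that("Lyapunov exponents separate contraction, cycling and chaos", {
  expect_lt(largest_lyapunov(fixture_params("steady"), horizon = 50), 0)
  lam_osc <- largest_lyapunov(fixture_params("oscillatory"),
                              init = c(0.5, 1, 0.5), horizon = 100)
  expect_lt(abs(lam_osc), 0.02)
  lam_chaos <- largest_lyapunov(fixture_params("chaotic"),
                                init = c(0.5, 1, 0.5), horizon = 200)
  expect_gt(lam_chaos, 0.05)
})

test_that("the labeling cascade assigns the canonical regions", {
  expect_equal(label_regime(fixture_params("steady"))$label, "steady_state")
  expect_equal(label_regime(fixture_params("steady3"))$label,
               "steady_state")
  expect_equal(label_regime(fixture_params("oscillatory"),
                            init = c(0.5, 1, 0.5))$label, "oscillatory")
  expect_equal(label_regime(fixture_params("bursting"),
                            init = c(0.5, 1, 0.5))$label, "bursting")
  expect_equal(label_regime(fixture_params("chaotic"),
                            init = c(0.5, 1, 0.5))$label, "chaotic")
})

test_that("labeling is deterministic and scale-insensitive in its features", {
  p <- fixture_params("bursting")
  a <- label_regime(p, init = c(0.5, 1, 0.5))
  b <- label_regime(p, init = c(0.5, 1, 0.5))
  expect_identical(a$label, b$label)
  expect_identical(a$n_peaks, b$n_peaks)
  # periodicity order is invariant to uniform scaling and offset
  amps <- rep(c(1, 0.4), 8)
  s1 <- make_cycle_signal(amps)
  s2 <- s1; s2$x <- 5 + 3 * s1$x
  expect_equal(classify_periodic_order(extract_peaks(s1)),
               classify_periodic_order(extract_peaks(s2)))
})

test_that("the 3-class projection is total and maps periodics to others", {
  out <- project_3class(regime_levels())
  expect_equal(levels(out), c("bursting", "steady_state", "others"))
  expect_false(anyNA(out))
  expect_equal(as.character(out[regime_levels() == "period3"]), "others")
  expect_equal(as.character(out[regime_levels() == "bursting"]), "bursting")
  expect_equal(sum(out == "others"), 6)
})
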