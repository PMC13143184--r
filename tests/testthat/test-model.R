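# Rate laws, drift field, deterministic integration, fixed points.

r1 <- ca_params(beta = 0.5, eps = 5, region = "region1")

test_that("rate laws honor zeros, half-saturation points and bounds", {
  expect_equal(rate_V2(0, r1), 0)
  expect_equal(rate_V2(unclass(r1)[["k2"]], r1), unclass(r1)[["VM2"]] / 2)
  # hand evaluation: VM2 = 6, k2 = 0.1, x = 0.3 -> 6 * 0.09 / 0.10 = 5.4
  expect_equal(rate_V2(0.3, r1), 5.4)

  expect_equal(rate_V3(0.3, 0, 0.2, r1), 0)
  p <- unclass(r1)
  expect_equal(rate_V3(p[["kx"]], p[["ky"]], p[["kz"]], r1), p[["VM3"]] / 8)
  expect_lt(rate_V3(100, 100, 100, r1), p[["VM3"]])
  expect_gt(rate_V3(100, 100, 100, r1), 0.99 * p[["VM3"]])

  expect_equal(rate_V5(0.5, 0, r1), 0)
  expect_equal(rate_V5(1e6, p[["k5"]], r1), p[["VM5"]] / 2,
               tolerance = 1e-6)
  expect_equal(rate_V5(p[["kd"]], p[["k5"]], r1), p[["VM5"]] / 4)

  # monotone nondecreasing in substrate
  xs <- seq(0, 2, by = 0.05)
  expect_true(all(diff(rate_V2(xs, r1)) >= 0))
  expect_true(all(diff(rate_V5(xs, 0.3, r1)) >= 0))
  expect_error(rate_V2(-0.1, r1), "non-negative")
})

test_that("drift matches its algebraic structure", {
  # all Hill terms vanish at the origin
  expect_equal(unname(ca_drift(c(0, 0, 0), r1)),
               c(unclass(r1)[["V0"]] + unclass(r1)[["V1"]] * 0.5, 0,
                 0.5 * unclass(r1)[["V4"]]))
  # mass-exchange identity: xdot + ydot = V0 + V1 beta - k_out x
  set.seed(1)
  for (i in 1:100) {
    s <- runif(3, 0, 2)
    f <- ca_drift(s, r1)
    expect_equal(unname(f["x"] + f["y"]),
                 unclass(r1)[["V0"]] + unclass(r1)[["V1"]] * 0.5 -
                   unclass(r1)[["k_out"]] * s[1],
                 tolerance = 1e-12)
  }
})

test_that("steady-state location returns a non-negative root of the drift", {
  for (p in list(r1, fixture_params("steady3"),
                 ca_params(beta = 0.7, eps = 12, region = "region2"))) {
    ss <- find_steady_state(p)
    expect_true(all(ss >= 0))
    expect_lt(max(abs(ca_drift(ss, p))), 1e-10)
  }
  # low-Ca2+ resting state in the steady sub-range
  ss3 <- find_steady_state(fixture_params("steady3"))
  expect_lt(ss3["x"], 0.3)
})

test_that("deterministic integration is fixed-point-faithful and step-converged", {
  ss <- find_steady_state(r1)
  tr <- integrate_deterministic(r1, init = ss, duration = 10, dt = 1e-3)
  expect_lt(max(abs(tr$x - ss["x"])), 1e-8)
  expect_lt(max(abs(tr$z - ss["z"])), 1e-8)

  # halving dt barely moves the final state for an oscillatory set
  posc <- fixture_params("oscillatory")
  init <- c(0.5, 1, 0.5)
  a <- integrate_deterministic(posc, init, duration = 20, dt = 1e-3)
  b <- integrate_deterministic(posc, init, duration = 20, dt = 5e-4)
  expect_lt(abs(a$x[nrow(a)] - b$x[nrow(b)]), 1e-4)

  # resting cytosolic Ca2+ settles in the low physiological band
  p3 <- fixture_params("steady3")
  tr3 <- integrate_deterministic(p3, duration = 60, record_from = 40)
  expect_true(all(tr3$x > 0.05 & tr3$x < 0.25))
  expect_lt(max(tr3$x) - min(tr3$x), 0.02)
})

test_that("trajectories in the oscillatory range stay physiological", {
  tr <- integrate_deterministic(fixture_params("oscillatory"),
                                init = c(0.5, 1, 0.5), duration = 60,
                                record_from = 20)
  expect_true(all(tr$x >= 0))
  expect_lt(max(tr$x), 1.6)
  expect_gt(max(tr$x) - min(tr$x), 0.02)  # genuinely oscillating
})

test_that("parameter construction validates and round-trips", {
  expect_error(ca_params(beta = 1.2, eps = 1, region = "region1"), "beta")
  expect_error(ca_params(beta = 0.5, eps = 1, region = "region1", m = 5),
               "Hill")
  expect_error(ca_params(beta = 0.5, eps = -1, region = "region1"),
               "non-negative")
  expect_error(ca_params(beta = 0.5, eps = 1), "missing parameter")
  f <- tempfile(fileext = ".json")
  write_ca_params(r1, f)
  r1b <- read_ca_params(f)
  expect_equal(as.numeric(r1b), as.numeric(r1))
  expect_equal(attr(r1b, "region"), "region1")
})
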