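# Chemical Langevin simulation: channel decomposition, Euler-Maruyama step,
# deterministic limit, noise scaling, reproducibility.

r1 <- ca_params(beta = 0.5, eps = 5, region = "region1")

test_that("channel rates decompose the drift field", {
  ch0 <- channel_rates(c(0, 0, 0), r1)
  p <- unclass(r1)
  # only the constant-input channels fire at the origin
  expect_equal(ch0$r[ch0$rate == "V0"], p[["V0"]])
  expect_equal(ch0$r[ch0$rate == "V1*beta"], p[["V1"]] * 0.5)
  expect_equal(ch0$r[ch0$rate == "beta*V4"], 0.5 * p[["V4"]])
  expect_true(all(ch0$r[!ch0$rate %in% c("V0", "V1*beta", "beta*V4")] == 0))
  expect_equal(nrow(ch0), 12)

  # k_out extrusion channel: k_out * x = 10 * 0.3
  ch <- channel_rates(c(0.3, 0.5, 0.2), r1)
  expect_equal(ch$r[ch$rate == "k_out*x"], 3.0)

  set.seed(2)
  for (i in 1:100) {
    s <- runif(3, 0, 2)
    ch <- channel_rates(s, r1)
    agg <- tapply(ch$sign * ch$r, ch$species, sum)
    expect_equal(as.numeric(agg[c("x", "y", "z")]),
                 as.numeric(ca_drift(s, r1)), tolerance = 1e-12)
  }
})

test_that("the Euler-Maruyama step reduces to explicit Euler without noise", {
  s <- c(0.3, 0.5, 0.2)
  dt <- 1e-3
  euler <- s + as.numeric(ca_drift(s, r1)) * dt
  # V = Inf: any noise vector is ignored
  expect_equal(unname(em_step(s, r1, Inf, dt, rnorm(12))), euler)
  # zero noise draws: identical at any finite V
  expect_equal(unname(em_step(s, r1, 1e5, dt, rep(0, 12))), euler)
  expect_error(em_step(s, r1, 1e5, dt, rep(0, 5)), "12")
})

test_that("one-step variance matches the channel-rate closed form", {
  s <- find_steady_state(r1)
  V <- 1e6
  dt <- 1e-3
  ch <- channel_rates(s, r1)
  expected_var <- (dt / V) * sum(ch$r[ch$species == "x"])
  set.seed(7)
  n <- 20000
  noise <- matrix(rnorm(12 * n), n, 12)
  xs <- vapply(seq_len(n),
               function(i) em_step(s, r1, V, dt, noise[i, ])[["x"]],
               numeric(1))
  expect_equal(var(xs), expected_var, tolerance = 0.05)
})

test_that("the V = Inf CLE path is exactly the Euler path", {
  init <- c(0.3, 0.5, 0.2)
  dt <- 1e-3
  tr <- simulate_cle(r1, V = Inf, init = init, duration = 2, burn_in = 0,
                     dt = dt, sample_interval = 0.1, seed = 1)
  # independent reference: plain explicit Euler on the drift
  s <- init
  ref <- matrix(NA_real_, 20, 3)
  for (step in 1:2000) {
    s <- pmax(s + as.numeric(ca_drift(pmax(s, 0), r1)) * dt, 0)
    if (step %% 100 == 0) ref[step / 100, ] <- s
  }
  expect_identical(tr$x, ref[, 1])
  expect_identical(tr$y, ref[, 2])
  expect_identical(tr$z, ref[, 3])
})

test_that("identical seeds reproduce, different seeds differ", {
  a <- simulate_cle(r1, V = 1e5, duration = 5, burn_in = 0, dt = 1e-3,
                    seed = 11)
  b <- simulate_cle(r1, V = 1e5, duration = 5, burn_in = 0, dt = 1e-3,
                    seed = 11)
  d <- simulate_cle(r1, V = 1e5, duration = 5, burn_in = 0, dt = 1e-3,
                    seed = 12)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, d$x))
  expect_true(all(a$x >= 0 & a$y >= 0 & a$z >= 0))
})

test_that("stationary fluctuations scale as the inverse square root of V", {
  p <- fixture_params("steady")
  ss <- find_steady_state(p)
  Vs <- c(1e7, 1e6, 1e5)
  sds <- vapply(seq_along(Vs), function(i) {
    tr <- simulate_cle(p, V = Vs[i], init = ss, duration = 30, burn_in = 10,
                       dt = 1e-4, sample_interval = 0.01, seed = 100 + i)
    sd(tr$x)
  }, numeric(1))
  slope <- coef(lm(log10(sds) ~ log10(Vs)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("the ensemble mean tracks the deterministic path", {
  p <- fixture_params("steady")
  ss <- find_steady_state(p)
  init <- ss + c(0.05, 0, 0)
  det <- simulate_cle(p, V = Inf, init = init, duration = 3, burn_in = 0,
                      dt = 1e-3, sample_interval = 1)
  n <- 300
  finals <- vapply(seq_len(n), function(i) {
    simulate_cle(p, V = 1e7, init = init, duration = 3, burn_in = 0,
                 dt = 1e-3, sample_interval = 1, seed = 1000 + i)$x[3]
  }, numeric(1))
  se <- sd(finals) / sqrt(n)
  expect_lt(abs(mean(finals) - det$x[3]), 3 * se + 1e-6)
})

test_that("trajectory CSV round-trips values and provenance", {
  tr <- simulate_cle(r1, V = 1e5, duration = 3, burn_in = 0, dt = 1e-3,
                     seed = 4)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  tr2 <- read_trajectory_csv(f)
  expect_equal(tr2$x, tr$x)
  expect_equal(attr(tr2, "V"), 1e5)
  expect_equal(attr(tr2, "seed"), 4)
})
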