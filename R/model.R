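# Rate laws, drift field, deterministic integration and fixed-point location
# for the Houart Ca2+ oscillation model.

.as_param_vec <- function(params) {
  stopifnot(inherits(params, "ca_params"))
  as.numeric(params)[match(.param_order, names(unclass(params)))]
}

.check_nonneg <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("concentrations must be finite and non-negative")
  }
  invisible(NULL)
}

#' Michaelis-Menten / Hill rate laws of the Ca2+ model
#'
#' `rate_V2` is the Ca2+ pumping rate from cytosol into the internal store,
#' `rate_V3` the CICR release rate from the store back into the cytosol
#' (activated by cytosolic Ca2+, store filling and InsP3), and `rate_V5` the
#' Ca2+-stimulated phosphorylation rate of InsP3 by the 3-kinase. All return
#' uM/min and are bounded by their `VM*` prefactors.
#'
#' @param x,y,z cytosolic Ca2+, stored Ca2+ and InsP3 concentrations (uM),
#'   each non-negative.
#' @param params a [ca_params()] record.
#' @return Rate in uM/min (vectorized over `x`, `y`, `z`).
#' @export
rate_V2 <- function(x, params) {
  .check_nonneg(x)
  p <- unclass(params)
  p[["VM2"]] * x^2 / (p[["k2"]]^2 + x^2)
}

#' @rdname rate_V2
#' @export
rate_V3 <- function(x, y, z, params) {
  .check_nonneg(x, y, z)
  p <- unclass(params)
  m <- p[["m"]]
  p[["VM3"]] * (x^m / (p[["kx"]]^m + x^m)) *
    (y^2 / (p[["ky"]]^2 + y^2)) * (z^4 / (p[["kz"]]^4 + z^4))
}

#' @rdname rate_V2
#' @export
rate_V5 <- function(x, z, params) {
  .check_nonneg(x, z)
  p <- unclass(params)
  pp <- p[["p"]]; n <- p[["n"]]
  p[["VM5"]] * (z^pp / (p[["k5"]]^pp + z^pp)) *
    (x^n / (p[["kd"]]^n + x^n))
}

#' Drift field of the deterministic model
#'
#' Evaluates the right-hand side F(x, y, z) of the three rate equations:
#' influx, stimulated entry, pump/release exchange with the store, passive
#' leak, linear extrusion for `x`; the mirrored exchange terms for `y`; and
#' stimulated synthesis minus 3-kinase and 5-phosphatase degradation for `z`.
#'
#' @param state numeric length-3 state `c(x, y, z)` in uM.
#' @param params a [ca_params()] record.
#' @return Named numeric length-3 vector of time derivatives (uM/min).
#' @export
ca_drift <- function(state, params) {
  .check_nonneg(state)
  out <- .houart_drift_cpp(as.numeric(state), .as_param_vec(params))
  names(out) <- c("x", "y", "z")
  out
}

#' Deterministic trajectory of the Ca2+ model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the rate equations,
#' sampled uniformly. This is the noiseless (infinite system size) reference
#' dynamics; [simulate_cle()] with `V = Inf` gives the same limit under the
#' Euler scheme.
#'
#' @param params a [ca_params()] record.
#' @param init length-3 initial state (uM); default is the located fixed
#'   point perturbed by +0.1 uM in `x`, so oscillatory regimes start
#'   off-equilibrium.
#' @param duration total integrated time (min).
#' @param dt integration step (min).
#' @param sample_interval recording interval (min), a multiple of `dt`.
#' @param record_from discard samples before this time (min).
#' @return A `ca_trajectory`: data frame with columns `time`, `x`, `y`, `z`
#'   and provenance attributes (`params`, `V`, `dt`, `seed`).
#' @export
integrate_deterministic <- function(params, init = NULL, duration = 120,
                                    dt = 1e-3, sample_interval = 0.1,
                                    record_from = 0) {
  stopifnot(dt > 0, duration > 0, sample_interval >= dt)
  if (is.null(init)) init <- default_init(params)
  m <- .houart_rk4_cpp(.as_param_vec(params), as.numeric(init), dt, duration,
                       sample_interval, record_from)
  .new_trajectory(m, params, V = Inf, dt = dt, seed = NA_real_)
}

.new_trajectory <- function(m, params, V, dt, seed) {
  out <- data.frame(time = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4])
  structure(out, class = c("ca_trajectory", "data.frame"),
            params = params, V = V, dt = dt, seed = seed)
}

#' @export
print.ca_trajectory <- function(x, ...) {
  V <- attr(x, "V")
  cat(sprintf(
    "Ca2+ trajectory: %d samples, t = %.4g..%.4g min, V = %s, dt = %g min\n",
    nrow(x), min(x$time), max(x$time),
    if (is.infinite(V)) "Inf (noiseless)" else format(V, scientific = TRUE),
    attr(x, "dt")))
  cat(sprintf("x range: %.4f..%.4f uM\n", min(x$x), max(x$x)))
  invisible(x)
}

#' @export
plot.ca_trajectory <- function(x, species = "x", ...) {
  graphics::plot(x$time, x[[species]], type = "l", xlab = "time (min)",
                 ylab = sprintf("%s (uM)", species), ...)
}

#' Locate a steady state of the model
#'
#' Finds a non-negative root of the drift field by damped Newton iteration
#' with a forward-difference Jacobian, from several physiological starting
#' points.
#'
#' @param params a [ca_params()] record.
#' @param tol residual norm required of the root.
#' @return Named length-3 state with `max(abs(drift)) < tol`.
#' @export
find_steady_state <- function(params, tol = 1e-10) {
  pv <- .as_param_vec(params)
  f <- function(s) .houart_drift_cpp(pmax(s, 0), pv)
  # x* is pinned by total-Ca2+ balance: x = (V0 + V1 beta) / k_out
  x_star <- (pv[3] + pv[4] * pv[1]) / max(pv[15], 1e-12)
  starts <- list(c(x_star, 0.5, 0.2), c(0.1, 0.5, 0.2), c(0.3, 1, 0.5),
                 c(0.05, 0.1, 0.05), c(1, 2, 1), c(0.5, 0.2, 0.8))
  for (s0 in starts) {
    root <- .newton_root(f, s0, tol)
    if (!is.null(root)) {
      return(stats::setNames(pmax(root, 0), c("x", "y", "z")))
    }
  }
  stop("no steady state found with residual < ", tol,
       "; supply an explicit initial state instead")
}

# damped Newton with forward-difference Jacobian; returns NULL on failure
.newton_root <- function(f, s0, tol, max_iter = 60) {
  s <- pmax(as.numeric(s0), 0)
  fs <- f(s)
  for (iter in seq_len(max_iter)) {
    res <- max(abs(fs))
    if (res < tol) return(s)
    h <- pmax(abs(s), 1e-4) * 1e-7
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      sp <- s
      sp[j] <- sp[j] + h[j]
      J[, j] <- (f(sp) - fs) / h[j]
    }
    step <- tryCatch(solve(J, -fs), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      s_new <- pmax(s + lam * step, 0)
      f_new <- f(s_new)
      if (max(abs(f_new)) < res || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(f_new)) >= res && lam < 1e-4) return(NULL)
    s <- s_new
    fs <- f_new
  }
  if (max(abs(fs)) < tol) s else NULL
}

#' Default initial condition
#'
#' The located fixed point perturbed by +0.1 uM in cytosolic Ca2+, so that
#' oscillatory parameter sets leave the (possibly unstable) equilibrium
#' deterministically. Falls back to a fixed physiological state when no root
#' is found.
#'
#' @param params a [ca_params()] record.
#' @return Named length-3 state (uM).
#' @export
default_init <- function(params) {
  ss <- tryCatch(find_steady_state(params), error = function(e) NULL)
  if (is.null(ss)) ss <- c(x = 0.1, y = 0.5, z = 0.2)
  ss["x"] <- ss["x"] + 0.1
  ss
}
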