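# Chemical Langevin simulation of the 12-channel birth-death decomposition.

# channel table: species touched and sign, in the fixed channel order used by
# the Euler-Maruyama core
.channel_table <- data.frame(
  channel = 1:12,
  species = c("x", "x", "x", "x", "x", "x", "y", "y", "y", "z", "z", "z"),
  sign = c(+1, +1, -1, +1, +1, -1, +1, -1, -1, +1, -1, -1),
  rate = c("V0", "V1*beta", "V2", "V3", "kf*y", "k_out*x",
           "V2", "V3", "kf*y", "beta*V4", "V5", "eps*z"),
  stringsAsFactors = FALSE
)

#' Reaction-channel rates at a state
#'
#' Concentration-scale propensities (a_j / V, uM/min) of the 12 birth-death
#' channels of the Ca2+ reaction network, with signed unit stoichiometry on
#' one species each. The signed sum per species equals the drift field.
#'
#' @param state length-3 state `c(x, y, z)` (uM); small negative components
#'   are clamped to zero before evaluation.
#' @param params a [ca_params()] record.
#' @return Data frame with columns `channel`, `species`, `sign`, `rate`
#'   (label) and `r` (uM/min, non-negative).
#' @export
channel_rates <- function(state, params) {
  s <- pmax(as.numeric(state), 0)
  p <- unclass(params)
  x <- s[1]; y <- s[2]; z <- s[3]
  V2 <- rate_V2(x, params)
  V3 <- rate_V3(x, y, z, params)
  V5 <- rate_V5(x, z, params)
  r <- c(p[["V0"]], p[["V1"]] * p[["beta"]], V2, V3, p[["kf"]] * y,
         p[["k_out"]] * x, V2, V3, p[["kf"]] * y, p[["beta"]] * p[["V4"]],
         V5, p[["eps"]] * z)
  out <- .channel_table
  out$r <- pmax(r, 0)
  out
}

#' One Euler-Maruyama step of the chemical Langevin equation
#'
#' s' = s + F dt + sqrt(dt/V) * sum_j nu_j sqrt(r_j) eta_j, with channel
#' rates clamped at zero before the square root and the resulting state
#' clamped at zero component-wise. At `V = Inf` this is exactly an explicit
#' Euler step of the drift. Exposed chiefly for testing; [simulate_cle()]
#' runs the full integration in compiled code.
#'
#' @param state length-3 state (uM).
#' @param params a [ca_params()] record.
#' @param V system size (um^3) or `Inf`.
#' @param dt step (min).
#' @param noise length-12 vector of standard-normal draws, one per channel.
#' @return Named length-3 updated state.
#' @export
em_step <- function(state, params, V, dt, noise) {
  stopifnot(dt > 0, length(noise) == 12)
  ch <- channel_rates(state, params)
  f <- ca_drift(pmax(state, 0), params)
  s <- as.numeric(state) + as.numeric(f) * dt
  if (is.finite(V)) {
    g <- ch$sign * sqrt(ch$r) * noise
    add <- sqrt(dt / V) *
      c(sum(g[ch$species == "x"]), sum(g[ch$species == "y"]),
        sum(g[ch$species == "z"]))
    s <- s + add
  }
  s <- pmax(s, 0)
  if (any(!is.finite(s))) stop("integration failure: non-finite state")
  stats::setNames(s, c("x", "y", "z"))
}

#' Simulate the chemical Langevin equation
#'
#' Euler-Maruyama integration of the Ca2+ reaction network with intrinsic
#' noise of amplitude 1/sqrt(V): each of the 12 channels contributes an
#' independent Gaussian increment scaled by the square root of its rate.
#' Bit-reproducible for a fixed `seed`; `V = Inf` yields the deterministic
#' Euler path and consumes no random numbers.
#'
#' @param params a [ca_params()] record.
#' @param V system size (um^3), or `Inf` for the noiseless limit.
#' @param init length-3 initial state; default [default_init()].
#' @param duration total simulated time (min), including burn-in.
#' @param burn_in initial span discarded from the record (min).
#' @param dt Euler-Maruyama step (min). Default 1e-4 for desk-scale work;
#'   smaller steps are available where the weak-convergence margin matters.
#' @param sample_interval recording interval (min).
#' @param seed integer seed for the trajectory's own RNG stream.
#' @return A `ca_trajectory` (see [integrate_deterministic()]) whose
#'   provenance records `V`, `dt` and `seed`.
#' @export
simulate_cle <- function(params, V, init = NULL, duration = 120,
                         burn_in = 20, dt = 1e-4, sample_interval = 0.1,
                         seed = 1) {
  stopifnot(dt > 0, sample_interval >= dt, duration > burn_in)
  if (is.null(init)) init <- default_init(params)
  m <- .houart_cle_cpp(.as_param_vec(params), as.numeric(init), V, dt,
                       duration, burn_in, sample_interval, as.double(seed))
  .new_trajectory(m, params, V = V, dt = dt, seed = seed)
}

#' Write a trajectory to CSV
#'
#' Plain-text export with a commented metadata header (system size, step,
#' seed) followed by `time,x[,y,z]` columns.
#'
#' @param traj a `ca_trajectory`.
#' @param path output file.
#' @param species columns to write besides `time`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, species = c("x", "y", "z")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# V=%s dt=%g seed=%s", attr(traj, "V"),
                     attr(traj, "dt"), attr(traj, "seed")), con)
  utils::write.csv(as.data.frame(traj)[, c("time", species)], con,
                   row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return A `ca_trajectory` with the recorded provenance (parameters are
#'   not stored in the CSV and come back as `NULL`).
#' @export
read_trajectory_csv <- function(path) {
  first <- readLines(path, n = 1)
  meta <- list(V = NA_real_, dt = NA_real_, seed = NA_real_)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[A-Za-z_]+=[^ ]+", first))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- as.numeric(parts[2])
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!"y" %in% names(df)) df$y <- NA_real_
  if (!"z" %in% names(df)) df$z <- NA_real_
  structure(df[, c("time", "x", "y", "z")],
            class = c("ca_trajectory", "data.frame"),
            params = NULL, V = meta$V, dt = meta$dt, seed = meta$seed)
}
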