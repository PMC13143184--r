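# Model parameters for the Houart three-variable Ca2+ oscillation model.

.param_order <- c("beta", "eps", "V0", "V1", "VM2", "k2", "VM3", "kx", "ky",
                  "kz", "VM5", "k5", "kd", "kf", "k_out", "V4", "m", "p", "n")

.hill_names <- c("m", "p", "n")

# Fixed rate constants of the three canonical parameter regions; beta and eps
# vary within the printed per-region ranges and select the dynamical regime.
.region_fixed <- list(
  region1 = list(V0 = 2, V1 = 2, VM2 = 6, k2 = 0.1, VM3 = 20, kx = 0.3,
                 ky = 0.2, kz = 0.1, VM5 = 30, k5 = 0.6, kd = 1, kf = 1,
                 k_out = 10, V4 = 3, m = 4, p = 1, n = 2),
  region2 = list(V0 = 2, V1 = 2, VM2 = 6, k2 = 0.1, VM3 = 30, kx = 0.6,
                 ky = 0.3, kz = 0.4, VM5 = 50, k5 = 0.3194, kd = 1, kf = 1,
                 k_out = 10, V4 = 10, m = 2, p = 1, n = 4),
  region3 = list(V0 = 2, V1 = 2, VM2 = 6, k2 = 0.1, VM3 = 20, kx = 0.5,
                 ky = 0.2, kz = 0.2, VM5 = 30, k5 = 0.3, kd = 0.5, kf = 1,
                 k_out = 10, V4 = 5, m = 2, p = 2, n = 4)
)

.region_ranges <- list(
  region1 = list(beta = c(0.0, 0.8), eps = c(0.0, 10.0)),
  region2 = list(beta = c(0.65, 0.8), eps = c(10.0, 16.8)),
  region3 = list(beta = c(0.0, 0.8), eps = c(0.0, 2.5))
)

# Dynamical regimes each region can produce (its published bifurcation menu).
.region_classes <- list(
  region1 = c("bursting", "oscillatory", "steady_state"),
  region2 = c("chaotic", "period2", "period3", "period4", "steady_state",
              "oscillatory"),
  region3 = c("quasiperiodic", "steady_state", "oscillatory")
)

#' Regime labels
#'
#' The eight dynamical classes of cytosolic Ca2+ dynamics, in the fixed
#' ordering used throughout (confusion matrices, dataset quotas).
#'
#' @return Character vector of the eight class names.
#' @export
regime_levels <- function() {
  c("steady_state", "bursting", "oscillatory", "period2", "period3",
    "period4", "chaotic", "quasiperiodic")
}

#' Construct a Houart model parameter set
#'
#' Builds a validated parameter record for the three-variable model of
#' InsP3-gated Ca2+-induced Ca2+ release. `x` (cytosolic Ca2+), `y` (stored
#' Ca2+) and `z` (InsP3) are concentrations in uM; time is in minutes.
#'
#' @param beta dimensionless degree of agonist stimulation, in \[0, 1\].
#' @param eps InsP3 5-phosphatase rate (1/min).
#' @param region optional preset name (`"region1"`, `"region2"`, `"region3"`)
#'   supplying all fixed rate constants; individual values may be overridden.
#' @param ... individual parameter overrides: `V0`, `V1`, `VM2`, `k2`, `VM3`,
#'   `kx`, `ky`, `kz`, `VM5`, `k5`, `kd`, `kf`, `k_out`, `V4` (rates in
#'   uM/min or 1/min, thresholds in uM) and integer Hill coefficients `m`,
#'   `p`, `n`. `k5` is the half-saturation constant of InsP3 3-kinase; `k_out`
#'   is the linear Ca2+ extrusion rate.
#' @return An object of class `ca_params`: a named numeric vector of the 19
#'   model parameters with a `region` attribute.
#' @examples
#' p <- ca_params(beta = 0.5, eps = 5, region = "region1")
#' p["VM2"]
#' @export
ca_params <- function(beta, eps, region = NULL, ...) {
  over <- list(...)
  vals <- stats::setNames(rep(NA_real_, length(.param_order)), .param_order)
  if (!is.null(region)) {
    region <- match.arg(region, names(.region_fixed))
    fixed <- .region_fixed[[region]]
    vals[names(fixed)] <- unlist(fixed)
  }
  vals["beta"] <- beta
  vals["eps"] <- eps
  if (length(over)) {
    bad <- setdiff(names(over), .param_order)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    vals[names(over)] <- unlist(over)
  }
  if (anyNA(vals)) {
    stop("missing parameter(s): ",
         paste(names(vals)[is.na(vals)], collapse = ", "),
         " (supply them or choose a region preset)")
  }
  .validate_params(vals)
  structure(vals, class = "ca_params", region = region)
}

.validate_params <- function(vals) {
  if (any(vals < 0)) {
    stop("all rate constants and thresholds must be non-negative; offending: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  hills <- vals[.hill_names]
  if (any(hills != round(hills)) || any(hills < 1) || any(hills > 4)) {
    stop("Hill coefficients m, p, n must be integers in 1..4")
  }
  if (vals["beta"] > 1) stop("beta must lie in [0, 1]")
  invisible(vals)
}

#' @export
print.ca_params <- function(x, ...) {
  reg <- attr(x, "region")
  cat("Houart Ca2+ model parameters",
      if (!is.null(reg)) paste0(" (preset: ", reg, ")"), "\n", sep = "")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Region parameter ranges
#'
#' The (beta, eps) sampling box of a canonical parameter region and the
#' regimes that region can produce.
#'
#' @param region `"region1"`, `"region2"` or `"region3"`.
#' @return List with elements `beta` and `eps` (length-2 ranges) and
#'   `classes` (admissible regime labels).
#' @export
region_ranges <- function(region) {
  region <- match.arg(region, names(.region_ranges))
  c(.region_ranges[[region]], list(classes = .region_classes[[region]]))
}

#' Write / read parameter sets as flat key-value files
#'
#' Serializes a `ca_params` record to a single-object JSON file (flat
#' key-value map plus the region tag) and reads it back.
#'
#' @param params a `ca_params` object.
#' @param path file path.
#' @return `read_ca_params` returns a `ca_params` object;
#'   `write_ca_params` returns `path` invisibly.
#' @export
write_ca_params <- function(params, path) {
  stopifnot(inherits(params, "ca_params"))
  obj <- as.list(stats::setNames(as.numeric(params), names(unclass(params))))
  obj$region <- attr(params, "region")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ca_params
#' @export
read_ca_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  region <- obj$region
  obj$region <- NULL
  out <- do.call(ca_params, c(obj, list(region = NULL)))
  attr(out, "region") <- region
  out
}
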