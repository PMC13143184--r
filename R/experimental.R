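# Ingestion of experimental Ca2+ traces: Fura-2 ratio calibration, uniform
# resampling, and 3-class evaluation of a trained 8-class model.

#' Fura-2 calibration constants
#'
#' Parameters of the ratiometric calibration converting a Fura-2
#' fluorescence ratio R into a free Ca2+ concentration:
#' \[Ca2+\] = Kd * (R - Rmin) / (Rmax - R) * sf_over_sb.
#' The shipped defaults are documented placeholders in the usual in-vitro
#' ballpark, not ground truth for any particular instrument; calibrate per
#' experiment.
#'
#' @param Kd Fura-2 dissociation constant (nM), default 225.
#' @param Rmin,Rmax ratio at zero and saturating Ca2+.
#' @param sf_over_sb ratio of free to bound fluorescence at the second
#'   wavelength (S_f2 / S_b2).
#' @return A `fura2_calibration` list.
#' @export
fura2_calibration <- function(Kd = 225, Rmin = 0.2, Rmax = 6,
                              sf_over_sb = 5) {
  stopifnot(Kd > 0, Rmin < Rmax, sf_over_sb > 0)
  structure(list(Kd = Kd, Rmin = Rmin, Rmax = Rmax,
                 sf_over_sb = sf_over_sb),
            class = "fura2_calibration")
}

#' Convert Fura-2 ratios to Ca2+ concentrations
#'
#' Ratiometric calibration: \[Ca2+\] = Kd (R - Rmin)/(Rmax - R) S_f2/S_b2.
#' Ratios below Rmin floor at 0 with a warning; ratios at or above Rmax are
#' saturated and raise an error.
#'
#' @param R numeric ratio values.
#' @param cal a [fura2_calibration()].
#' @return Concentrations in the units of `Kd` (nM by default).
#' @export
grynkiewicz_convert <- function(R, cal = fura2_calibration()) {
  if (any(R >= cal$Rmax)) {
    stop("ratio at or above Rmax: indicator saturated, conversion undefined")
  }
  if (any(R < cal$Rmin)) {
    warning("ratio below Rmin floored at zero Ca2+")
    R <- pmax(R, cal$Rmin)
  }
  cal$Kd * (R - cal$Rmin) / (cal$Rmax - R) * cal$sf_over_sb
}

#' Read an experimental trace
#'
#' Two-column tabular file (time, value), comma/tab/whitespace separated,
#' optional header. Irregular sampling is tolerated; time must be strictly
#' increasing.
#'
#' @param path file path.
#' @param units recorded unit of the value column (`"ratio"` or `"uM"`).
#' @param label optional curator label (`bursting`, `steady_state`,
#'   `others`).
#' @return An `experimental_trace`: data frame (`time`, `value`) with
#'   attributes `units`, `source`, `label`.
#' @export
read_trace <- function(path, units = c("ratio", "uM"), label = NA) {
  units <- match.arg(units)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first_fields <- strsplit(trimws(lines[1]), "[,\t ]+")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first_fields))))
  body <- if (has_header) lines[-1] else lines
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "[,\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(f))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop("non-numeric row at line ", i + has_header, " of ", path)
    }
    vals[1:2]
  })
  m <- do.call(rbind, rows)
  if (any(diff(m[, 1]) <= 0)) {
    bad <- which(diff(m[, 1]) <= 0)[1]
    stop("time not strictly increasing at line ", bad + 1 + has_header,
         " of ", path)
  }
  structure(data.frame(time = m[, 1], value = m[, 2]),
            class = c("experimental_trace", "data.frame"),
            units = units, source = path, label = label)
}

#' Write a trace (round-trip counterpart of [read_trace()])
#'
#' @param trace an `experimental_trace` or data frame with `time`, `value`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$time, value = trace$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Resample a trace to 1000 uniform points
#'
#' Linear interpolation at 1000 uniformly spaced times spanning the full
#' recorded window; both endpoints are preserved exactly.
#'
#' @param trace an `experimental_trace` (or data frame with `time`,
#'   `value`).
#' @param n_points output length (default 1000).
#' @return Numeric vector of length `n_points`.
#' @export
resample_to_1000 <- function(trace, n_points = 1000) {
  if (nrow(trace) < 2) stop("need at least 2 samples to resample")
  stats::approx(trace$time, trace$value,
                xout = seq(trace$time[1], trace$time[nrow(trace)],
                           length.out = n_points))$y
}

#' Evaluate a trained model on experimental traces
#'
#' Converts each trace to a concentration series if needed, resamples to
#' the model's input length, normalizes ([prepare_input()] scaling),
#' predicts with the 8-class model and projects predictions onto the
#' 3-class experimental scheme (bursting / steady state / others).
#'
#' @param model an `lkcnn` fit.
#' @param traces list of `experimental_trace` objects with curator labels.
#' @param cal a [fura2_calibration()] applied to ratio-unit traces.
#' @return List: `predictions` (data frame: source, predicted 8-class,
#'   projected 3-class, curator label, max softmax) and `confusion`
#'   (3-class [confusion_matrix()]).
#' @export
evaluate_experimental <- function(model, traces, cal = fura2_calibration()) {
  rows <- lapply(traces, function(tr) {
    v <- tr$value
    if (identical(attr(tr, "units"), "ratio")) {
      v <- grynkiewicz_convert(v, cal)
    }
    series <- prepare_input(data.frame(time = tr$time, x = v),
                            model$dims$input_length)
    prob <- predict(model, matrix(series, 1), type = "prob")
    pred8 <- colnames(prob)[which.max(prob)]
    data.frame(source = attr(tr, "source") %||% NA_character_,
               predicted = pred8,
               projected = as.character(project_3class(pred8)),
               label = as.character(attr(tr, "label")),
               confidence = max(prob), stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, rows)
  cm <- confusion_matrix(preds$label, preds$projected,
                         labels = c("bursting", "steady_state", "others"))
  list(predictions = preds, confusion = cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
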