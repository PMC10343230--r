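#' Time-series trace of an observed quantity
#'
#' A time-ordered series of observations with a declared quantity kind.
#' Kinds: `pO2_hPa` (gas-phase oxygen partial pressure), `dissolved_uM` and
#' `dissolved_ppm` (liquid-phase oxygen), `absorbance` (dimensionless AU),
#' `lifetime_us` (probe lifetime).
#'
#' @param time_min numeric vector of times in minutes, strictly increasing,
#'   first value >= 0.
#' @param value numeric vector of observations, same length, no missing
#'   values.
#' @param kind one of `"pO2_hPa"`, `"dissolved_uM"`, `"dissolved_ppm"`,
#'   `"absorbance"`, `"lifetime_us"`.
#' @param meta named list of free-form metadata (geometry, calibration,
#'   generating parameters, scheme tag ...).
#' @return object of class `o2_trace`.
#' @export
o2_trace <- function(time_min, value,
                     kind = c("pO2_hPa", "dissolved_uM", "dissolved_ppm",
                              "absorbance", "lifetime_us"),
                     meta = list()) {
  kind <- match.arg(kind)
  time_min <- as.numeric(time_min)
  value <- as.numeric(value)
  if (length(time_min) != length(value))
    stop("time and value must have equal length")
  if (length(time_min) < 1L) stop("trace must contain at least one point")
  if (anyNA(time_min) || anyNA(value))
    stop("trace must not contain missing values")
  if (time_min[1] < 0) stop("first time must be >= 0")
  if (length(time_min) > 1L && any(diff(time_min) <= 0))
    stop("times must be strictly increasing")
  structure(list(time_min = time_min, value = value, kind = kind,
                 meta = meta),
            class = "o2_trace")
}

#' @export
print.o2_trace <- function(x, ...) {
  cat(sprintf("<o2_trace> %d points, kind = %s, t = %g..%g min, value range [%.4g, %.4g]\n",
              length(x$time_min), x$kind, min(x$time_min), max(x$time_min),
              min(x$value), max(x$value)))
  if (length(x$meta)) {
    flat <- x$meta[vapply(x$meta, function(v)
      is.atomic(v) && length(v) == 1L, logical(1))]
    if (length(flat))
      cat("  meta:", paste(names(flat), unlist(flat), sep = "=",
                           collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.o2_trace <- function(x, ...) {
  data.frame(time_min = x$time_min, value = x$value)
}

#' @export
length.o2_trace <- function(x) length(x$time_min)

#' Display units for a trace kind
#' @param kind a trace kind string.
#' @return unit label.
#' @export
trace_units <- function(kind) {
  switch(kind,
         pO2_hPa = "hPa",
         dissolved_uM = "uM",
         dissolved_ppm = "ppm",
         absorbance = "AU",
         lifetime_us = "us",
         stop("unknown trace kind: ", kind))
}
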