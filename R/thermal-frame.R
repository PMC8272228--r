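#' Construct a thermal frame
#'
#' A thermal frame is one 2D skin-temperature image in degrees Celsius with
#' a timestamp in seconds from the start of the session. Values are checked
#' against a plausibility window (default 0-60 C) so that mis-scaled raw
#' sensor counts are caught at construction.
#'
#' @param temperatures Numeric matrix of temperatures in degrees C.
#' @param timestamp_s Timestamp in seconds (>= 0).
#' @param window Plausibility window `c(lo, hi)` in degrees C.
#' @return A `thermal_frame` object.
#' @export
thermal_frame <- function(temperatures, timestamp_s = 0,
                          window = c(0, 60)) {
  if (!is.matrix(temperatures) || !is.numeric(temperatures))
    stop("temperatures must be a numeric matrix")
  if (any(!is.finite(temperatures)))
    stop("temperatures must be finite")
  rng <- range(temperatures)
  if (rng[1] < window[1] || rng[2] > window[2])
    stop(sprintf(
      "temperatures [%.2f, %.2f] C outside plausibility window [%g, %g] C",
      rng[1], rng[2], window[1], window[2]))
  if (length(timestamp_s) != 1 || !is.finite(timestamp_s) || timestamp_s < 0)
    stop("timestamp_s must be a single nonnegative number")
  structure(list(temperatures = temperatures, timestamp_s = timestamp_s),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> %d x %d px, t = %g s, range [%.2f, %.2f] C\n",
              nrow(x$temperatures), ncol(x$temperatures), x$timestamp_s,
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' @export
as.matrix.thermal_frame <- function(x, ...) x$temperatures

#' @export
dim.thermal_frame <- function(x) dim(x$temperatures)
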