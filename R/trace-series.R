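#' Uniformly sampled time series
#'
#' Light-weight container for a uniformly sampled signal: fluorescence,
#' eye angle, stimulus position, or any derived trace. Values are stored
#' together with the sampling rate so downstream spectral and phase
#' operations never have to guess the time base.
#'
#' @param values numeric vector of samples.
#' @param rate sampling rate in Hz (> 0).
#' @param channel label, e.g. `"TexasRed"`, `"dYFP"`, `"eye"`, `"stimulus"`.
#' @param start time of the first sample in seconds.
#' @param units unit label for the values (e.g. `"deg"`, `"%"`, `"a.u."`).
#' @return An object of class `trace_series`.
#' @export
trace_series <- function(values, rate, channel = "signal", start = 0, units = "a.u.") {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("`rate` must be a positive sampling rate in Hz", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), rate = rate, channel = channel,
         start = start, units = units),
    class = "trace_series"
  )
}

#' @export
length.trace_series <- function(x) length(x$values)

#' Sample times of a trace
#' @param x a [trace_series()].
#' @return numeric vector of times in seconds.
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "trace_series"))
  x$start + (seq_along(x$values) - 1L) / x$rate
}

#' Duration of a trace in seconds
#' @param x a [trace_series()].
#' @export
trace_duration <- function(x) length(x$values) / x$rate

#' @export
print.trace_series <- function(x, ...) {
  cat(sprintf("<trace_series> channel '%s': %d samples @ %g Hz (%.1f s), units %s\n",
              x$channel, length(x$values), x$rate, trace_duration(x), x$units))
  invisible(x)
}

#' @export
as.data.frame.trace_series <- function(x, ...) {
  data.frame(time_s = trace_time(x), value = x$values)
}
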