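#' Current trace container
#'
#' A uniformly sampled single-channel current recording. Samples are in pA,
#' with the usual electrophysiology sign convention: outward currents
#' positive, inward currents negative.
#'
#' @param samples Numeric vector of current samples (pA).
#' @param rate Sampling rate in Hz (> 0).
#' @param voltage Holding voltage in mV.
#' @param t0 Time of the first sample in seconds. Default 0.
#' @param meta Named list of provenance metadata (scenario name, seed,
#'   condition labels, ...).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, rate, voltage = NA_real_, t0 = 0,
                          meta = list()) {
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  check_scalar(t0, "t0")
  if (!is.numeric(samples)) abort_invalid("'samples' must be numeric")
  structure(list(
    samples = as.double(samples),
    rate = rate,
    voltage = voltage,
    t0 = t0,
    meta = meta
  ), class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %d samples @ %g Hz (%.3f s), V = %s mV\n",
    length(x$samples), x$rate, length(x$samples) / x$rate,
    if (is.na(x$voltage)) "?" else format(x$voltage)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$samples)

#' Trace time axis
#' @param trace A `current_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

#' Trace duration in seconds
#' @param trace A `current_trace`.
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate
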