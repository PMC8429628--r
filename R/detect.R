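#' Channel-current detector configuration
#'
#' Parameters of the rule used by the automated acquisition software to
#' recognize a channel current on the 1 kHz analysis stream: the current
#' must change by more than `amp_threshold` (pA) within `onset_window`
#' (ms) and then return to its original value within
#' `[return_min, return_max]` seconds.
#'
#' @param amp_threshold Amplitude threshold in pA (> 0). Default 2.
#' @param onset_window Maximum rise time of the excursion in ms. Default 10.
#' @param return_min Minimum time before return to baseline, s. Default 0.01.
#' @param return_max Maximum time before return to baseline, s. Default 1.
#' @param return_tolerance Half-width of the "returned to its original
#'   value" band around the frozen baseline, pA. Default 1.
#' @param baseline_window Trailing running-median window for the baseline
#'   estimate, ms. Default 100.
#' @param analysis_rate Detection sampling rate in Hz. Default 1000.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(amp_threshold = 2, onset_window = 10,
                            return_min = 0.01, return_max = 1.0,
                            return_tolerance = 1, baseline_window = 100,
                            analysis_rate = 1000) {
  check_scalar(amp_threshold, "amp_threshold", lower = 0,
               strict_lower = TRUE)
  check_scalar(onset_window, "onset_window", lower = 0, strict_lower = TRUE)
  check_scalar(return_min, "return_min", lower = 0, strict_lower = TRUE)
  check_scalar(return_max, "return_max", lower = return_min,
               strict_lower = TRUE)
  check_scalar(return_tolerance, "return_tolerance", lower = 0,
               strict_lower = TRUE)
  check_scalar(baseline_window, "baseline_window", lower = 0,
               strict_lower = TRUE)
  check_scalar(analysis_rate, "analysis_rate", lower = 0,
               strict_lower = TRUE)
  structure(list(
    amp_threshold = amp_threshold, onset_window = onset_window,
    return_min = return_min, return_max = return_max,
    return_tolerance = return_tolerance,
    baseline_window = baseline_window, analysis_rate = analysis_rate
  ), class = "detector_config")
}

#' Contact / rupture detector configuration
#'
#' Thresholds for recognizing the large transient current produced when the
#' probe first contacts the lipid solution, and for classifying a sustained
#' large current as membrane rupture.
#'
#' @param contact_threshold Contact transient threshold, pA. Default 100.
#' @param sustained_threshold Rupture current threshold, pA. Default 100.
#' @param sustained_dur Duration above `sustained_threshold` that counts as
#'   rupture, s. Default 2.
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(contact_threshold = 100,
                           sustained_threshold = 100, sustained_dur = 2) {
  check_scalar(contact_threshold, "contact_threshold", lower = 0,
               strict_lower = TRUE)
  check_scalar(sustained_threshold, "sustained_threshold", lower = 0,
               strict_lower = TRUE)
  check_scalar(sustained_dur, "sustained_dur", lower = 0,
               strict_lower = TRUE)
  structure(list(
    contact_threshold = contact_threshold,
    sustained_threshold = sustained_threshold,
    sustained_dur = sustained_dur
  ), class = "contact_config")
}

#' Trailing running-median baseline
#'
#' Robust per-sample baseline estimate: the median of the trailing
#' `window` ms of samples (including the current one). The window is
#' rounded to an odd number of samples. Within the first window the median
#' runs over whatever prefix is available; a window longer than the trace
#' degrades to the global median.
#'
#' @param samples Numeric vector (pA).
#' @param window Window length in ms.
#' @param rate Sampling rate in Hz. Default 1000.
#' @return Numeric vector of baseline levels, same length as `samples`.
#' @export
estimate_baseline <- function(samples, window = 100, rate = 1000) {
  n <- length(samples)
  if (n == 0) return(numeric(0))
  k <- max(1L, round(window / 1000 * rate))
  if (k >= n) return(rep(stats::median(samples), n))
  # centered runmed shifted to trailing alignment
  kk <- if (k %% 2 == 0) k + 1L else k
  ctr <- stats::runmed(samples, kk, endrule = "keep")
  half <- (kk - 1L) %/% 2L
  out <- c(rep(NA_real_, half), ctr[seq_len(n - half)])
  # prefix: expanding median
  for (i in seq_len(min(n, kk - 1L))) {
    out[i] <- stats::median(samples[seq_len(i)])
  }
  # runmed's endrule="keep" leaves the first half-window raw; those indices
  # are already overwritten by the expanding prefix above
  out
}

#' Detect channel-current events
#'
#' Applies the acquisition rule to a trace at the analysis rate: an
#' excursion qualifies as a channel event iff
#' \itemize{
#'   \item `|I - baseline|` exceeds `amp_threshold`, with the excursion
#'     developing (from the last baseline-conforming sample to the first
#'     sample beyond threshold) within `onset_window`;
#'   \item the current then re-enters `baseline +/- return_tolerance`
#'     no sooner than `return_min` and no later than `return_max`.
#' }
#' The baseline is frozen at candidate onset so the event does not
#' contaminate its own reference. Excursions that return too early are
#' classified `background_spike`; those that never return within
#' `return_max` are classified `background_spike` unless they exceed the
#' contact threshold, in which case `contact_transient`. Candidates
#' overlapping an accepted event are suppressed (first onset wins). Both
#' polarities qualify.
#'
#' @param trace A `current_trace`. If its rate differs from
#'   `cfg$analysis_rate` it is [downsample()]d first (block-mean).
#' @param cfg A `detector_config`.
#' @param contact_cfg Optional `contact_config` used only to label
#'   non-returning excursions as contact transients. Default
#'   [contact_config()].
#' @return A data.frame of events: `onset_t`, `end_t`, `amplitude`
#'   (signed pA relative to frozen baseline), `kind` (one of
#'   `channel_event`, `background_spike`, `contact_transient`).
#' @export
detect_channel_events <- function(trace, cfg = detector_config(),
                                  contact_cfg = contact_config()) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(cfg, "detector_config"))
  if (trace$rate != cfg$analysis_rate) {
    trace <- downsample(trace, cfg$analysis_rate)
  }
  x <- trace$samples
  n <- length(x)
  empty <- data.frame(onset_t = numeric(0), end_t = numeric(0),
                      amplitude = numeric(0), kind = character(0))
  if (n == 0) return(empty)

  rate <- cfg$analysis_rate
  base <- estimate_baseline(x, cfg$baseline_window, rate)
  onset_samp <- max(1L, round(cfg$onset_window / 1000 * rate))
  rmin <- round(cfg$return_min * rate)
  rmax <- round(cfg$return_max * rate)

  contact_amp <- if (is.null(contact_cfg)) Inf else
    contact_cfg$contact_threshold
  events <- list()
  i <- 1L
  # After an event returns to its frozen baseline, the trailing median still
  # remembers the event for up to one window; hold the frozen value until
  # the running estimate re-converges, so the decaying median cannot fire a
  # spurious candidate.
  hold <- NA_real_
  while (i <= n) {
    b_i <- base[i]
    if (!is.na(hold)) {
      if (abs(base[i] - hold) <= cfg$return_tolerance) hold <- NA_real_
      else b_i <- hold
    }
    if (abs(x[i] - b_i) > cfg$amp_threshold) {
      b0 <- b_i  # freeze baseline for this candidate
      # onset check: last sample conforming to the frozen baseline
      conf <- which(abs(x[seq_len(i - 1L)] - b0) <= cfg$return_tolerance)
      last_conf <- if (length(conf)) conf[length(conf)] else 0L
      rise_ok <- (i - last_conf) <= onset_samp || last_conf == 0L
      # return search
      j <- i + 1L
      ret <- NA_integer_
      while (j <= n && (j - i) <= rmax) {
        if (abs(x[j] - b0) <= cfg$return_tolerance) { ret <- j; break }
        j <- j + 1L
      }
      seg_end <- if (is.na(ret)) min(n, i + rmax) else ret - 1L
      amp <- stats::median(x[i:seg_end]) - b0
      if (!is.na(ret)) {
        dur <- (ret - i) / rate
        kind <- if (abs(amp) >= contact_amp) "contact_transient"
          else if (rise_ok && dur >= cfg$return_min &&
                   dur <= cfg$return_max) "channel_event"
          else "background_spike"
        events[[length(events) + 1L]] <- data.frame(
          onset_t = trace$t0 + (i - 1L) / rate,
          end_t = trace$t0 + (ret - 1L) / rate,
          amplitude = amp, kind = kind)
        i <- ret + 1L
        hold <- b0
      } else {
        # never returned: adopt the shifted level as the new baseline
        kind <- if (abs(amp) >= contact_amp) "contact_transient"
          else "background_spike"
        events[[length(events) + 1L]] <- data.frame(
          onset_t = trace$t0 + (i - 1L) / rate,
          end_t = trace$t0 + seg_end / rate,
          amplitude = amp, kind = kind)
        i <- seg_end + 1L
        hold <- NA_real_
      }
    } else {
      i <- i + 1L
    }
  }
  if (!length(events)) return(empty)
  do.call(rbind, events)
}

#' Detect probe contact in a trace chunk
#'
#' Returns the first time at which `|I|` crosses the contact threshold
#' (the large transient produced when the probe touches the lipid
#' solution), or `NA` if it never does.
#'
#' @param chunk A `current_trace`.
#' @param cfg A `contact_config`.
#' @return Contact time in seconds (absolute, using the chunk's `t0`), or
#'   `NA_real_`.
#' @export
detect_contact <- function(chunk, cfg = contact_config()) {
  stopifnot(inherits(chunk, "current_trace"))
  idx <- which(abs(chunk$samples) > cfg$contact_threshold)
  if (!length(idx)) return(NA_real_)
  chunk$t0 + (idx[1] - 1) / chunk$rate
}

#' Detect sustained large current (membrane rupture)
#'
#' @param chunk A `current_trace`.
#' @param cfg A `contact_config`.
#' @return `TRUE` iff `|I|` stays above `sustained_threshold` for at least
#'   `sustained_dur` seconds somewhere in the chunk.
#' @export
detect_rupture <- function(chunk, cfg = contact_config()) {
  stopifnot(inherits(chunk, "current_trace"))
  need <- round(cfg$sustained_dur * chunk$rate)
  r <- rle(abs(chunk$samples) > cfg$sustained_threshold)
  any(r$values & r$lengths >= need)
}

#' Window-level detection decision
#'
#' The acquisition software's per-step decision: did the analysis window
#' contain at least one channel event?
#'
#' @param events Event data.frame from [detect_channel_events()].
#' @param window Decision window length in seconds (kept for interface
#'   symmetry; events are assumed to fall within it). Default 2.
#' @return `TRUE` iff at least one event of kind `channel_event` is present.
#' @export
decide_window <- function(events, window = 2) {
  if (is.null(events) || nrow(events) == 0) return(FALSE)
  any(events$kind == "channel_event")
}
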