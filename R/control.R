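#' Block-mean decimation
#'
#' Downsamples a trace by averaging non-overlapping blocks, the way the
#' acquisition software reduced the 10 kHz archival stream to the 1 kHz
#' analysis stream.
#'
#' @param trace A `current_trace`.
#' @param to_rate Target rate in Hz; `trace$rate` must be an integer
#'   multiple of it.
#' @return A `current_trace` at `to_rate`.
#' @export
downsample <- function(trace, to_rate = 1000) {
  stopifnot(inherits(trace, "current_trace"))
  check_scalar(to_rate, "to_rate", lower = 0, strict_lower = TRUE)
  ratio <- trace$rate / to_rate
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    abort_invalid(sprintf(
      "rate %g Hz is not an integer multiple of target %g Hz",
      trace$rate, to_rate))
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(trace)
  n_out <- length(trace$samples) %/% ratio
  x <- trace$samples[seq_len(n_out * ratio)]
  out <- colMeans(matrix(x, nrow = ratio))
  current_trace(out, rate = to_rate, voltage = trace$voltage,
                t0 = trace$t0, meta = trace$meta)
}

#' Acquisition controller configuration
#'
#' Control constants of the automated probe-descent state machine: descend
#' at `descent_speed` until contact, pause `contact_pause` seconds, then
#' advance in `step_size` increments every `step_interval` seconds while
#' analysing each interval's current for channel events.
#'
#' @param descent_speed Probe descent speed, um/s. Default 260.
#' @param contact_pause Pause after the contact transient, s. Default 10.
#' @param step_size Step increment during search, um. Default 10.
#' @param step_interval Dwell (and analysis window) per step, s. Default 2.
#' @param max_depth Abort depth, um. Default 5000.
#' @param abort_on_rupture Abort when a sustained large current is seen.
#'   Default `TRUE`.
#' @param voltage Holding voltage during the search, mV. Default -60.
#' @param descent_chunk Chunk length used to poll the stream while
#'   descending, s. Default 0.5.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(descent_speed = 260, contact_pause = 10,
                              step_size = 10, step_interval = 2,
                              max_depth = 5000, abort_on_rupture = TRUE,
                              voltage = -60, descent_chunk = 0.5) {
  for (nm in c("descent_speed", "contact_pause", "step_size",
               "step_interval", "max_depth", "descent_chunk")) {
    check_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  check_scalar(voltage, "voltage")
  structure(list(
    descent_speed = descent_speed, contact_pause = contact_pause,
    step_size = step_size, step_interval = step_interval,
    max_depth = max_depth, abort_on_rupture = isTRUE(abort_on_rupture),
    voltage = voltage, descent_chunk = descent_chunk
  ), class = "controller_config")
}

#' Run the automated acquisition state machine
#'
#' Drives a (simulated) probe against an [acquisition_stream()]: the probe
#' descends continuously until the contact transient is detected, pauses,
#' then steps downward while the detector analyses each step's window; the
#' run terminates in `DETECTED_HOLD` on the first window containing a
#' channel event, `ABORTED_RUPTURE` on a sustained large current (if
#' enabled), or `FAILED_MAX_DEPTH` when `max_depth` is reached. Time is
#' simulated and advanced by the controller, so runs are fully
#' reproducible.
#'
#' @param stream An `acquisition_stream`.
#' @param detector_cfg A `detector_config`.
#' @param contact_cfg A `contact_config`.
#' @param ctl A `controller_config`.
#' @param keep_traces Keep each analysis window's `current_trace` in the
#'   log. Default `TRUE`.
#' @return An `acquisition_log`: list with `transitions` (data.frame of
#'   `time`, `phase`, `position`), `detection` (`NULL`, or list with
#'   `time`, `position`, `events`), `outcome` (terminal phase), `n_steps`,
#'   and `traces`.
#' @export
run_acquisition <- function(stream,
                            detector_cfg = detector_config(),
                            contact_cfg = contact_config(),
                            ctl = controller_config(),
                            keep_traces = TRUE) {
  stopifnot(inherits(stream, "acquisition_stream"),
            inherits(ctl, "controller_config"))
  transitions <- data.frame(time = 0, phase = "DESCENDING", position = 0)
  traces <- list()
  add <- function(t, phase, pos) {
    transitions[nrow(transitions) + 1L, ] <<- list(t, phase, pos)
  }

  pos_fun_descend <- function(tt) pmin(ctl$descent_speed * tt,
                                       ctl$max_depth)
  attr(pos_fun_descend, "voltage") <- ctl$voltage

  # --- DESCENDING ---------------------------------------------------------
  t <- 0
  contact_t <- NA_real_
  t_max_descend <- ctl$max_depth / ctl$descent_speed
  while (t < t_max_descend) {
    dur <- min(ctl$descent_chunk, t_max_descend - t)
    ch <- stream$chunk(t, dur, pos_fun_descend)
    hit <- detect_contact(ch, contact_cfg)
    if (!is.na(hit)) { contact_t <- hit; break }
    t <- t + dur
  }
  if (is.na(contact_t)) {
    add(t_max_descend, "FAILED_MAX_DEPTH", ctl$max_depth)
    return(new_acquisition_log(transitions, NULL, "FAILED_MAX_DEPTH",
                               0L, traces,
                               diagnostic = "no contact before max_depth"))
  }
  contact_pos <- ctl$descent_speed * contact_t
  add(contact_t, "CONTACT_PAUSE", contact_pos)

  # --- CONTACT_PAUSE ------------------------------------------------------
  t <- contact_t + ctl$contact_pause
  pos <- contact_pos
  add(t, "STEPPING", pos)

  # --- STEPPING -----------------------------------------------------------
  n_steps <- 0L
  repeat {
    if (pos + ctl$step_size > ctl$max_depth) {
      add(t, "FAILED_MAX_DEPTH", pos)
      return(new_acquisition_log(transitions, NULL, "FAILED_MAX_DEPTH",
                                 n_steps, traces,
                                 diagnostic = "max_depth reached"))
    }
    pos <- pos + ctl$step_size
    n_steps <- n_steps + 1L
    pf <- local({
      p <- pos
      f <- function(tt) rep(p, length(tt))
      attr(f, "voltage") <- ctl$voltage
      f
    })
    ch <- stream$chunk(t, ctl$step_interval, pf)
    t <- t + ctl$step_interval
    if (keep_traces) traces[[length(traces) + 1L]] <- ch
    if (ctl$abort_on_rupture && detect_rupture(ch, contact_cfg)) {
      add(t, "ABORTED_RUPTURE", pos)
      return(new_acquisition_log(transitions, NULL, "ABORTED_RUPTURE",
                                 n_steps, traces))
    }
    ev <- detect_channel_events(ch, detector_cfg, contact_cfg)
    if (decide_window(ev, ctl$step_interval)) {
      add(t, "DETECTED_HOLD", pos)
      det <- list(time = t, position = pos, events = ev)
      return(new_acquisition_log(transitions, det, "DETECTED_HOLD",
                                 n_steps, traces))
    }
  }
}

new_acquisition_log <- function(transitions, detection, outcome, n_steps,
                                traces, diagnostic = NULL) {
  structure(list(transitions = transitions, detection = detection,
                 outcome = outcome, n_steps = n_steps, traces = traces,
                 diagnostic = diagnostic),
            class = "acquisition_log")
}

#' @export
print.acquisition_log <- function(x, ...) {
  cat("<acquisition_log>\n")
  print(x$transitions, row.names = FALSE)
  cat(sprintf("  outcome: %s after %d step(s)\n", x$outcome, x$n_steps))
  if (!is.null(x$detection)) {
    cat(sprintf("  detection at t = %.2f s, depth %.0f um (%d event(s))\n",
                x$detection$time, x$detection$position,
                sum(x$detection$events$kind == "channel_event")))
  }
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}
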