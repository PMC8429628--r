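#' Channel recording scenario
#'
#' A `channel_scenario` bundles the generative parameters for one recording
#' condition: the single-channel slope conductance, reversal potential,
#' two-state gating kinetics, and the channel-incorporation law used to draw
#' how many channels end up in the bilayer.
#'
#' The gating model is a two-state (closed/open) continuous-time Markov
#' chain. The three kinetic quantities are linked by
#' `open_prob = mean_open / (mean_open + mean_closed)`; supply any two and
#' the third is filled in. Supplying all three is allowed only when
#' consistent.
#'
#' @param name Text label for the condition.
#' @param conductance_g Single-channel slope conductance in pS (>= 0).
#' @param reversal_E Reversal potential in mV. Default 0 (symmetric 200 mM
#'   K+ solutions).
#' @param open_prob Stationary open probability in \[0, 1\].
#' @param mean_open Mean open dwell time in ms (> 0).
#' @param mean_closed Mean closed dwell time in ms (> 0).
#' @param channel_count_lambda Intensity of the zero-truncated Poisson
#'   channel-incorporation law (> 0). Default 0.6, which reproduces an
#'   approximately 73/22/5 single/double/multiple split.
#' @param fixed_channel_count Optional positive integer that bypasses the
#'   incorporation law and fixes the channel count.
#' @return An object of class `channel_scenario`.
#' @examples
#' sc <- channel_scenario("demo", conductance_g = 100,
#'                        open_prob = 0.5, mean_open = 50)
#' sc$mean_closed  # 50, filled in from the other two
#' @export
channel_scenario <- function(name,
                             conductance_g,
                             reversal_E = 0,
                             open_prob = NULL,
                             mean_open = NULL,
                             mean_closed = NULL,
                             channel_count_lambda = 0.6,
                             fixed_channel_count = NULL) {
  check_scalar(conductance_g, "conductance_g", lower = 0)
  check_scalar(reversal_E, "reversal_E")
  kin <- resolve_kinetics(open_prob, mean_open, mean_closed)
  check_scalar(channel_count_lambda, "channel_count_lambda",
               lower = 0, strict_lower = TRUE)
  if (!is.null(fixed_channel_count)) {
    check_scalar(fixed_channel_count, "fixed_channel_count",
                 lower = 1)
    if (fixed_channel_count != round(fixed_channel_count)) {
      abort_invalid("'fixed_channel_count' must be a positive integer")
    }
    fixed_channel_count <- as.integer(fixed_channel_count)
  }
  structure(list(
    name = as.character(name)[1],
    conductance_g = conductance_g,
    reversal_E = reversal_E,
    open_prob = kin$open_prob,
    mean_open = kin$mean_open,
    mean_closed = kin$mean_closed,
    channel_count_lambda = channel_count_lambda,
    fixed_channel_count = fixed_channel_count
  ), class = "channel_scenario")
}

resolve_kinetics <- function(open_prob, mean_open, mean_closed) {
  given <- !vapply(list(open_prob, mean_open, mean_closed), is.null,
                   logical(1))
  if (sum(given) < 2L) {
    abort_invalid(
      "supply at least two of open_prob, mean_open, mean_closed")
  }
  if (!is.null(open_prob)) {
    check_scalar(open_prob, "open_prob", lower = 0, upper = 1,
                 strict_lower = TRUE)
    if (open_prob >= 1) abort_invalid("'open_prob' must be < 1")
  }
  if (!is.null(mean_open)) {
    check_scalar(mean_open, "mean_open", lower = 0, strict_lower = TRUE)
  }
  if (!is.null(mean_closed)) {
    check_scalar(mean_closed, "mean_closed", lower = 0, strict_lower = TRUE)
  }
  if (is.null(open_prob)) {
    open_prob <- mean_open / (mean_open + mean_closed)
  } else if (is.null(mean_open)) {
    mean_open <- mean_closed * open_prob / (1 - open_prob)
  } else if (is.null(mean_closed)) {
    mean_closed <- mean_open * (1 - open_prob) / open_prob
  } else {
    implied <- mean_open / (mean_open + mean_closed)
    if (abs(implied - open_prob) > 1e-8) {
      abort_invalid(sprintf(
        "inconsistent kinetics: open_prob %g but mean_open/mean_closed imply %g",
        open_prob, implied))
    }
  }
  list(open_prob = open_prob, mean_open = mean_open,
       mean_closed = mean_closed)
}

#' @export
print.channel_scenario <- function(x, ...) {
  cat(sprintf("<channel_scenario> %s\n", x$name))
  cat(sprintf("  g = %.1f pS, E_rev = %.1f mV\n",
              x$conductance_g, x$reversal_E))
  cat(sprintf("  gating: Po = %.3f, mean open %.1f ms, mean closed %.1f ms\n",
              x$open_prob, x$mean_open, x$mean_closed))
  if (is.null(x$fixed_channel_count)) {
    cat(sprintf("  channel count ~ zero-truncated Poisson(%.2f)\n",
                x$channel_count_lambda))
  } else {
    cat(sprintf("  channel count fixed at %d\n", x$fixed_channel_count))
  }
  invisible(x)
}

#' Trace noise specification
#'
#' Describes the background noise added to simulated current traces:
#' Gaussian baseline noise, slow linear drift, and sparse background current
#' spikes (the kind the detection rule must reject).
#'
#' @param baseline_rms Gaussian noise RMS in pA (>= 0) at the rendering
#'   bandwidth. Default 0.5.
#' @param drift_rate Linear baseline drift in pA/s. Default 0.2.
#' @param spike_rate Background spike rate in events/s (>= 0). Default 0.02.
#' @param spike_amplitude Spike amplitude in pA. Default 3.
#' @param spike_width Spike width in ms. Default 2 (shorter than the
#'   detector's minimum return time, so spikes are classified as background).
#' @param lowpass_cutoff Low-pass cutoff in Hz applied to the Gaussian
#'   component (single-pole filter), or `Inf` for white noise. Default 1000.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_rms = 0.5, drift_rate = 0.2,
                       spike_rate = 0.02, spike_amplitude = 3,
                       spike_width = 2, lowpass_cutoff = 1000) {
  check_scalar(baseline_rms, "baseline_rms", lower = 0)
  check_scalar(drift_rate, "drift_rate")
  check_scalar(spike_rate, "spike_rate", lower = 0)
  check_scalar(spike_amplitude, "spike_amplitude")
  check_scalar(spike_width, "spike_width", lower = 0, strict_lower = TRUE)
  if (!identical(lowpass_cutoff, Inf)) {
    check_scalar(lowpass_cutoff, "lowpass_cutoff", lower = 0,
                 strict_lower = TRUE)
  }
  structure(list(
    baseline_rms = baseline_rms,
    drift_rate = drift_rate,
    spike_rate = spike_rate,
    spike_amplitude = spike_amplitude,
    spike_width = spike_width,
    lowpass_cutoff = lowpass_cutoff
  ), class = "noise_spec")
}

#' Noise-free specification
#'
#' Convenience constructor for a silent `noise_spec` (no Gaussian noise,
#' drift, or spikes); used by deterministic fixtures and oracles.
#' @return A `noise_spec` with all components zero.
#' @export
noise_off <- function() {
  noise_spec(baseline_rms = 0, drift_rate = 0, spike_rate = 0,
             spike_amplitude = 0, lowpass_cutoff = Inf)
}

#' Built-in scenario presets
#'
#' Returns one of the scenario presets shipped with the package as JSON
#' under `inst/extdata/scenarios/`. Conductances are the published
#' slope-conductance values for the corresponding recording conditions;
#' gating kinetics and the incorporation law are synthetic defaults (the
#' source experiments did not quantify them).
#'
#' * `kcsa_e71a_decane` — KcsA(E71A), POPE–POPG in n-decane, g = 103.6 pS.
#' * `kcsa_e71a_hexadecane` — KcsA(E71A), POPE–POPG in n-hexadecane,
#'   g = 127.6 pS.
#' * `kcsa_wt_control` — KcsA(WT), no blocker, g = 90.2 pS.
#' * `kcsa_wt_tea` — KcsA(WT) with 10 mM TEA; the blocker effect is modeled
#'   as a reduced apparent conductance, g = 52.2 pS.
#'
#' @param name Preset name (see above), or omit to list available names.
#' @return A `channel_scenario`, or a character vector of names if `name`
#'   is missing.
#' @examples
#' scenario_preset()
#' scenario_preset("kcsa_e71a_decane")
#' @export
scenario_preset <- function(name) {
  dir <- system.file("extdata", "scenarios", package = "autobilayer")
  avail <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
  if (missing(name)) return(sort(avail))
  if (!name %in% avail) {
    abort_invalid(sprintf("unknown scenario preset '%s' (available: %s)",
                          name, paste(sort(avail), collapse = ", ")))
  }
  read_scenario_json(file.path(dir, paste0(name, ".json")))
}

#' Read / write a scenario as JSON
#'
#' @param path File path.
#' @return `read_scenario_json` returns a `channel_scenario`;
#'   `write_scenario_json` returns `path` invisibly.
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_scenario(
    name = x$name,
    conductance_g = x$conductance_g,
    reversal_E = if (is.null(x$reversal_E)) 0 else x$reversal_E,
    open_prob = x$open_prob,
    mean_open = x$mean_open,
    mean_closed = x$mean_closed,
    channel_count_lambda =
      if (is.null(x$channel_count_lambda)) 0.6 else x$channel_count_lambda,
    fixed_channel_count = x$fixed_channel_count
  )
}

#' @rdname read_scenario_json
#' @param scenario A `channel_scenario`.
#' @export
write_scenario_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "channel_scenario"))
  keep <- scenario[!vapply(scenario, is.null, logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
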