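#' Fit a current-voltage relationship
#'
#' Ordinary least-squares line through (voltage, unitary amplitude) pairs.
#' The slope in pA/mV is converted to a slope conductance in pS
#' (1 pA/mV = 1 nS = 1000 pS).
#'
#' @param data A data.frame with columns `voltage` (mV) and `unitary_pA`
#'   (pA); rows with `NA` amplitude are dropped. An optional `n` column
#'   (recordings per point) is carried through.
#' @return An `iv_fit`: list with `conductance_pS`, `intercept_pA`, `r2`,
#'   `se_pS`, `n_points`, and `data`.
#' @examples
#' d <- data.frame(voltage = seq(-100, 100, 20),
#'                 unitary_pA = 0.1 * seq(-100, 100, 20))
#' fit_iv(d)$conductance_pS  # 100
#' @export
fit_iv <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("voltage", "unitary_pA") %in% names(data)))
  d <- data[is.finite(data$voltage) & is.finite(data$unitary_pA), ,
            drop = FALSE]
  if (length(unique(d$voltage)) < 2) {
    stop(structure(
      class = c("autobilayer_insufficient_data", "error", "condition"),
      list(message = "need >= 2 distinct voltages for an I-V fit",
           call = sys.call())))
  }
  fit <- stats::lm(unitary_pA ~ voltage, data = d)
  s <- suppressWarnings(summary(fit))  # exact lines are legitimate here
  structure(list(
    conductance_pS = unname(stats::coef(fit)[2]) * 1000,
    intercept_pA = unname(stats::coef(fit)[1]),
    r2 = s$r.squared,
    se_pS = unname(s$coefficients[2, 2]) * 1000,
    n_points = nrow(d),
    data = d
  ), class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf(
    "<iv_fit> g = %.1f pS (se %.1f), intercept %.2f pA, r2 = %.4f, %d points\n",
    x$conductance_pS, x$se_pS, x$intercept_pA, x$r2, x$n_points))
  invisible(x)
}

#' Measure an I-V relationship from simulated recordings
#'
#' The full measurement pipeline applied across a voltage grid: for each
#' voltage, render a recording from the scenario, estimate the unitary
#' current from detected events ([estimate_unitary()]), [idealize()] the
#' trace, refine the amplitude ([unitary_amplitude()]), and finally fit
#' the I-V line ([fit_iv()]). Voltages where no channel event clears the
#' detection threshold (near the reversal potential) yield `NA` amplitude
#' and are excluded from the fit, as they would be in practice.
#'
#' @param scenario A `channel_scenario`.
#' @param voltages Voltage grid in mV. Default `seq(-100, 100, by = 20)`.
#' @param duration Recording length per voltage, s. Default 30.
#' @param noise A `noise_spec`. Default [noise_spec()].
#' @param rate Recording rate, Hz. Default 10000.
#' @param seed Integer seed (one per-voltage sub-seed is derived from it).
#' @param n_channels Optional channel-count override passed to
#'   [render_trace()].
#' @param detector_cfg Detector configuration for the unitary-current
#'   seed estimate.
#' @param min_amplitude Smallest unitary-current estimate (pA, absolute)
#'   considered measurable; voltages whose events sit at or below this
#'   are reported `NA`, as amplitudes near the detection threshold are
#'   dominated by noise. Defaults to the detector's `amp_threshold`.
#' @return A list with `iv` (data.frame `voltage`, `unitary_pA`, `n`) and
#'   `fit` (an `iv_fit`).
#' @export
measure_iv <- function(scenario, voltages = seq(-100, 100, by = 20),
                       duration = 30, noise = noise_spec(), rate = 10000,
                       seed = NULL, n_channels = NULL,
                       detector_cfg = detector_config(),
                       min_amplitude = detector_cfg$amp_threshold) {
  stopifnot(inherits(scenario, "channel_scenario"))
  amps <- vapply(seq_along(voltages), function(i) {
    v <- voltages[i]
    tr <- render_trace(scenario, voltage = v, duration = duration,
                       noise = noise, rate = rate,
                       seed = if (is.null(seed)) NULL
                              else derive_seed(seed, 1000 + i),
                       n_channels = n_channels)
    u0 <- estimate_unitary(tr, detector_cfg)
    if (is.na(u0) || abs(u0) < min_amplitude) return(NA_real_)
    id <- idealize(tr, u0)
    if (count_open_levels(id) == 0L) return(NA_real_)
    unitary_amplitude(id, tr)
  }, numeric(1))
  iv <- data.frame(voltage = voltages, unitary_pA = amps,
                   n = ifelse(is.na(amps), 0L, 1L))
  list(iv = iv, fit = fit_iv(iv))
}

#' Full automated-run measurement
#'
#' Emulates one complete automated experiment: the controller descends the
#' probe against a simulated acquisition stream until channel currents are
#' detected ([run_acquisition()]), then the held bilayer is recorded
#' across the voltage grid and the slope conductance fitted
#' ([measure_iv()]). Fails with an error if the run does not terminate in
#' `DETECTED_HOLD`.
#'
#' @param scenario A `channel_scenario` (e.g. from [scenario_preset()]).
#' @param seed Integer seed for the stream and the recordings.
#' @param contact_depth,formation_depth Stream geometry, um. Defaults
#'   2600 / 2650.
#' @param noise A `noise_spec`.
#' @param ctl A `controller_config`.
#' @param detector_cfg,contact_cfg Detector configurations.
#' @param ... Passed on to [measure_iv()] (`voltages`, `duration`, ...).
#' @return A list with `log` (the `acquisition_log`), `iv`, and `fit`.
#' @export
automated_iv_run <- function(scenario, seed = 1,
                             contact_depth = 2600, formation_depth = 2650,
                             noise = noise_spec(),
                             ctl = controller_config(),
                             detector_cfg = detector_config(),
                             contact_cfg = contact_config(), ...) {
  stopifnot(inherits(scenario, "channel_scenario"))
  spec <- stream_spec(scenario, contact_depth = contact_depth,
                      formation_depth = formation_depth, noise = noise)
  stream <- acquisition_stream(spec, seed = derive_seed(seed, 5))
  log <- run_acquisition(stream, detector_cfg, contact_cfg, ctl)
  if (log$outcome != "DETECTED_HOLD") {
    stop("automated run did not detect channel currents (outcome: ",
         log$outcome, ")")
  }
  m <- measure_iv(scenario, noise = noise, seed = derive_seed(seed, 6),
                  detector_cfg = detector_cfg, ...)
  list(log = log, iv = m$iv, fit = m$fit)
}

#' Membrane area from capacitance
#'
#' Planar bilayer area inferred from its electrical capacitance and the
#' specific capacitance of the membrane:
#' `area = C / c_spec` (1 nF at 0.4 uF/cm^2 gives 0.25 mm^2).
#'
#' @param capacitance_nF Measured membrane capacitance in nF (>= 0).
#' @param specific_uF_cm2 Specific capacitance in uF/cm^2 (> 0).
#'   Default 0.4.
#' @return Area in mm^2.
#' @examples
#' membrane_area(1, 0.4)  # 0.25
#' @export
membrane_area <- function(capacitance_nF, specific_uF_cm2 = 0.4) {
  check_scalar(capacitance_nF, "capacitance_nF", lower = 0)
  check_scalar(specific_uF_cm2, "specific_uF_cm2", lower = 0,
               strict_lower = TRUE)
  # nF / (uF/cm^2) = 1e-3 uF / (uF/cm^2) = 1e-3 cm^2 = 0.1 mm^2
  0.1 * capacitance_nF / specific_uF_cm2
}

#' Welch's t-test from group summaries
#'
#' The unequal-variance two-sample t statistic computed from summary
#' statistics:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`, with the
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1 Group 1 mean, SD, and size (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Group 2 likewise.
#' @return A list with `t`, `df`, and two-sided `p`. Equal means with
#'   zero variance give `t = 0`; unequal means with zero variance give an
#'   infinite `t` (flagged by `is.infinite(t)`), `df = NA`.
#' @examples
#' welch_t_from_summary(90.2, 26.4, 7, 52.2, 9.1, 5)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_scalar(n1, "n1", lower = 2); check_scalar(n2, "n2", lower = 2)
  check_scalar(sd1, "sd1", lower = 0); check_scalar(sd2, "sd2", lower = 0)
  check_scalar(mean1, "mean1"); check_scalar(mean2, "mean2")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = NA_real_, p = 1))
    }
    return(list(t = sign(mean1 - mean2) * Inf, df = NA_real_, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Compare conductances between two conditions
#'
#' Condition-level comparison of per-recording slope conductances (e.g.
#' control vs blocker): group means/SDs, the conductance ratio
#' (`condition B / condition A`), and Welch's t-test on the group
#' summaries.
#'
#' @param fits_a List of `iv_fit` objects (or numeric conductances, pS)
#'   for condition A; at least 2.
#' @param fits_b Likewise for condition B.
#' @param labels Length-2 character vector of condition names.
#' @return A `condition_comparison`: list with `summary` (data.frame of
#'   `condition`, `mean_pS`, `sd_pS`, `n`), `conductance_ratio`,
#'   `welch_t`, `welch_df`, `p_value`.
#' @export
compare_conditions <- function(fits_a, fits_b,
                               labels = c("control", "treated")) {
  ga <- extract_conductances(fits_a)
  gb <- extract_conductances(fits_b)
  if (length(ga) < 2 || length(gb) < 2) {
    stop(structure(
      class = c("autobilayer_insufficient_data", "error", "condition"),
      list(message = "need >= 2 per-recording conductances per condition",
           call = sys.call())))
  }
  w <- welch_t_from_summary(mean(ga), stats::sd(ga), length(ga),
                            mean(gb), stats::sd(gb), length(gb))
  structure(list(
    summary = data.frame(
      condition = labels,
      mean_pS = c(mean(ga), mean(gb)),
      sd_pS = c(stats::sd(ga), stats::sd(gb)),
      n = c(length(ga), length(gb))),
    conductance_ratio = mean(gb) / mean(ga),
    welch_t = w$t, welch_df = w$df, p_value = w$p
  ), class = "condition_comparison")
}

extract_conductances <- function(fits) {
  if (is.numeric(fits)) return(as.double(fits))
  vapply(fits, function(f) {
    if (inherits(f, "iv_fit")) f$conductance_pS
    else if (is.numeric(f) && length(f) == 1) as.double(f)
    else abort_invalid("expected an iv_fit or a conductance value")
  }, numeric(1))
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  ratio = %.3f, Welch t = %.2f (df %.1f), p = %.3g\n",
              x$conductance_ratio, x$welch_t, x$welch_df, x$p_value))
  invisible(x)
}
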