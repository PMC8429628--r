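#' Draw an alternating open/closed dwell sequence
#'
#' Simulates the two-state (closed <-> open) continuous-time Markov gating
#' chain: dwell times are exponential with the given means, and states
#' alternate. The sequence is extended until its total duration reaches at
#' least `duration`; the renderer truncates the final dwell at the trace
#' end (no partial-dwell correction).
#'
#' The initial state is drawn from the stationary distribution
#' (`P(open) = mean_open / (mean_open + mean_closed)`), so time-averaged
#' statistics converge to their stationary values without burn-in.
#'
#' @param mean_open Mean open dwell in ms (> 0).
#' @param mean_closed Mean closed dwell in ms (> 0).
#' @param duration Requested total duration in seconds (>= 0).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param start_state `"stationary"` (default), `"closed"`, or `"open"`.
#' @return A data.frame with columns `state` ("closed"/"open") and
#'   `duration` (seconds). Zero rows when `duration == 0`.
#' @examples
#' d <- draw_dwell_sequence(50, 50, duration = 1, seed = 1)
#' head(d)
#' @export
draw_dwell_sequence <- function(mean_open, mean_closed, duration,
                                seed = NULL,
                                start_state = c("stationary", "closed",
                                                "open")) {
  check_scalar(mean_open, "mean_open", lower = 0, strict_lower = TRUE)
  check_scalar(mean_closed, "mean_closed", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0)
  start_state <- match.arg(start_state)
  if (duration == 0) {
    return(data.frame(state = character(0), duration = numeric(0)))
  }
  with_seed(seed, {
    po <- mean_open / (mean_open + mean_closed)
    first_open <- switch(start_state,
      stationary = stats::runif(1) < po,
      closed = FALSE,
      open = TRUE)
    mo <- mean_open / 1000    # work in seconds
    mc <- mean_closed / 1000
    states <- character(0)
    durs <- numeric(0)
    total <- 0
    is_open <- first_open
    # draw in batches: expected cycle length is mo + mc
    batch <- max(16L, ceiling(2 * duration / (mo + mc)))
    while (total < duration) {
      n_open <- ceiling(batch / 2)
      d_open <- stats::rexp(n_open, rate = 1 / mo)
      d_closed <- stats::rexp(n_open, rate = 1 / mc)
      if (is_open) {
        d <- as.vector(rbind(d_open, d_closed))
        s <- rep(c("open", "closed"), n_open)
      } else {
        d <- as.vector(rbind(d_closed, d_open))
        s <- rep(c("closed", "open"), n_open)
      }
      states <- c(states, s)
      durs <- c(durs, d)
      total <- total + sum(d)
      is_open <- s[length(s)] == "closed"  # next state alternates
      batch <- max(16L, ceiling(2 * (duration - total) / (mo + mc)))
    }
    keep <- which(cumsum(durs) - durs < duration)
    data.frame(state = states[keep], duration = durs[keep])
  })
}

#' Sample the number of incorporated channels
#'
#' Channel incorporation into the bilayer is modeled as a zero-truncated
#' Poisson law: the number of channels is Poisson(`lambda`) conditioned on
#' being at least 1 (a recording only exists once one channel made it into
#' the membrane). Sampling uses exact quantile inversion.
#'
#' @param lambda Intensity of the untruncated Poisson law (> 0).
#' @param seed Optional integer seed.
#' @param n Number of draws. Default 1.
#' @return Integer vector of channel counts, all >= 1.
#' @seealso [ztpois_pmf()] for the probability mass function.
#' @export
sample_channel_count <- function(lambda, seed = NULL, n = 1) {
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  with_seed(seed, {
    p0 <- stats::ppois(0, lambda)
    u <- stats::runif(n)
    as.integer(stats::qpois(p0 + u * (1 - p0), lambda))
  })
}

#' Zero-truncated Poisson probability mass function
#'
#' `P(K = k | K >= 1)` for `K ~ Poisson(lambda)`.
#'
#' @param k Vector of counts (>= 1).
#' @param lambda Poisson intensity (> 0).
#' @return Vector of probabilities (0 for k < 1).
#' @export
ztpois_pmf <- function(k, lambda) {
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  p <- stats::dpois(k, lambda) / (1 - exp(-lambda))
  p[k < 1] <- 0
  p
}

#' Render a gated single-channel current trace
#'
#' Generates a `current_trace` for a scenario at a holding voltage: each
#' active channel contributes its unitary current
#' `i = g * (V - E_rev) / 1000` pA while open (pS x mV -> pA), channels gate
#' independently, and baseline noise, drift, and background spikes are
#' superposed per the `noise_spec`. Outward currents are positive.
#'
#' @param scenario A `channel_scenario`.
#' @param voltage Holding voltage in mV.
#' @param duration Trace duration in seconds (> 0).
#' @param noise A `noise_spec`. Default [noise_spec()].
#' @param rate Sampling rate in Hz. Default 10000 (archival rate); detection
#'   runs on a 1 kHz [downsample()].
#' @param seed Optional integer seed; a given seed reproduces the trace
#'   bit-for-bit.
#' @param n_channels Optional channel-count override; otherwise
#'   `scenario$fixed_channel_count` or a [sample_channel_count()] draw.
#' @return A `current_trace`. The true per-sample open-channel count is
#'   attached as `trace$levels` (simulation ground truth, used by tests;
#'   analysis code must not read it).
#' @examples
#' sc <- scenario_preset("kcsa_e71a_decane")
#' tr <- render_trace(sc, voltage = 100, duration = 1, noise = noise_off(),
#'                    seed = 1, n_channels = 1)
#' unique(round(tr$samples, 2))  # 0 and 10.36 pA
#' @export
render_trace <- function(scenario, voltage, duration,
                         noise = noise_spec(), rate = 10000,
                         seed = NULL, n_channels = NULL) {
  stopifnot(inherits(scenario, "channel_scenario"),
            inherits(noise, "noise_spec"))
  check_scalar(voltage, "voltage")
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)

  if (is.null(n_channels)) {
    n_channels <- if (!is.null(scenario$fixed_channel_count)) {
      scenario$fixed_channel_count
    } else {
      sample_channel_count(scenario$channel_count_lambda,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, 0))
    }
  }
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  i_unit <- scenario$conductance_g * (voltage - scenario$reversal_E) / 1000

  levels <- integer(n)
  for (ch in seq_len(n_channels)) {
    dw <- draw_dwell_sequence(scenario$mean_open, scenario$mean_closed,
                              duration,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, ch))
    levels <- levels + dwells_to_levels(dw, tt)
  }
  samples <- levels * i_unit +
    render_noise(noise, n, rate,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, 900))

  tr <- current_trace(samples, rate = rate, voltage = voltage,
                      meta = list(scenario = scenario$name,
                                  n_channels = n_channels,
                                  seed = if (is.null(seed)) NA else seed))
  tr$levels <- levels
  tr
}

# per-sample open indicator from a dwell table
dwells_to_levels <- function(dwells, tt) {
  if (nrow(dwells) == 0) return(integer(length(tt)))
  b <- cumsum(dwells$duration)
  idx <- findInterval(tt, c(0, b[-length(b)]), rightmost.closed = FALSE)
  as.integer(dwells$state[idx] == "open")
}

render_noise <- function(noise, n, rate, seed = NULL) {
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    out <- numeric(n)
    if (noise$baseline_rms > 0) {
      g <- stats::rnorm(n)
      if (is.finite(noise$lowpass_cutoff) &&
          noise$lowpass_cutoff < rate / 2) {
        a <- exp(-2 * pi * noise$lowpass_cutoff / rate)
        g <- as.numeric(stats::filter(g * (1 - a), a, method = "recursive"))
        g <- g / sqrt((1 - a)^2 / (1 - a^2))  # restore unit RMS
      }
      out <- out + noise$baseline_rms * g
    }
    tt <- (seq_len(n) - 1) / rate
    if (noise$drift_rate != 0) out <- out + noise$drift_rate * tt
    if (noise$spike_rate > 0) {
      k <- stats::rpois(1, noise$spike_rate * n / rate)
      if (k > 0) {
        t_sp <- stats::runif(k, 0, n / rate)
        sgn <- sample(c(-1, 1), k, replace = TRUE)
        w <- max(1L, round(noise$spike_width / 1000 * rate))
        for (j in seq_len(k)) {
          i0 <- floor(t_sp[j] * rate) + 1
          i1 <- min(n, i0 + w - 1L)
          out[i0:i1] <- out[i0:i1] + sgn[j] * noise$spike_amplitude
        }
      }
    }
    out
  })
}
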