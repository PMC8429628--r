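#' Acquisition stream specification
#'
#' Describes the phenomenology of one automated probe-descent run: quiet
#' open-circuit current until the probe reaches the lipid solution at
#' `contact_depth` (a large transient fires on first contact), baseline
#' current while the bilayer is forming between `contact_depth` and
#' `formation_depth`, gated channel current once the probe is at or below
#' `formation_depth`, and a sustained large current if the probe is pushed
#' to `rupture_depth` (membrane breakage).
#'
#' @param scenario A `channel_scenario` generating the channel current.
#' @param contact_depth Depth at which the probe touches the lipid
#'   solution, um.
#' @param formation_depth Depth at which a channel-bearing bilayer exists,
#'   um (>= `contact_depth`).
#' @param rupture_depth Optional depth at which the membrane breaks, um
#'   (> `formation_depth`), or `NULL`.
#' @param noise A `noise_spec` for the post-contact baseline.
#' @param contact_transient_amp Contact transient amplitude, pA.
#'   Default 500.
#' @param contact_transient_dur Contact transient duration, ms. Default 50.
#' @param rupture_current Sustained current after rupture, pA. Default 500.
#' @param gating `"markov"` (stochastic two-state gating, default) or
#'   `"periodic"` (a deterministic square wave with period
#'   `mean_open + mean_closed` and on-time `mean_open`; used by
#'   deterministic controller-timing fixtures).
#' @return An object of class `stream_spec`.
#' @export
stream_spec <- function(scenario,
                        contact_depth,
                        formation_depth = contact_depth,
                        rupture_depth = NULL,
                        noise = noise_spec(),
                        contact_transient_amp = 500,
                        contact_transient_dur = 50,
                        rupture_current = 500,
                        gating = c("markov", "periodic")) {
  stopifnot(inherits(scenario, "channel_scenario"),
            inherits(noise, "noise_spec"))
  check_scalar(contact_depth, "contact_depth", lower = 0)
  check_scalar(formation_depth, "formation_depth", lower = contact_depth)
  if (!is.null(rupture_depth)) {
    check_scalar(rupture_depth, "rupture_depth", lower = formation_depth,
                 strict_lower = TRUE)
  }
  structure(list(
    scenario = scenario,
    contact_depth = contact_depth,
    formation_depth = formation_depth,
    rupture_depth = rupture_depth,
    noise = noise,
    contact_transient_amp = contact_transient_amp,
    contact_transient_dur = contact_transient_dur,
    rupture_current = rupture_current,
    gating = match.arg(gating)
  ), class = "stream_spec")
}

#' Open a simulated acquisition stream
#'
#' Returns a stateful stream object the controller can query chunk by
#' chunk. Each query supplies the probe position over a time interval and
#' receives the corresponding `current_trace`. The stream keeps its own
#' channel-gating state so that gating is continuous across chunk
#' boundaries, and remembers whether contact has already occurred (the
#' transient fires exactly once, the first time the position reaches
#' `contact_depth`).
#'
#' @param spec A `stream_spec`.
#' @param seed Integer seed; identical seeds give identical streams.
#' @param rate Rendering sample rate in Hz. Default 1000 (the analysis
#'   rate).
#' @param max_gating_horizon Maximum gated time pre-generated per channel,
#'   s. Default 600.
#' @return An object of class `acquisition_stream` with element
#'   `$chunk(t0, duration, position_fun)`: `position_fun(t)` maps absolute
#'   time (s) to probe depth (um); the call returns a `current_trace`
#'   covering `[t0, t0 + duration)`.
#' @export
acquisition_stream <- function(spec, seed = 1, rate = 1000,
                               max_gating_horizon = 600) {
  stopifnot(inherits(spec, "stream_spec"))
  env <- new.env(parent = emptyenv())
  env$contact_done <- FALSE
  env$formation_t <- NA_real_   # absolute time channel gating started
  env$level_fun <- NULL

  make_level_fun <- function() {
    sc <- spec$scenario
    n_ch <- if (!is.null(sc$fixed_channel_count)) sc$fixed_channel_count
            else sample_channel_count(sc$channel_count_lambda,
                                      seed = derive_seed(seed, 11))
    if (spec$gating == "periodic") {
      period <- (sc$mean_open + sc$mean_closed) / 1000
      on_t <- sc$mean_open / 1000
      function(tau) n_ch * as.integer((tau %% period) < on_t)
    } else {
      dwell_tabs <- lapply(seq_len(n_ch), function(ch) {
        draw_dwell_sequence(sc$mean_open, sc$mean_closed,
                            max_gating_horizon,
                            seed = derive_seed(seed, 100 + ch))
      })
      function(tau) {
        lev <- integer(length(tau))
        for (tab in dwell_tabs) lev <- lev + dwells_to_levels(tab, tau)
        lev
      }
    }
  }

  chunk_fun <- function(t0, duration, position_fun) {
    n <- round(duration * rate)
    tt <- t0 + (seq_len(n) - 1) / rate
    pos <- position_fun(tt)
    if (length(pos) == 1L) pos <- rep(pos, n)
    x <- numeric(n)
    pre <- pos < spec$contact_depth

    # quiet open-circuit segment: a tenth of the post-contact noise
    nz <- render_noise(spec$noise, n, rate,
                       seed = derive_seed(seed, 7 + round(t0 * 1000)))
    x[pre] <- 0.1 * nz[pre]
    x[!pre] <- nz[!pre]

    # contact transient fires once, at first arrival at contact_depth
    if (!env$contact_done && any(!pre)) {
      i0 <- which(!pre)[1]
      w <- max(1L, round(spec$contact_transient_dur / 1000 * rate))
      i1 <- min(n, i0 + w - 1L)
      x[i0:i1] <- x[i0:i1] + spec$contact_transient_amp
      env$contact_done <- TRUE
    }

    # channel gating at/below formation depth
    formed <- pos >= spec$formation_depth
    if (any(formed)) {
      if (is.na(env$formation_t)) {
        env$formation_t <- tt[which(formed)[1]]
        env$level_fun <- make_level_fun()
      }
      sc <- spec$scenario
      v <- attr(position_fun, "voltage")
      if (is.null(v)) v <- -60
      i_unit <- sc$conductance_g * (v - sc$reversal_E) / 1000
      tau <- tt[formed] - env$formation_t
      x[formed] <- x[formed] + i_unit * env$level_fun(tau)
    }

    # rupture: sustained large current
    if (!is.null(spec$rupture_depth)) {
      rup <- pos >= spec$rupture_depth
      x[rup] <- spec$rupture_current + nz[rup]
    }

    v <- attr(position_fun, "voltage")
    current_trace(x, rate = rate,
                  voltage = if (is.null(v)) NA_real_ else v, t0 = t0,
                  meta = list(scenario = spec$scenario$name))
  }

  structure(list(chunk = chunk_fun, spec = spec, rate = rate, seed = seed,
                 state = env),
            class = "acquisition_stream")
}
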