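# Shared fixture builders. Everything is generated in code; no stored data.

# scenario with simple symmetric kinetics, deterministic channel count
test_scenario <- function(g = 100, mean_open = 50, mean_closed = 50,
                          n_channels = 1, name = "test") {
  channel_scenario(name, conductance_g = g, mean_open = mean_open,
                   mean_closed = mean_closed,
                   fixed_channel_count = n_channels)
}

# a stream spec whose post-formation gating is a deterministic square wave
timing_stream_spec <- function(contact_depth = 2600,
                               formation_depth = 2650, ...) {
  stream_spec(test_scenario(), contact_depth = contact_depth,
              formation_depth = formation_depth, noise = noise_off(),
              gating = "periodic", ...)
}

# brute-force trailing-window median (same odd-window contract as
# estimate_baseline)
oracle_trailing_median <- function(x, window_ms, rate = 1000) {
  k <- max(1L, round(window_ms / 1000 * rate))
  kk <- if (k %% 2 == 0) k + 1L else k
  vapply(seq_along(x), function(i) {
    stats::median(x[max(1L, i - kk + 1L):i])
  }, numeric(1))
}

# the printed acquisition rule as a bare indicator function
oracle_pulse_rule <- function(amplitude, duration) {
  abs(amplitude) > 2 && duration >= 0.01 && duration <= 1
}
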