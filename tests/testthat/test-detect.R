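test_that("trailing-median baseline matches the brute-force oracle", {
  # constants and median robustness
  expect_equal(estimate_baseline(rep(3.2, 50), 100, 1000), rep(3.2, 50))
  x <- rep(1, 200); x[100] <- 50
  expect_equal(estimate_baseline(x, 100, 1000), rep(1, 200))

  # linear ramp and a noisy trace against the direct windowed-median oracle
  ramp <- seq(0, 5, length.out = 400)
  expect_equal(estimate_baseline(ramp, 100, 1000),
               oracle_trailing_median(ramp, 100, 1000))
  set.seed(7)
  z <- cumsum(rnorm(300))
  expect_equal(estimate_baseline(z, 50, 1000),
               oracle_trailing_median(z, 50, 1000))

  # window longer than trace: global median
  expect_equal(estimate_baseline(c(1, 2, 30), 100, 1000), rep(2, 3))
})

test_that("noiseless pulse detection equals the printed rule on the full grid", {
  amps <- c(1, 1.9, 2.1, 4, 5, 10)
  durs <- c(0.005, 0.02, 0.5, 0.99, 1.5)
  for (a in amps) for (d in durs) for (sgn in c(1, -1)) {
    tr <- square_pulse_trace(sgn * a, d)
    ev <- detect_channel_events(tr)
    hits <- sum(ev$kind == "channel_event")
    want <- oracle_pulse_rule(sgn * a, d)
    expect_equal(hits, as.integer(want),
                 info = sprintf("amp %g pA, dur %g s", sgn * a, d))
    if (want) {
      expect_equal(ev$amplitude[ev$kind == "channel_event"], sgn * a)
      expect_equal(ev$end_t[ev$kind == "channel_event"] -
                     ev$onset_t[ev$kind == "channel_event"],
                   d, tolerance = 2e-3)
    }
  }
})

test_that("detector is invariant to offset and leading baseline", {
  tr <- square_pulse_trace(5, 0.05)
  ev <- detect_channel_events(tr)

  shifted <- tr
  shifted$samples <- tr$samples + 17.3
  ev_s <- detect_channel_events(shifted)
  expect_equal(ev_s$kind, ev$kind)
  expect_equal(ev_s$onset_t, ev$onset_t)
  expect_equal(ev_s$amplitude, ev$amplitude)

  padded <- current_trace(c(numeric(500), tr$samples), rate = tr$rate)
  ev_p <- detect_channel_events(padded)
  expect_equal(ev_p$kind, ev$kind)
  expect_equal(ev_p$onset_t, ev$onset_t + 0.5)
})

test_that("detection probability is monotone in amplitude under default noise", {
  p_detect <- function(amp) {
    hits <- vapply(1:30, function(s) {
      tr <- square_pulse_trace(amp, 0.05)
      tr$samples <- tr$samples + with_noise(s, length(tr$samples))
      any(detect_channel_events(tr)$kind == "channel_event")
    }, logical(1))
    mean(hits)
  }
  with_noise <- function(seed, n) {
    set.seed(seed)
    rnorm(n, sd = 0.5)
  }
  p <- vapply(c(1, 3, 6, 10), p_detect, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_lt(p[1], 0.5)   # 1 pA is below the rule threshold
  expect_equal(p[4], 1)  # 10 pA pulses always detected
})

test_that("slow excursions violating the onset window are rejected", {
  # 2-s linear rise to 6 pA and back: large amplitude but no fast change
  rate <- 1000
  x <- c(numeric(500), seq(0, 6, length.out = 1000),
         seq(6, 0, length.out = 1000), numeric(500))
  ev <- detect_channel_events(current_trace(x, rate))
  expect_false(any(ev$kind == "channel_event"))
})

test_that("contact and rupture detection behave per their thresholds", {
  flat <- current_trace(rnorm(2000, sd = 0.5), 1000)
  expect_true(is.na(detect_contact(flat)))

  tr <- square_pulse_trace(500, 0.05, onset = 1)
  expect_equal(detect_contact(tr), 1)
  expect_true(is.na(detect_contact(tr, contact_config(
    contact_threshold = 600))))
  # a returning contact-sized transient is labeled contact_transient
  ev <- detect_channel_events(tr)
  expect_equal(ev$kind, "contact_transient")

  rup <- current_trace(rep(500, 3000), 1000)
  expect_true(detect_rupture(rup))
  expect_false(detect_rupture(square_pulse_trace(500, 0.5)))
})

test_that("window decision requires a channel-kind event", {
  expect_false(decide_window(NULL))
  empty <- detect_channel_events(current_trace(numeric(0), 1000))
  expect_equal(nrow(empty), 0L)
  expect_false(decide_window(empty))
  expect_true(decide_window(data.frame(kind = "channel_event")))
  expect_false(decide_window(data.frame(
    kind = c("contact_transient", "background_spike"))))
})

test_that("gated traces at both polarities yield channel events", {
  sc <- test_scenario(g = 90, mean_open = 20, mean_closed = 180)
  for (v in c(-60, 60)) {
    tr <- render_trace(sc, v, 10, noise_spec(), rate = 1000, seed = 3)
    ev <- detect_channel_events(tr)
    ch <- ev[ev$kind == "channel_event", ]
    expect_gt(nrow(ch), 3)
    # event polarity follows the sign convention
    expect_true(all(sign(ch$amplitude) == sign(v)))
  }
})
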