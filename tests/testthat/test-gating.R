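test_that("dwell sequences have the requested exponential structure", {
  # zero-length request
  d0 <- draw_dwell_sequence(50, 50, 0)
  expect_equal(nrow(d0), 0L)

  d <- draw_dwell_sequence(50, 50, 100, seed = 11)
  # alternation
  expect_true(all(d$state[-1] != d$state[-nrow(d)]))
  expect_gte(sum(d$duration), 100)
  # >= 1000 dwells at these kinetics; sample mean within 5 % of 50 ms
  opens <- d$duration[d$state == "open"] * 1000
  expect_gt(length(opens), 1000)
  expect_lt(abs(mean(opens) - 50) / 50, 0.05)
  closed <- d$duration[d$state == "closed"] * 1000
  expect_lt(abs(mean(closed) - 50) / 50, 0.05)

  # fraction-open converges to the stationary open probability
  d2 <- draw_dwell_sequence(50, 50, 1000, seed = 12)
  fo <- sum(d2$duration[d2$state == "open"]) / sum(d2$duration)
  expect_lt(abs(fo - 0.5), 0.02)

  # asymmetric kinetics
  d3 <- draw_dwell_sequence(20, 180, 1000, seed = 13)
  fo3 <- sum(d3$duration[d3$state == "open"]) / sum(d3$duration)
  expect_lt(abs(fo3 - 0.1), 0.02)

  expect_error(draw_dwell_sequence(-1, 50, 10), "mean_open")
  expect_error(draw_dwell_sequence(50, 0, 10), "mean_closed")
  expect_error(draw_dwell_sequence(50, 50, -1), "duration")
})

test_that("zero-truncated Poisson sampling matches brute-force pmf", {
  # brute-force pmf from the factorial formula
  lam <- 0.6
  brute <- exp(-lam) * lam^(1:6) / factorial(1:6) / (1 - exp(-lam))
  expect_equal(ztpois_pmf(1:6, lam), brute)
  expect_equal(sum(ztpois_pmf(1:50, lam)), 1)
  # values the truncated law implies at lambda 0.6
  expect_equal(brute[1], 0.7298, tolerance = 1e-4)
  expect_equal(brute[2], 0.2189, tolerance = 1e-3)

  k <- sample_channel_count(lam, seed = 5, n = 20000)
  expect_true(all(k >= 1))
  freq <- tabulate(k, 6) / length(k)
  expect_equal(freq, brute, tolerance = 0.02)

  # lambda -> 0+: nearly all mass on 1
  expect_gt(ztpois_pmf(1, 1e-6), 1 - 1e-5)
  expect_error(sample_channel_count(0), "lambda")
  expect_error(sample_channel_count(-2), "lambda")
})

test_that("rendered traces obey the unitary-current arithmetic", {
  sc <- test_scenario(g = 103.6)
  tr <- render_trace(sc, voltage = 100, duration = 2, noise = noise_off(),
                     rate = 1000, seed = 1)
  # noiseless samples are exact multiples of g*(V - E)/1000
  expect_true(all(abs(tr$samples - tr$levels * 10.36) < 1e-12))
  expect_setequal(unique(tr$levels), c(0L, 1L))

  # sign symmetry at negative voltage
  trn <- render_trace(sc, voltage = -100, duration = 2, noise = noise_off(),
                      rate = 1000, seed = 1)
  expect_equal(sort(unique(round(trn$samples, 10))), c(-10.36, 0))

  # zero conductance: flat trace
  tr0 <- render_trace(test_scenario(g = 0), voltage = 100, duration = 1,
                      noise = noise_off(), rate = 1000, seed = 1)
  expect_equal(max(abs(tr0$samples)), 0)

  # multi-channel superposition: levels up to the channel count
  tr3 <- render_trace(test_scenario(g = 100, n_channels = 3), voltage = 100,
                      duration = 10, noise = noise_off(), rate = 1000,
                      seed = 2)
  expect_lte(max(tr3$levels), 3L)
  expect_gte(max(tr3$levels), 2L)  # symmetric kinetics overlap a lot
  expect_true(all(abs(tr3$samples - tr3$levels * 10) < 1e-12))
})

test_that("identical seeds reproduce traces bit-for-bit", {
  sc <- scenario_preset("kcsa_e71a_decane")
  a <- render_trace(sc, 100, 2, noise_spec(), rate = 1000, seed = 99)
  b <- render_trace(sc, 100, 2, noise_spec(), rate = 1000, seed = 99)
  expect_identical(a$samples, b$samples)
  c <- render_trace(sc, 100, 2, noise_spec(), rate = 1000, seed = 100)
  expect_false(identical(a$samples, c$samples))
})

test_that("scenario kinetics are kept mutually consistent", {
  s1 <- channel_scenario("x", 100, open_prob = 0.85, mean_open = 100)
  expect_equal(s1$mean_closed, 100 * 0.15 / 0.85)
  s2 <- channel_scenario("x", 100, mean_open = 20, mean_closed = 180)
  expect_equal(s2$open_prob, 0.1)
  s3 <- channel_scenario("x", 100, open_prob = 0.25, mean_closed = 90)
  expect_equal(s3$mean_open, 30)
  expect_error(channel_scenario("x", 100, open_prob = 0.5, mean_open = 10,
                                mean_closed = 30), "inconsistent")
  expect_error(channel_scenario("x", 100, open_prob = 0.5), "at least two")
  expect_error(channel_scenario("x", -5, open_prob = 0.5, mean_open = 10),
               "conductance_g")
})

test_that("presets carry the published conductances", {
  expect_setequal(scenario_preset(),
                  c("kcsa_e71a_decane", "kcsa_e71a_hexadecane",
                    "kcsa_wt_control", "kcsa_wt_tea"))
  g <- vapply(scenario_preset(), function(p)
    scenario_preset(p)$conductance_g, numeric(1))
  expect_equal(unname(g[c("kcsa_e71a_decane", "kcsa_e71a_hexadecane",
                          "kcsa_wt_control", "kcsa_wt_tea")]),
               c(103.6, 127.6, 90.2, 52.2))
  expect_error(scenario_preset("nope"), "unknown scenario")
})

test_that("acquisition streams respect depth causality", {
  sp <- timing_stream_spec()
  st <- acquisition_stream(sp, seed = 1)
  shallow <- function(tt) rep(1000, length(tt))
  ch <- st$chunk(0, 2, shallow)
  # never reached contact depth: no transient, quiet current
  expect_lt(max(abs(ch$samples)), 100)

  st2 <- acquisition_stream(sp, seed = 1)
  descend <- function(tt) 260 * tt
  # transient onset at contact_depth / speed = 10 s
  ch2 <- st2$chunk(9.8, 0.5, descend)
  i_hit <- which(abs(ch2$samples) > 100)[1]
  expect_equal(ch2$t0 + (i_hit - 1) / ch2$rate, 10, tolerance = 1e-6)

  # between contact and formation: baseline only (transient already fired)
  st2$chunk(10.3, 0.2, descend)
  mid <- function(tt) rep(2620, length(tt))
  ch3 <- st2$chunk(12, 2, mid)
  expect_lt(max(abs(ch3$samples)), 2)

  # at/below formation depth: gated current appears
  deep <- function(tt) rep(2650, length(tt))
  ch4 <- st2$chunk(14, 2, deep)
  expect_gt(max(abs(ch4$samples)), 2)
})
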