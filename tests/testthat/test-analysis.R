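test_that("idealization recovers noiseless dwell structures exactly", {
  # flat trace: all level 0, no open dwells
  flat <- current_trace(numeric(2000), 1000)
  id0 <- idealize(flat, unitary_guess = 5)
  expect_equal(count_open_levels(id0), 0L)
  expect_error(unitary_amplitude(id0, flat), "no open dwells")

  # 10 noiseless square pulses: exactly 10 open dwells, exact durations
  rate <- 1000
  x <- numeric(10000)
  for (p in 0:9) x[(p * 1000 + 101):(p * 1000 + 300)] <- 5
  tr <- current_trace(x, rate)
  id <- idealize(tr, 5)
  open <- id$dwells[id$dwells$level == 1L, ]
  expect_equal(nrow(open), 10L)
  expect_equal(open$duration, rep(0.2, 10))
  expect_equal(unitary_amplitude(id, tr), 5)

  # rendered gating trace: idealized levels equal the generator's truth
  # everywhere except inside sub-threshold dwells, which are merged by
  # design (missed-event threshold of 2 samples)
  sc <- test_scenario(g = 100)
  tr2 <- render_trace(sc, -80, 10, noise_off(), rate = 1000, seed = 21)
  id2 <- idealize(tr2, unitary_guess = -8)
  r <- rle(tr2$levels)
  resolvable <- inverse.rle(list(values = r$lengths >= 2,
                                 lengths = r$lengths))
  expect_equal(id2$levels[resolvable], tr2$levels[resolvable])
  expect_lt(mean(id2$levels != tr2$levels), 0.005)
  # sub-threshold dwell merging perturbs the amplitude only marginally
  expect_equal(unitary_amplitude(id2, tr2), -8, tolerance = 1e-3)
})

test_that("idealization handles superposed channels and classification", {
  sc3 <- test_scenario(g = 100, n_channels = 3)
  tr <- render_trace(sc3, 100, 20, noise_off(), rate = 1000, seed = 8)
  id <- idealize(tr, 10)
  r <- rle(tr$levels)
  resolvable <- inverse.rle(list(values = r$lengths >= 2,
                                 lengths = r$lengths))
  expect_equal(id$levels[resolvable], tr$levels[resolvable])
  expect_equal(count_open_levels(id), max(tr$levels))
  expect_gte(count_open_levels(id), 2L)
  expect_equal(classify_channel_count(c(0, 1, 2, 3, 5)),
               c("none", "single", "double", "multiple", "multiple"))
})

test_that("amplitude estimation tolerates noise, drift, and a coarse guess", {
  sc <- test_scenario(g = 100)
  tr <- render_trace(sc, 50, 20, noise_spec(), rate = 10000, seed = 31)
  # true unitary current 5 pA; guess off by 30 %
  id <- idealize(tr, 6.5)
  expect_equal(unitary_amplitude(id, tr), 5, tolerance = 0.02)
  # negative polarity with drift
  trn <- render_trace(sc, -50, 20, noise_spec(), rate = 10000, seed = 32)
  idn <- idealize(trn, -4)
  expect_equal(unitary_amplitude(idn, trn), -5, tolerance = 0.02)
  # data-driven seed estimate lands near the truth
  u0 <- estimate_unitary(tr)
  expect_equal(u0, 5, tolerance = 0.25)
  expect_equal(sign(estimate_unitary(trn)), -1)
})

test_that("I-V fits reproduce exact lines and the normal-equations oracle", {
  v <- seq(-100, 100, 20)
  exact <- data.frame(voltage = v, unitary_pA = 0.1 * v)
  f <- fit_iv(exact)
  expect_equal(f$conductance_pS, 100)
  expect_equal(f$intercept_pA, 0)
  expect_equal(f$r2, 1)

  off <- data.frame(voltage = v, unitary_pA = 0.1 * v + 0.5)
  f2 <- fit_iv(off)
  expect_equal(f2$conductance_pS, 100)
  expect_equal(f2$intercept_pA, 0.5)

  set.seed(17)
  for (rep in 1:5) {
    vv <- sample(v, 7)
    yy <- 0.09 * vv + rnorm(7, sd = 0.4)
    got <- fit_iv(data.frame(voltage = vv, unitary_pA = yy))
    X <- cbind(1, vv)
    beta <- solve(t(X) %*% X, t(X) %*% yy)  # brute-force normal equations
    expect_equal(got$intercept_pA, beta[1], tolerance = 1e-10)
    expect_equal(got$conductance_pS, beta[2] * 1000, tolerance = 1e-10)
  }

  expect_error(fit_iv(data.frame(voltage = c(10, 10),
                                 unitary_pA = c(1, 2))),
               "distinct voltages")
  # NA amplitudes (undetectable voltages) are dropped, not propagated
  with_na <- data.frame(voltage = v, unitary_pA = 0.1 * v)
  with_na$unitary_pA[v == 0] <- NA
  expect_equal(fit_iv(with_na)$conductance_pS, 100)
  expect_equal(fit_iv(with_na)$n_points, 10)
})

test_that("membrane area follows the capacitance arithmetic", {
  expect_identical(membrane_area(1, 0.4), 0.25)
  expect_identical(membrane_area(0, 0.7), 0)
  expect_identical(membrane_area(2, 0.5), 0.4)
  # exactly linear in C, inversely proportional to specific capacitance
  expect_equal(membrane_area(3, 0.4), 3 * membrane_area(1, 0.4))
  expect_equal(membrane_area(1, 0.8), membrane_area(1, 0.4) / 2)
  expect_error(membrane_area(1, 0), "specific_uF_cm2")
  expect_error(membrane_area(-1, 0.4), "capacitance_nF")
})

test_that("Welch statistic matches independent oracles", {
  # identical groups
  w0 <- welch_t_from_summary(5, 1, 4, 5, 1, 4)
  expect_equal(w0$t, 0)
  # frozen oracle: scipy ttest_ind_from_stats(90.2, 26.4, 7, 52.2, 9.1, 5)
  w <- welch_t_from_summary(90.2, 26.4, 7, 52.2, 9.1, 5)
  expect_equal(w$t, 3.526271, tolerance = 1e-6)
  expect_equal(w$df, 7.836861, tolerance = 1e-6)
  # doubling both n scales |t| by sqrt(2)
  w2 <- welch_t_from_summary(90.2, 26.4, 14, 52.2, 9.1, 10)
  expect_equal(w2$t / w$t, sqrt(2), tolerance = 1e-12)
  # agrees with t.test on raw data via the summary route
  set.seed(3)
  a <- rnorm(8, 10, 2); b <- rnorm(6, 7, 3)
  ref <- t.test(a, b)
  got <- welch_t_from_summary(mean(a), sd(a), 8, mean(b), sd(b), 6)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p, ref$p.value)
  # zero-variance branches
  expect_equal(welch_t_from_summary(1, 0, 3, 1, 0, 3)$t, 0)
  expect_true(is.infinite(welch_t_from_summary(2, 0, 3, 1, 0, 3)$t))
})

test_that("condition comparison reports ratio and Welch test", {
  idt <- compare_conditions(c(90, 91, 89), c(90, 91, 89))
  expect_equal(idt$conductance_ratio, 1)
  expect_equal(idt$welch_t, 0)

  cmp <- compare_conditions(c(88, 92, 90.6), c(51, 53.5, 52))
  expect_equal(cmp$conductance_ratio, mean(c(51, 53.5, 52)) / 90.2,
               tolerance = 1e-12)
  expect_lt(cmp$conductance_ratio, 1)
  expect_gt(cmp$welch_t, 0)
  expect_error(compare_conditions(c(90, 91), 52), "per condition")
})
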