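test_that("peaks of a sine are found at its analytic maxima", {
  t <- 0:350
  tr <- intensity_trace(t, sin(2 * pi * t / 100), time_unit = "s")
  pk <- detect_peaks(tr, min_prominence_fraction = 0.2, min_distance = 30)
  expect_equal(pk$n, 4)
  expect_equal(pk$peak_times, c(25, 125, 225, 325), tolerance = 0.02)
})

test_that("degenerate traces yield empty peak series", {
  con <- intensity_trace(0:100, rep(1, 101), time_unit = "s")
  expect_equal(detect_peaks(con)$n, 0)
  short <- intensity_trace(c(0, 1), c(0, 1), time_unit = "s")
  expect_warning(pk <- detect_peaks(short), "shorter")
  expect_equal(pk$n, 0)
})

test_that("prominence filtering ignores small wiggles riding on pulses", {
  t <- seq(0, 1000, 1)
  base <- exp(-((t %% 200) - 100)^2 / (2 * 15^2)) # one pulse per 200 s
  wiggle <- 0.05 * sin(2 * pi * t / 15)
  tr <- intensity_trace(t, base + wiggle, time_unit = "s")
  pk <- detect_peaks(tr, min_prominence_fraction = 0.2, min_distance = 30)
  expect_equal(pk$n, 5)
})

test_that("interval statistics summarize peak spacings as mean/SD/n", {
  st <- interval_statistics(c(10, 120, 230, 340))
  expect_equal(st$mean, 110)
  expect_equal(st$sd, 0)
  expect_equal(st$n, 3)
  one <- interval_statistics(c(0, 100))
  expect_equal(one$mean, 100)
  expect_equal(one$n, 1)
  expect_true(is.na(one$sd))
  none <- interval_statistics(numeric(0))
  expect_equal(none$n, 0)
  expect_true(is.na(none$mean))
})

test_that("interval statistics are invariant to trace shifts and scaling", {
  g <- generate_pulse_trace(pulse_train_spec(n_pulses = 30, seed = 5,
                                             noise_sd = 2))
  s0 <- interval_statistics(detect_peaks(g$trace))
  shifted <- intensity_trace(g$trace$times + 500, 3 * g$trace$values + 40,
                             time_unit = "s")
  s1 <- interval_statistics(detect_peaks(shifted))
  expect_equal(s1$mean, s0$mean)
  expect_equal(s1$sd, s0$sd)
  expect_equal(s1$n, s0$n)
})

test_that("relative-frequency histograms bin left-closed and sum to one", {
  h <- relative_frequency_histogram(c(100, 100, 140), bin_width = 20)
  f <- function(x) h$relative_frequencies[findInterval(x, h$bin_edges)]
  expect_equal(f(100), 2 / 3)
  expect_equal(f(140), 1 / 3)
  expect_equal(sum(h$relative_frequencies), 1)
  h1 <- relative_frequency_histogram(55, bin_width = 20)
  expect_equal(h1$relative_frequencies, 1)
  h0 <- relative_frequency_histogram(interval_statistics(numeric(0)))
  expect_length(h0$relative_frequencies, 0)
})

test_that("pearson correlation handles exact and undefined cases", {
  tr <- function(v) intensity_trace(seq_along(v), v, time_unit = "s")
  expect_equal(pearson_correlation(tr(c(1, 2, 3)), tr(c(3, 2, 1))), -1)
  a <- sine_trace(period = 100, duration = 1000, dt = 1)
  expect_equal(pearson_correlation(a, a), 1)
  b <- sine_trace(period = 100, duration = 1000, dt = 1, phase = pi)
  expect_equal(pearson_correlation(a, b, window = c(0, 400)), -1,
               tolerance = 1e-6)
  flat <- intensity_trace(a$times, rep(2, length(a$times)), time_unit = "s")
  expect_true(is.na(pearson_correlation(a, flat)))
})

test_that("windowed correlation tracks a known change point", {
  a <- sine_trace(period = 100, duration = 900, dt = 1)
  expect_true(all(windowed_correlation(a, a, 200, 100)$correlation == 1))
  # non-overlapping windows: floor(duration / window) of them
  wc <- windowed_correlation(a, a, 300, 300)
  expect_equal(nrow(wc), 3)
  # uncoordinated then anti-phase, via the entrainment generator
  g <- generate_entrainment_sequence(
    pulse_train_spec(seed = 2, noise_sd = 3), 1,
    segment_durations = c(800, 100, 900))
  wc2 <- windowed_correlation(g$trace1, g$trace2, 300, 100)
  early <- wc2$correlation[wc2$center < 700]
  late <- wc2$correlation[wc2$center > 1100]
  expect_lt(max(abs(early)), 0.5)
  expect_lt(mean(late), -0.3)
})

test_that("phase relation classifies sines exactly", {
  a <- sine_trace(period = 100, duration = 1000, dt = 2)
  pr <- phase_relation(a, a)
  expect_equal(pr$label, "in-phase")
  expect_equal(pr$lag_fraction, 0)
  b <- sine_trace(period = 100, duration = 1000, dt = 2, phase = pi)
  pr2 <- phase_relation(a, b)
  expect_equal(pr2$label, "anti-phase")
  expect_equal(pr2$lag_fraction, 0.5, tolerance = 0.02)
  # hilbert method agrees on clean oscillations
  expect_equal(phase_relation(a, b, method = "hilbert")$lag_fraction, 0.5,
               tolerance = 0.02)
})

test_that("phase relation is symmetric: lags of (a,b) and (b,a) sum to 1", {
  a <- sine_trace(period = 100, duration = 1000, dt = 2)
  b <- sine_trace(period = 100, duration = 1000, dt = 2, phase = 0.6 * pi)
  f1 <- phase_relation(a, b)$lag_fraction
  f2 <- phase_relation(b, a)$lag_fraction
  expect_equal((f1 + f2) %% 1, 0, tolerance = 0.03)
})

test_that("non-oscillatory input is labelled uncoordinated with a diagnostic", {
  a <- sine_trace(period = 100, duration = 1000, dt = 2)
  flat <- intensity_trace(a$times, rep(1, length(a$times)), time_unit = "s")
  pr <- phase_relation(a, flat)
  expect_equal(pr$label, "uncoordinated")
  expect_match(pr$diagnostic, "non-oscillatory")
})

test_that("independently jittered trains are mostly uncoordinated", {
  votes <- sapply(1:20, function(s) {
    g <- generate_pair(pulse_train_spec(n_pulses = 15, seed = s),
                       shared_jitter = FALSE)
    phase_relation(g$trace1, g$trace2)$label
  })
  expect_gt(mean(votes == "uncoordinated"), 0.5)
})

test_that("the slowdown statistic is the stated interval ratio", {
  # pre mean 100 s, transition mean 150 s, post mean 110 s -> 150/105
  pk <- cumsum(c(50, rep(100, 5), rep(150, 5), rep(110, 5)))
  pre <- c(0, 550); tra <- c(551, 1300); post <- c(1301, 2000)
  r <- slowdown_statistic(pk, pk, pre, tra, post)
  expect_equal(r$ratio, 150 / 105, tolerance = 1e-12)
  same <- cumsum(rep(100, 20))
  r1 <- slowdown_statistic(same, same, c(0, 600), c(600, 1300), c(1300, 2000))
  expect_equal(r1$ratio, 1)
  w <- capture_warnings(
    r2 <- slowdown_statistic(c(1, 2), c(1, 2), c(0, 0.5), c(0.5, 1.5),
                             c(1.5, 3)))
  expect_match(w, "insufficient", all = TRUE)
  expect_true(is.na(r2$ratio))
})

test_that("peak counts are stable under mild measurement noise", {
  spec0 <- pulse_train_spec(n_pulses = 50, period_sd = 10, seed = 9)
  clean <- detect_peaks(generate_pulse_trace(spec0)$trace)$n
  spec5 <- pulse_train_spec(n_pulses = 50, period_sd = 10, seed = 9,
                            noise_sd = 5) # 5% of amplitude 100
  noisy <- detect_peaks(generate_pulse_trace(spec5)$trace)$n
  expect_lte(abs(noisy - clean), 1)
})

test_that("episode onsets count plateau switches, not plateau noise", {
  t <- seq(0, 100, 0.1)
  square <- ifelse((t %% 20) < 10, 1, 0) + 0.02 * sin(20 * t)
  tr <- intensity_trace(t, square, time_unit = "model")
  expect_equal(length(detect_episodes(tr)), 5)
})
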