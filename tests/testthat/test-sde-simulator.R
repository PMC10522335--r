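test_that("a deterministic Euler step matches hand arithmetic", {
  p <- default_parameters()
  s <- em_step(initial_state(), p, d = 10, dt = 0.001, noise_mode = "off")
  # A1 + 8.48 * driftA1 * 0.001 and Z1 + 8.48 * (-0.7065) * 0.001
  expect_equal(unname(s["A1"]), 0.7124916022, tolerance = 1e-9)
  expect_equal(unname(s["Z1"]), 0.9940088800, tolerance = 1e-9)
})

test_that("a zero step leaves any state unchanged", {
  set.seed(3)
  u <- random_nonneg_state()
  s <- em_step(u, default_parameters(), dt = 0, noise_mode = "as-printed")
  expect_equal(unname(s), unname(u))
})

test_that("stochastic steps are reproducible under an identical seed", {
  p <- default_parameters()
  set.seed(99)
  s1 <- em_step(initial_state(), p, dt = 0.001)
  set.seed(99)
  s2 <- em_step(initial_state(), p, dt = 0.001)
  expect_identical(s1, s2)
})

test_that("deterministic trajectories are bitwise reproducible and seed-free", {
  st <- simulation_settings(burn_in = 0, total_time = 5, noise_mode = "off")
  t1 <- simulate_dialog(settings = st, schedule = 0)
  st$seed <- 123
  t2 <- simulate_dialog(settings = st, schedule = 0)
  expect_identical(t1$states, t2$states)
})

test_that("identically seeded stochastic runs are identical", {
  st <- simulation_settings(seed = 5, burn_in = 10, total_time = 10)
  t1 <- simulate_dialog(settings = st, schedule = 0)
  t2 <- simulate_dialog(settings = st, schedule = 0)
  expect_identical(t1$states, t2$states)
  t3 <- simulate_dialog(settings = simulation_settings(seed = 6,
                                                       burn_in = 10,
                                                       total_time = 10),
                        schedule = 0)
  expect_false(identical(t1$states, t3$states))
})

test_that("trajectory bookkeeping: grid, stride and record counts", {
  st <- simulation_settings(burn_in = 0, total_time = 0.1,
                            record_stride = 100, noise_mode = "off")
  tr <- simulate_dialog(settings = st)
  expect_equal(length(tr$times), 2) # t = 0 and one stride block
  expect_equal(tr$times, c(0, 0.1))
  st2 <- simulation_settings(burn_in = 1, total_time = 3, seed = 1)
  tr2 <- simulate_dialog(settings = st2)
  expect_equal(length(tr2$times), 31)
  expect_equal(diff(tr2$times), rep(0.1, 30), tolerance = 1e-12)
  expect_equal(nrow(tr2$states), 31)
})

test_that("the deterministic trajectory agrees with a finer-step RK oracle", {
  p <- default_parameters()
  times <- seq(0, 20, 0.1)
  ora <- rk_oracle(p, d = 0, times, hini = 1e-4)
  tr <- simulate_dialog(p, simulation_settings(burn_in = 0, total_time = 20,
                                               noise_mode = "off"),
                        schedule = 0)
  expect_lt(max(abs(ora - tr$states)), 0.1)
})

test_that("step halving shrinks the deterministic discrepancy", {
  cc1 <- deterministic_convergence_check(schedule = 0, total_time = 10,
                                         dt = 0.002)
  cc2 <- deterministic_convergence_check(schedule = 0, total_time = 10,
                                         dt = 0.001)
  expect_lt(cc1$max_discrepancy, 0.1)
  expect_lt(cc2$max_discrepancy, cc1$max_discrepancy)
})

test_that("mirrored noise keeps the two identical cells perfectly correlated", {
  st <- simulation_settings(seed = 4, burn_in = 50, total_time = 30,
                            mirror_noise = TRUE)
  tr <- simulate_dialog(settings = st, schedule = 3)
  expect_equal(tr$states[, "A1"], tr$states[, "A2"])
  expect_equal(stats::cor(tr$states[, "A1"], tr$states[, "A2"]), 1)
})

test_that("per-channel and aggregated draws give matching noise magnitude", {
  sd_of <- function(per_channel) {
    st <- simulation_settings(seed = 21, burn_in = 60, total_time = 20,
                              per_channel = per_channel)
    p <- default_parameters(omega = 1e5) # quiescent: fluctuations only
    stats::sd(simulate_dialog(p, st, schedule = 10)$states[, "A1"])
  }
  r <- sd_of(TRUE) / sd_of(FALSE)
  expect_gt(r, 0.5)
  expect_lt(r, 2)
})

test_that("fluctuation size scales with the system size as the mode dictates", {
  sd_at <- function(om, mode, seed) {
    p <- default_parameters(omega = om)
    st <- simulation_settings(seed = seed, burn_in = 60, total_time = 20,
                              noise_mode = mode)
    stats::sd(simulate_dialog(p, st, schedule = 10)$states[, "A1"])
  }
  # chemical-langevin: amplitude ~ 1/sqrt(omega), so 4x omega halves the SD
  r_cl <- mean(sapply(1:8, function(s)
    sd_at(1e5, "chemical-langevin", s) /
      sd_at(4e5, "chemical-langevin", s + 100)))
  expect_gt(r_cl, 1.6)
  expect_lt(r_cl, 2.4)
  # as-printed: amplitude ~ 1/omega, so 4x omega quarters the SD
  r_ap <- mean(sapply(1:8, function(s)
    sd_at(1e5, "as-printed", s) / sd_at(4e5, "as-printed", s + 100)))
  expect_gt(r_ap, 3.2)
  expect_lt(r_ap, 4.8)
})

test_that("ramp schedules evaluate correctly and drive the integrator", {
  s <- ramp_schedule(10, 0, ramp_start = 0, ramp_end = 30)
  expect_equal(s$evaluate(c(-5, 0, 15, 30, 50)), c(10, 10, 5, 0, 0))
  pw <- piecewise_schedule(c(0, 10, 20), c(10, 4, 0))
  expect_equal(pw$evaluate(c(0, 5, 15, 25)), c(10, 7, 2, 0))
  expect_error(ramp_schedule(10, 0, 5, 5), "exceed")
  expect_error(piecewise_schedule(c(0, 0), c(1, 2)), "increasing")
  # a degenerate ramp equals a constant run under the same seed
  st <- simulation_settings(seed = 8, burn_in = 5, total_time = 5)
  t1 <- simulate_dialog(settings = st,
                        schedule = ramp_schedule(2, 2, 0, 1))
  t2 <- simulate_dialog(settings = st, schedule = constant_schedule(2))
  expect_identical(t1$states, t2$states)
})
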