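test_that("default parameters reproduce the published constant set", {
  p <- default_parameters()
  expect_s3_class(p, "dialog_params")
  expect_equal(p$tau, 8.48)
  expect_equal(p$epsilon, 0.55)
  expect_equal(p$alpha, 12.4)
  expect_equal(p$beta, 8.05)
  expect_equal(p$gamma, 8)
  expect_equal(p$k, 6)
  expect_equal(p$a0, 5.6)
  expect_equal(p$i0, 0.1)
  expect_equal(p$x0, 1.0)
  expect_equal(p$k1, 0.1)
  expect_equal(p$k2, 1.0)
  expect_equal(p$kz, 10.0)
  expect_equal(p$kcext, 5)
  expect_equal(p$cmedia, 1)
  expect_equal(p$d, 10)
  expect_equal(p$omega, 1000)
  # overriding every field with itself is the identity
  expect_equal(do.call(default_parameters, unclass(p)), p)
})

test_that("invalid parameters are rejected with named diagnostics", {
  expect_error(default_parameters(omega = -1), "omega")
  expect_error(default_parameters(cmedia = -0.1), "cmedia")
  expect_error(default_parameters(tau = 0), "tau")
  expect_error(default_parameters(nonsense = 1), "nonsense")
})

test_that("drift at the canonical initial state matches hand arithmetic", {
  u0 <- initial_state()
  f <- drift(u0, default_parameters())
  # a0 - alpha*A + beta*A^2 - A^3 - A*I + A*Z at A=0.7065, I=0.7145, Z=1
  expect_equal(unname(f["A1"]), 0.706556862875, tolerance = 1e-10)
  # eps*(i0 + gamma*A^2/(A^2+k) - I): nearly balanced at the initial state
  expect_equal(unname(f["I1"]), -4.9499138713e-05, tolerance = 1e-6)
  # X1 = 0 kills the consumption term, leaving x0
  expect_equal(unname(f["X1"]), 1.0)
  expect_equal(unname(f["Y1"]), 0.0)
  # Z exchange vanishes (Z1 = Z2 and Z = Cmedia), leaving -A*Z
  expect_equal(unname(f["Z1"]), -0.7065)
  # both cells start identically
  expect_equal(unname(f[1:5]), unname(f[6:10]))
})

test_that("drift rejects non-finite states naming the offender", {
  u <- initial_state()
  u["Y2"] <- NaN
  expect_error(drift(u, default_parameters()), "Y2")
})

test_that("drift is equivariant under swapping the two cells", {
  set.seed(42)
  swap <- c(6:10, 1:5)
  p <- default_parameters()
  for (i in 1:5) {
    u <- random_nonneg_state()
    expect_equal(unname(drift(u[swap], p, d = 2)),
                 unname(drift(u, p, d = 2)[swap]))
  }
})

test_that("tip-to-tip exchange is conservative and vanishes at infinity", {
  set.seed(7)
  p <- default_parameters()
  for (i in 1:5) {
    u <- random_nonneg_state()
    f0 <- drift(u, p, d = 0)
    f5 <- drift(u, p, d = 5)
    # the coupling terms cancel in the Z sum, so it cannot depend on d
    expect_equal(f0["Z1"] + f0["Z2"], f5["Z1"] + f5["Z2"])
    # decoupling limit: far-apart drift equals the uncoupled system
    finf <- drift(u, p, d = 700)
    fun <- drift(u, p, d = 0) # reference with the coupling removed by hand
    fun["Z1"] <- fun["Z1"] - p$kz * (u[10] - u[5])
    fun["Z2"] <- fun["Z2"] - p$kz * (u[5] - u[10])
    expect_equal(unname(finf), unname(fun), tolerance = 1e-12)
  }
})

test_that("noise propensities follow the printed channel layout", {
  g <- noise_propensities(initial_state(), default_parameters(), d = 10)
  expect_equal(nrow(g), 38)
  counts <- table(g$cell, g$target_variable)
  expect_equal(unname(counts["1", c("A", "I", "X", "Y", "Z")]),
               c(6, 3, 2, 2, 6))
  a1 <- g[g$cell == 1 & g$target_variable == "A", "propensity"]
  expect_true(any(abs(a1 - 5.6) < 1e-12))          # a0 channel
  expect_true(any(abs(a1 - 0.7065) < 1e-12))       # A1*Z1 channel
  # Y channels vanish at the canonical state (X1 = Y1 = 0)
  expect_equal(g[g$cell == 1 & g$target_variable == "Y", "propensity"],
               c(0, 0))
  # the shared release term keeps distinct channel indices in Y and Z rows
  z1 <- g[g$cell == 1 & g$target_variable == "Z", "channel_index"]
  y1 <- g[g$cell == 1 & g$target_variable == "Y", "channel_index"]
  expect_length(intersect(z1, y1), 0)
})

test_that("only constant channels survive at the zero state", {
  p <- default_parameters()
  g <- noise_propensities(rep(0, 10), p, d = 1)
  const <- g$propensity[g$propensity > 0]
  expect_setequal(round(const, 10),
                  round(c(p$a0, p$epsilon * p$i0, p$x0,
                          p$kcext * p$cmedia), 10))
})

test_that("all propensities are nonnegative on the nonnegative orthant", {
  set.seed(11)
  p <- default_parameters()
  for (i in 1:10) {
    g <- noise_propensities(random_nonneg_state(), p,
                            d = stats::runif(1, 0, 10))
    expect_true(all(g$propensity >= 0))
  }
})

test_that("coupling rate is kz * exp(-d)", {
  p <- default_parameters()
  expect_equal(coupling_rate(p, d = 0), 10.0)
  expect_equal(coupling_rate(p, d = 10), 10 * exp(-10), tolerance = 1e-12)
  expect_equal(coupling_rate(p, d = 10), 4.54e-4, tolerance = 1e-3)
  expect_lt(coupling_rate(p, d = 500), 1e-200)
  expect_error(coupling_rate(p, d = -1), ">= 0")
})
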