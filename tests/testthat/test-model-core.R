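# The two-epoch coalescent core: coalescence-time density, closed-form
# mismatch pmf, expectation.

test_that("coalescence-time density has the stated piecewise form and mass 1", {
  # t0 = 0 collapses to a constant-size exponential with rate 1/(2*N0)
  expect_equal(coalescence_time_density(0, t0 = 0, N0 = 1, N1 = 5), 0.5)

  # normalisation for a generic expansion
  total <- integrate(coalescence_time_density, 0, Inf,
                     t0 = 100, N0 = 50, N1 = 1000,
                     rel.tol = 1e-12)$value
  expect_equal(total, 1, tolerance = 1e-9)

  # mass before the epoch boundary at t0 = 2*N1 is 1 - exp(-1)
  mass <- integrate(coalescence_time_density, 0, 2000,
                    t0 = 2000, N0 = 50, N1 = 1000, rel.tol = 1e-12)$value
  expect_equal(mass, 1 - exp(-1), tolerance = 1e-9)

  # continuity everywhere except the epoch boundary
  expect_equal(coalescence_time_density(99.999999, 100, 50, 1000),
               coalescence_time_density(99.9999991, 100, 50, 1000),
               tolerance = 1e-6)

  expect_error(coalescence_time_density(-1, 100, 50, 1000), "s")
  expect_error(coalescence_time_density(1, 100, -50, 1000), "positive|> 0")
})

test_that("mismatch pmf reduces to the geometric distribution in the limits", {
  # tau = 0: geometric in theta0 for all k
  p0 <- demography_params(0, 1, 10)
  expect_equal(mismatch_pmf(0, p0), 0.5)
  k <- 0:20
  expect_equal(mismatch_pmf(k, p0), (1 / 2) ^ k / 2, tolerance = 1e-12)

  # equal epoch sizes: geometric in theta for any tau
  expect_equal(mismatch_pmf(2, demography_params(3, 1, 1)), 0.125)
  for (tau in c(0, 0.5, 17)) {
    expect_equal(mismatch_pmf(k, demography_params(tau, 2, 2)),
                 (2 / 3) ^ k / 3, tolerance = 1e-10)
  }

  # tau -> infinity: geometric in theta1
  expect_equal(mismatch_pmf(k, demography_params(1e4, 0.5, 3)),
               (3 / 4) ^ k / 4, tolerance = 1e-10)
})

test_that("closed-form pmf agrees with quadrature of the defining integral", {
  # frozen from the quadrature oracle: k=3, tau=5, theta0=0.5, theta1=10
  expect_equal(mismatch_pmf(3, demography_params(5, 0.5, 10)),
               0.124252403, tolerance = 1e-8)

  set.seed(401)
  for (i in 1:12) {
    tau <- runif(1, 0, 50)
    th0 <- runif(1, 1e-3, 20)
    th1 <- runif(1, 1e-3, 20)
    par <- demography_params(tau, th0, th1)
    for (k in c(0L, 1L, 4L, 17L, 60L)) {
      expect_equal(mismatch_pmf(k, par), quad_mismatch_pmf(k, tau, th0, th1),
                   tolerance = 1e-8,
                   label = sprintf("pmf(k=%d; %.3f, %.3f, %.3f)",
                                   k, tau, th0, th1))
    }
  }
})

test_that("pmf is a normalised distribution and matches E(K)", {
  set.seed(402)
  for (i in 1:10) {
    par <- demography_params(runif(1, 0, 30), runif(1, 0.05, 15),
                             runif(1, 0.05, 15))
    k <- 0:mismatch_kmax(par, tol = 1e-12)
    p <- mismatch_pmf(k, par)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(sum(k * p), expected_mismatches(par), tolerance = 1e-8)
  }
})

test_that("expected mismatches follow the sudden-expansion formula", {
  expect_equal(expected_mismatches(demography_params(0, 0.7, 10)), 0.7)
  expect_equal(expected_mismatches(demography_params(17, 2, 2)), 2)
  p <- demography_params(5, 0.5, 10)
  expect_equal(expected_mismatches(p), 10 + (0.5 - 10) * exp(-0.5))
})

test_that("log pmf stays finite and stable at extreme parameters", {
  # tiny theta0: ancestral term must not corrupt normalisation
  for (th0 in c(1e-6, 1e-12, 1e-15)) {
    par <- demography_params(5.5, th0, 10)
    expect_equal(sum(mismatch_pmf(0:200, par)), 1, tolerance = 1e-9)
  }
  # large tau * (1 + 1/theta): no overflow, valid log values
  lp <- mismatch_log_pmf(0:50, demography_params(500, 0.01, 2))
  expect_true(all(is.finite(lp) | lp == -Inf))
  expect_true(all(lp <= 0))
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(demography_params(-1, 1, 1), "tau")
  expect_error(demography_params(1, 0, 1), "theta0")
  expect_error(demography_params(1, 1, Inf), "theta1")
  expect_error(mismatch_pmf(-1, demography_params(1, 1, 1)), "nonnegative")
  expect_error(mismatch_pmf(1.5, demography_params(1, 1, 1)), "integer")
})
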