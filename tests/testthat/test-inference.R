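# Composite-likelihood estimation, uncertainty, model comparison, and unit
# conversion.

test_that("disjoint pairing covers floor(n/2) pairs without reuse", {
  p2 <- make_disjoint_pairs(2, seed = 7)
  expect_equal(nrow(p2), 1L)
  expect_setequal(as.vector(p2), 1:2)

  p5 <- make_disjoint_pairs(5, seed = 7)
  expect_equal(nrow(p5), 2L)
  expect_equal(anyDuplicated(as.vector(p5)), 0L)

  for (seed in 1:5) {
    p7 <- make_disjoint_pairs(7, seed = seed)
    expect_equal(nrow(p7), 3L)
    expect_equal(anyDuplicated(as.vector(p7)), 0L)
    expect_true(all(as.vector(p7) %in% 1:7))
  }

  expect_identical(make_disjoint_pairs(100, seed = 3),
                   make_disjoint_pairs(100, seed = 3))
  expect_error(make_disjoint_pairs(1, seed = 1), "at least 2")
})

test_that("composite log-likelihood sums log pmf values and is additive", {
  expect_equal(composite_loglik(mismatch_sample(0L, 2L),
                                demography_params(0, 1, 10)),
               log(0.5))

  par <- demography_params(5, 0.5, 10)
  a <- mismatch_sample(c(0L, 3L, 7L))
  b <- mismatch_sample(c(2L, 2L))
  expect_equal(composite_loglik(mismatch_sample(c(a$counts, b$counts)), par),
               composite_loglik(a, par) + composite_loglik(b, par))

  # against the quadrature oracle
  expect_equal(composite_loglik(mismatch_sample(c(3L, 3L)), par),
               2 * log(quad_mismatch_pmf(3, 5, 0.5, 10)), tolerance = 1e-8)

  expect_error(composite_loglik(mismatch_sample(integer(0)), par))
})

test_that("fitting recovers simulated parameters and beats the truth's likelihood", {
  truth <- demography_params(5, 0.5, 10)
  s <- simulate_mismatch_counts(truth, n_pairs = 10000, seed = 301)
  fit <- fit_demography(s)
  expect_s3_class(fit, "demography_fit")
  expect_true(fit$converged)
  expect_lte(fit$loglik, 0)
  # MLE optimality: at least as good as the generating parameters
  expect_gte(fit$loglik, composite_loglik(s, truth) - 1e-6)
  expect_equal(fit$params$tau, 5, tolerance = 0.3)
  expect_equal(fit$params$theta1, 10, tolerance = 0.15 * 10)
  # well-identified replicate: SDs positive and finite where available
  avail <- !is.na(fit$sd)
  expect_true(any(avail))
  expect_true(all(fit$sd[avail] > 0 & is.finite(fit$sd[avail])))
})

test_that("an all-zero sample drives theta1 to the boundary with loglik near 0", {
  fit <- fit_demography(rep(0L, 50))
  expect_lte(fit$loglik, 0)
  expect_gt(fit$loglik, -1e-3)
  expect_lt(fit$params$theta1, 1e-3)
})

test_that("a flat theta0 ridge is reported with sd unavailable", {
  # expansion long ago relative to theta1: the ancestral epoch is
  # essentially unobserved, so theta0 is unidentified over decades
  s <- simulate_mismatch_counts(demography_params(33.8, 0.05, 0.217),
                                n_pairs = 2000, seed = 11)
  fit <- fit_demography(s, starts = list(c(30, 0.05, 0.25)))
  expect_true("theta0" %in% names(fit$flat_ridge))
  expect_true(is.na(fit$sd[["theta0"]]))
  iv <- fit$flat_ridge[["theta0"]]
  expect_lt(iv[["lower"]], iv[["upper"]])
  # flatness is real: loglik at the interval ends matches the optimum
  at <- function(th0) {
    p <- fit$params; p$theta0 <- th0
    composite_loglik(s, p)
  }
  expect_equal(at(iv[["lower"]]), fit$loglik, tolerance = 1e-6)
  expect_equal(at(iv[["upper"]]), fit$loglik, tolerance = 1e-6)
})

test_that("fit refuses undersized samples", {
  expect_error(fit_demography(rep(1L, 5)), "at least 10")
})

test_that("model comparison decides separate for distinct subsets, pooled on ties", {
  a <- simulate_mismatch_counts(demography_params(3, 1, 0.5), 2000,
                                seed = 51)$counts
  b <- simulate_mismatch_counts(demography_params(3, 1, 20), 2000,
                                seed = 951)$counts
  cmp <- compare_models(list(small = a, large = b))
  expect_equal(cmp$decision, "separate")
  expect_gt(cmp$separate_total_loglik, cmp$pooled$loglik)
  expect_named(cmp$per_subset, c("small", "large"))
  expect_equal(nrow(cmp$summary), 3L)
  expect_true(all(c("loglik", "n_pairs", "aic") %in% names(cmp$summary)))

  # one subset: pooled and separate coincide, tie broken toward pooled
  one <- compare_models(list(only = a))
  expect_equal(one$decision, "pooled")
  expect_equal(one$separate_total_loglik, one$pooled$loglik)
})

test_that("pooled pairing straddles subsets when sequences are supplied", {
  truth <- demography_params(4, 0.5, 4)
  ka <- simulate_mismatch_counts(truth, 30, seed = 61)
  kb <- simulate_mismatch_counts(truth, 30, seed = 62)
  sa <- emit_sequence_pairs(ka, seq_length = 381, seed = 63)
  sb <- emit_sequence_pairs(kb, seq_length = 381, seed = 64)
  cmp <- compare_models(list(a = sa, b = sb), seed = 9, min_pairs = 10)
  # pooled fit pairs the union: 120 phylotypes -> 60 pairs
  expect_equal(cmp$pooled$n_pairs, 60L)
  expect_equal(cmp$per_subset$a$n_pairs, 30L)
  expect_true(cmp$decision %in% c("pooled", "separate"))
})

test_that("unit conversion reproduces the worked cosmopolitan estimates", {
  rates <- rate_assumptions()
  expect_equal(rates$per_seq_rate, 2.08e-10 * 381)

  nat <- convert_units(demography_params(33.8, 0.108, 0.217), rates)
  # t0 = 33.8 / (2 * 7.9e-8) generations * 24/365 -> 1.4e7 years
  expect_equal(signif(nat$t0_years, 2), 1.4e7)
  expect_equal(signif(nat$N1, 2), 1.4e6)
  expect_equal(signif(nat$N0, 2), 6.8e5)

  # tau = 0 converts to time zero regardless of rates
  expect_equal(convert_units(demography_params(0, 1, 1), rates)$t0_years, 0)
})

test_that("range propagation takes the corner extremes of rate and generation", {
  rng <- propagate_ranges(tau = 33.8, rates = rate_assumptions())
  expect_equal(rng$reported$min_years, 3.6e6)
  expect_equal(rng$reported$max_years, 4.0e7)
  expect_lt(rng$min_years, rng$max_years)

  # corner evaluation equals a dense-grid extreme (monotone contract)
  rates <- rate_assumptions()
  grid <- expand.grid(
    u = seq(rates$per_site_ci[1], rates$per_site_ci[2], length.out = 25),
    g = seq(rates$generation_range[1], rates$generation_range[2],
            length.out = 25))
  t_grid <- 33.8 / (2 * grid$u * rates$seq_length) * grid$g / 365
  expect_equal(rng$min_years, min(t_grid), tolerance = 1e-12)
  expect_equal(rng$max_years, max(t_grid), tolerance = 1e-12)

  # collapsed ranges collapse the interval
  flat <- rate_assumptions(per_site_ci = c(2.08e-10, 2.08e-10),
                           generation_range = c(24, 24))
  rng0 <- propagate_ranges(tau = 33.8, rates = flat)
  expect_equal(rng0$min_years, rng0$max_years)

  # point-estimate scaling: endemic expansion time
  rng_e <- propagate_ranges(t_years = 9.2e6, rates = rate_assumptions())
  expect_equal(rng_e$reported$min_years, 2.3e6)
  expect_equal(rng_e$reported$max_years, 2.6e7)

  expect_error(propagate_ranges(tau = 1, t_years = 1), "exactly one")
})
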