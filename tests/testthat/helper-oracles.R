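# Independent oracles used across the suite.

# Mismatch pmf by adaptive quadrature of the defining integral
#   P(K = k) = int_0^inf f(x) e^{-x} x^k / k! dx
# in scaled time x (two-epoch exponential density with means theta1 then
# theta0 and boundary tau). Independent of the closed form under test.
quad_mismatch_pmf <- function(k, tau, theta0, theta1) {
  f_recent <- function(x) exp(-x / theta1) / theta1 * stats::dpois(k, x)
  f_ancestral <- function(x)
    exp(-tau / theta1) * exp(-(x - tau) / theta0) / theta0 * stats::dpois(k, x)
  i1 <- if (tau > 0)
    stats::integrate(f_recent, 0, tau, rel.tol = 1e-12,
                     abs.tol = 1e-14)$value else 0
  i2 <- stats::integrate(f_ancestral, tau, Inf, rel.tol = 1e-12,
                         abs.tol = 1e-14)$value
  i1 + i2
}

# CDF of the two-epoch coalescence time (piecewise exponential), written
# directly from the survival function; cross-validated against quadrature of
# coalescence_time_density in the simulator tests before use in KS checks.
two_epoch_cdf <- function(s, t0, N0, N1) {
  ifelse(s < t0,
         1 - exp(-s / (2 * N1)),
         1 - exp(-t0 / (2 * N1)) * exp(-(s - t0) / (2 * N0)))
}

# Total-variation distance between an empirical count sample and an analytic
# pmf (tail mass beyond the tabulated range attributed fully).
tv_distance <- function(counts, params, kmax = max(counts) + 1L) {
  emp <- tabulate(counts + 1L, nbins = kmax + 1L) / length(counts)
  ana <- mismatch_pmf(0:kmax, params)
  0.5 * sum(abs(emp - ana)) + 0.5 * (1 - sum(ana))
}
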