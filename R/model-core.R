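# Two-epoch coalescent model core: coalescence-time density, the closed-form
# mismatch pmf, and its expectation.

# Scaled sizes below this are clamped before evaluating 1/theta, which keeps
# tau/theta finite in double precision while preserving the theta -> 0 limit
# of the pmf.
.THETA_FLOOR <- 1e-12

#' Coalescence-time density under the two-epoch model
#'
#' Density of the coalescence time of a random pair of lineages, in
#' generations measured backwards from the present, for a population of size
#' \code{N1} more recently than \code{t0} generations ago and \code{N0}
#' before. The density is exponential with rate \eqn{1/(2N_1)} up to the
#' epoch boundary and, conditional on not having coalesced by then,
#' exponential with rate \eqn{1/(2N_0)} beyond it:
#' \deqn{f(s) = \frac{1}{2N_1} e^{-s/(2N_1)} \quad (s < t_0), \qquad
#'       f(s) = e^{-t_0/(2N_1)} \frac{1}{2N_0} e^{-(s - t_0)/(2N_0)}
#'       \quad (s \ge t_0).}
#'
#' @param s Time in generations, \eqn{s \ge 0}; vectorised.
#' @param t0 Expansion time in generations, \eqn{t_0 \ge 0}.
#' @param N0 Ancestral effective size, \eqn{> 0}.
#' @param N1 Current effective size, \eqn{> 0}.
#' @return Density values (per generation), same length as \code{s}.
#' @examples
#' coalescence_time_density(0, t0 = 0, N0 = 1, N1 = 5)  # 0.5
#' @export
coalescence_time_density <- function(s, t0, N0, N1) {
  stopifnot(is.numeric(s), is.numeric(t0), is.numeric(N0), is.numeric(N1))
  if (any(!is.finite(s)) || any(s < 0)) stop("'s' must be finite and >= 0")
  if (!is.finite(t0) || t0 < 0) stop("'t0' must be finite and >= 0")
  if (!is.finite(N0) || N0 <= 0 || !is.finite(N1) || N1 <= 0)
    stop("population sizes must be finite and > 0")
  ifelse(s < t0,
         exp(-s / (2 * N1)) / (2 * N1),
         exp(-t0 / (2 * N1)) * exp(-(s - t0) / (2 * N0)) / (2 * N0))
}

#' Log probability mass function of the pairwise mismatch count
#'
#' Log of [mismatch_pmf()], evaluated stably: each of the two epoch terms is
#' computed in log space (regularised incomplete gammas via
#' \code{\link[stats]{pgamma}} with \code{log.p = TRUE}) and combined by
#' log-sum-exp, so large \eqn{\tau(1 + 1/\theta)} and large \eqn{k} do not
#' overflow or underflow.
#'
#' @inheritParams mismatch_pmf
#' @return Log probabilities, same length as \code{k}.
#' @export
mismatch_log_pmf <- function(k, params) {
  params <- as_demography_params(params)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0) ||
      any(k != floor(k)))
    stop("'k' must be a vector of nonnegative integers")
  tau <- params$tau
  th0 <- max(params$theta0, .THETA_FLOOR)
  th1 <- max(params$theta1, .THETA_FLOOR)
  # recent-epoch term: (th1/(1+th1))^k / (1+th1) * P(k+1, x1), with P the
  # lower regularised incomplete gamma, P(k+1, x) = gamma(k+1, x) / k!
  lt1 <- k * (log(th1) - log1p(th1)) - log1p(th1) +
    stats::pgamma(tau * (1 + 1 / th1), k + 1, log.p = TRUE)
  # ancestral-epoch term. Since k + 1 is a positive integer, the upper
  # regularised incomplete gamma is the exact finite sum
  #   Q(k+1, x0) = e^{-x0} sum_{j=0}^{k} x0^j / j!,
  # and -x0 cancels the e^{tau/theta0} factor analytically:
  #   -x0 + tau/theta0 = -tau.
  # Using pgamma here instead would compute log Q ~ -x0 (huge when theta0
  # is small) and then add tau/theta0 back, destroying the pmf in the
  # cancellation; the explicit sum keeps every retained term moderate.
  x0 <- tau * (1 + 1 / th0)
  if (x0 > 0) {
    kmax <- max(k)
    terms <- (0:kmax) * log(x0) - lgamma(1:(kmax + 1L))
    # prefix log-sum-exp: S[j] = log sum_{i<=j} x0^i / i!
    S <- numeric(kmax + 1L)
    S[1L] <- terms[1L]
    if (kmax > 0) for (j in 2:(kmax + 1L)) {
      hi <- max(S[j - 1L], terms[j]); lo <- min(S[j - 1L], terms[j])
      S[j] <- hi + log1p(exp(lo - hi))
    }
    Sk <- S[k + 1L]
  } else {
    Sk <- 0
  }
  lt2 <- k * (log(th0) - log1p(th0)) - log1p(th0) - tau - tau / th1 + Sk
  m <- pmax(lt1, lt2)
  out <- m + log(exp(lt1 - m) + exp(lt2 - m))
  # both terms -Inf (e.g. tau = 0 makes the recent-epoch term vanish)
  out[is.nan(out)] <- -Inf
  out[lt1 == -Inf & is.finite(lt2)] <- lt2[lt1 == -Inf & is.finite(lt2)]
  out[lt2 == -Inf & is.finite(lt1)] <- lt1[lt2 == -Inf & is.finite(lt1)]
  out
}

#' Probability mass function of the pairwise mismatch count
#'
#' Probability that two random sequences differ at \code{k} sites under the
#' two-epoch coalescent with Poisson mutation: given coalescence time
#' \eqn{s}, the number of mismatches is Poisson with mean \eqn{2 u s}, and
#' integrating over the coalescence-time density gives the closed form
#' \deqn{P(K = k) =
#'   \left(\frac{\theta_1}{1+\theta_1}\right)^k \frac{1}{1+\theta_1}
#'   \frac{1}{k!}\, \gamma\!\left(k+1, \tau(1 + 1/\theta_1)\right) +
#'   \left(\frac{\theta_0}{1+\theta_0}\right)^k \frac{1}{1+\theta_0}
#'   \frac{1}{k!}\, \Gamma\!\left(k+1, \tau(1 + 1/\theta_0)\right)
#'   e^{-\tau(1/\theta_1 - 1/\theta_0)},}
#' where \eqn{\gamma} and \eqn{\Gamma} are the unregularised lower and upper
#' incomplete gamma functions. At \eqn{\tau = 0} or
#' \eqn{\theta_0 = \theta_1} this reduces to the geometric distribution of a
#' constant-size population.
#'
#' @param k Nonnegative integer mismatch counts; vectorised.
#' @param params A [demography_params()] object (or numeric
#'   \code{c(tau, theta0, theta1)}).
#' @return Probabilities in \eqn{[0, 1]}, same length as \code{k}.
#' @examples
#' mismatch_pmf(0, demography_params(0, 1, 10))      # 1/(1+theta0) = 0.5
#' mismatch_pmf(2, demography_params(3, 1, 1))       # geometric: 0.125
#' @export
mismatch_pmf <- function(k, params) {
  exp(mismatch_log_pmf(k, params))
}

#' Expected pairwise mismatch count
#'
#' First moment of the mismatch distribution,
#' \eqn{E(K) = \theta_1 + (\theta_0 - \theta_1) e^{-\tau/\theta_1}},
#' the classic expected number of pairwise differences under a sudden
#' expansion (a constant population gives \eqn{E(K) = \theta}).
#'
#' @inheritParams mismatch_pmf
#' @return The expected mismatch count (scalar).
#' @examples
#' expected_mismatches(demography_params(0, 0.7, 10))  # 0.7
#' @export
expected_mismatches <- function(params) {
  params <- as_demography_params(params)
  th1 <- max(params$theta1, .THETA_FLOOR)
  params$theta1 + (params$theta0 - params$theta1) * exp(-params$tau / th1)
}

#' Truncation point for mismatch-distribution tail sums
#'
#' Smallest \code{k} beyond which the geometric envelope
#' \eqn{(\theta/(1+\theta))^k} with \eqn{\theta = \max(\theta_0, \theta_1)}
#' bounds the remaining tail mass below \code{tol}; used to truncate
#' normalisation and moment sums.
#'
#' @inheritParams mismatch_pmf
#' @param tol Tail-mass bound.
#' @return An integer truncation point.
#' @export
mismatch_kmax <- function(params, tol = 1e-12) {
  params <- as_demography_params(params)
  th <- max(params$theta0, params$theta1, .THETA_FLOOR)
  r <- th / (1 + th)
  # tail of geometric envelope beyond k is r^(k+1); solve r^(k+1) < tol
  k <- ceiling(log(tol) / log(r))
  max(10L, as.integer(k) + 1L)
}
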