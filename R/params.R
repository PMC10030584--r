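#' Scaled parameters of the two-epoch demographic model
#'
#' Bundles the three dimensionless parameters of the sudden-expansion
#' coalescent model in mutational units: the scaled expansion time
#' \eqn{\tau = 2 u t_0}, the scaled ancestral population size
#' \eqn{\theta_0 = 2 N_0 u}, and the scaled current size
#' \eqn{\theta_1 = 2 N_1 u}, where \eqn{u} is the per-sequence
#' per-generation mutation rate.
#'
#' Setting \code{tau = 0} or \code{theta0 = theta1} collapses the model to a
#' constant-size population, for which the mismatch distribution is
#' geometric.
#'
#' @param tau Scaled expansion time, \eqn{\tau \ge 0}.
#' @param theta0 Scaled ancestral size, \eqn{\theta_0 > 0}.
#' @param theta1 Scaled current size, \eqn{\theta_1 > 0}.
#' @return An object of class \code{"demography_params"}: a named list with
#'   elements \code{tau}, \code{theta0}, \code{theta1}.
#' @examples
#' demography_params(tau = 5, theta0 = 0.5, theta1 = 10)
#' @export
demography_params <- function(tau, theta0, theta1) {
  stopifnot(is.numeric(tau), is.numeric(theta0), is.numeric(theta1),
            length(tau) == 1L, length(theta0) == 1L, length(theta1) == 1L)
  if (!is.finite(tau) || tau < 0)
    stop("'tau' must be finite and >= 0")
  if (!is.finite(theta0) || theta0 <= 0)
    stop("'theta0' must be finite and > 0")
  if (!is.finite(theta1) || theta1 <= 0)
    stop("'theta1' must be finite and > 0")
  structure(list(tau = tau, theta0 = theta0, theta1 = theta1),
            class = "demography_params")
}

#' @export
print.demography_params <- function(x, ...) {
  cat("Two-epoch demography (mutational units):\n")
  cat(sprintf("  tau    = %g\n  theta0 = %g\n  theta1 = %g\n",
              x$tau, x$theta0, x$theta1))
  invisible(x)
}

as_demography_params <- function(x) {
  if (inherits(x, "demography_params")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(demography_params(x[[1L]], x[[2L]], x[[3L]]))
  stop("cannot interpret 'x' as demography parameters")
}

#' Mutation-rate and generation-time assumptions
#'
#' Collects the quantities needed to convert scaled coalescent estimates to
#' natural units: a per-site per-generation mutation rate with its confidence
#' interval, the alignment length, and the generation time (in days) with its
#' plausible range. The per-sequence rate is derived as
#' \code{per_site_rate * seq_length}.
#'
#' Defaults are those of a mutation-accumulation estimate for a unicellular
#' green alga (2.08e-10 per site per generation, 95\% CI 1.09e-10 to
#' 3.74e-10), a 381-site ITS2 alignment, and an effective generation
#' (doubling) time of 24 days with an 11--36 day plausible range reflecting a
#' roughly two-month annual growth season.
#'
#' @param per_site_rate Mutations per site per generation.
#' @param per_site_ci Length-2 numeric, lower and upper bound of the rate.
#' @param seq_length Number of aligned sites.
#' @param generation_days Mean generation (doubling) time in days.
#' @param generation_range Length-2 numeric, plausible range in days.
#' @return An object of class \code{"rate_assumptions"} with the fields above
#'   plus \code{per_seq_rate}.
#' @examples
#' rate_assumptions()$per_seq_rate  # 2.08e-10 * 381
#' @export
rate_assumptions <- function(per_site_rate = 2.08e-10,
                             per_site_ci = c(1.09e-10, 3.74e-10),
                             seq_length = 381L,
                             generation_days = 24,
                             generation_range = c(11, 36)) {
  stopifnot(is.numeric(per_site_rate), length(per_site_rate) == 1L,
            is.numeric(per_site_ci), length(per_site_ci) == 2L,
            is.numeric(seq_length), length(seq_length) == 1L,
            is.numeric(generation_days), length(generation_days) == 1L,
            is.numeric(generation_range), length(generation_range) == 2L)
  if (per_site_rate <= 0 || seq_length <= 0 || generation_days <= 0)
    stop("rate, sequence length and generation time must be positive")
  if (per_site_ci[1L] > per_site_rate || per_site_ci[2L] < per_site_rate)
    stop("'per_site_ci' must bracket 'per_site_rate'")
  if (generation_range[1L] > generation_days ||
      generation_range[2L] < generation_days)
    stop("'generation_range' must bracket 'generation_days'")
  structure(list(per_site_rate = per_site_rate,
                 per_site_ci = as.numeric(per_site_ci),
                 seq_length = as.integer(seq_length),
                 per_seq_rate = per_site_rate * seq_length,
                 generation_days = generation_days,
                 generation_range = as.numeric(generation_range)),
            class = "rate_assumptions")
}

#' @export
print.rate_assumptions <- function(x, ...) {
  cat("Rate assumptions:\n")
  cat(sprintf("  per-site rate: %g (CI %g-%g) /site/generation\n",
              x$per_site_rate, x$per_site_ci[1L], x$per_site_ci[2L]))
  cat(sprintf("  sequence length: %d sites -> per-sequence rate %g\n",
              x$seq_length, x$per_seq_rate))
  cat(sprintf("  generation time: %g days (range %g-%g)\n",
              x$generation_days, x$generation_range[1L],
              x$generation_range[2L]))
  invisible(x)
}
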