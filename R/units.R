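# Conversion of scaled coalescent estimates to natural units, and range
# propagation over mutation-rate and generation-time uncertainty.

#' Convert scaled demographic estimates to natural units
#'
#' Undoes the mutational scaling: with per-sequence per-generation mutation
#' rate \eqn{u}, the expansion time is \eqn{t_0 = \tau / (2u)} generations
#' and the effective sizes are \eqn{N = \theta / (2u)}. Years follow from
#' the generation time in days,
#' \eqn{t_{years} = t_0 \cdot \mathrm{days} / 365}.
#'
#' @param params A [demography_params()] object.
#' @param rates A [rate_assumptions()] object.
#' @return An object of class \code{"natural_demography"}: list with
#'   \code{t0_generations}, \code{t0_years}, \code{N0}, \code{N1},
#'   \code{expansion_fold} (\code{N1 / N0}), and the \code{rates} used.
#' @examples
#' convert_units(demography_params(33.8, 0.108, 0.217), rate_assumptions())
#' @export
convert_units <- function(params, rates = rate_assumptions()) {
  params <- as_demography_params(params)
  stopifnot(inherits(rates, "rate_assumptions"))
  u <- rates$per_seq_rate
  if (u <= 0) stop("per-sequence mutation rate must be positive")
  t0_gen <- params$tau / (2 * u)
  structure(list(t0_generations = t0_gen,
                 t0_years = t0_gen * rates$generation_days / 365,
                 N0 = params$theta0 / (2 * u),
                 N1 = params$theta1 / (2 * u),
                 expansion_fold = params$theta1 / params$theta0,
                 rates = rates),
            class = "natural_demography")
}

#' @export
print.natural_demography <- function(x, ...) {
  cat("Demography in natural units:\n")
  cat(sprintf("  expansion time: %s generations = %s years\n",
              format(signif(x$t0_generations, 2)),
              format(signif(x$t0_years, 2))))
  cat(sprintf("  N0 = %s, N1 = %s (%s-fold change)\n",
              format(signif(x$N0, 2)), format(signif(x$N1, 2)),
              format(signif(x$expansion_fold, 2))))
  invisible(x)
}

#' Doubling time from an exponential growth rate
#'
#' The generation time of an alga corresponds to the doubling time of the
#' population: \eqn{t_2 = \ln 2 / r} for per-day growth rate \eqn{r}.
#'
#' @param growth_rate Exponential growth rate per day, \eqn{> 0}.
#' @return Doubling time in days.
#' @examples
#' doubling_time(0.42)  # 1.65 days
#' @export
doubling_time <- function(growth_rate) {
  stopifnot(is.numeric(growth_rate))
  if (any(growth_rate <= 0)) stop("'growth_rate' must be > 0")
  log(2) / growth_rate
}

#' Propagate rate and generation-time ranges into the expansion time
#'
#' Evaluates the expansion time in years over the four corner combinations
#' of the mutation-rate confidence interval and the generation-time range.
#' Since \eqn{t_{years} = \tau g / (730 u)} is decreasing in the rate
#' \eqn{u} and increasing in the generation time \eqn{g}, the corners attain
#' the extremes, so the returned interval is exact.
#'
#' Either a scaled estimate \code{tau} or an already-converted point
#' estimate \code{t_years} may be supplied. A point estimate is corner-scaled
#' relative to the central rate and generation time in \code{rates}
#' (\code{t_years * (u_point / u_corner) * (g_corner / g_point)}), which is
#' equivalent to recomputing from \eqn{\tau}.
#'
#' @param tau Scaled expansion time (used if \code{t_years} is \code{NULL}).
#' @param t_years A point estimate of the expansion time in years, obtained
#'   at the central rate and generation time of \code{rates}.
#' @param rates A [rate_assumptions()] object with a non-degenerate rate CI
#'   and generation range (degenerate ranges are allowed and collapse the
#'   interval).
#' @return A list with \code{min_years}, \code{max_years} (full precision)
#'   and \code{reported} (the same, rounded to 2 significant figures).
#' @examples
#' propagate_ranges(tau = 33.8, rates = rate_assumptions())
#' @export
propagate_ranges <- function(tau = NULL, t_years = NULL,
                             rates = rate_assumptions()) {
  stopifnot(inherits(rates, "rate_assumptions"))
  ci <- rates$per_site_ci
  gr <- rates$generation_range
  if (ci[1L] > ci[2L] || gr[1L] > gr[2L])
    stop("inverted rate CI or generation range")
  if (any(ci <= 0) || any(gr <= 0))
    stop("rate CI and generation range must be positive")
  if (is.null(tau) == is.null(t_years))
    stop("supply exactly one of 'tau' or 't_years'")
  if (is.null(tau)) {
    # back out tau from the point estimate at the central assumptions
    tau <- t_years * 365 * 2 * rates$per_seq_rate / rates$generation_days
  }
  if (tau < 0) stop("'tau' must be >= 0")
  corners <- expand.grid(rate = ci, gen = gr)
  t_corner <- tau / (2 * corners$rate * rates$seq_length) *
    corners$gen / 365
  out <- list(min_years = min(t_corner), max_years = max(t_corner))
  out$reported <- lapply(out, signif, digits = 2)
  out
}
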