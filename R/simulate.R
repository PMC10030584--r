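# Seeded generators with exactly the statistical structure the analysis
# assumes: two-epoch coalescence times, Poisson mismatch counts, sequence
# pairs realising given counts, and region-presence tables.

#' Sample pairwise coalescence times under the two-epoch model
#'
#' Draws coalescence times (in generations) whose marginal distribution is
#' [coalescence_time_density()]: with probability
#' \eqn{1 - e^{-t_0/(2N_1)}} the time falls before the epoch boundary and
#' is drawn from an exponential of mean \eqn{2N_1} truncated to
#' \eqn{[0, t_0)}; otherwise it is \eqn{t_0} plus an exponential of mean
#' \eqn{2N_0}.
#'
#' @param n Number of draws.
#' @param t0 Expansion time in generations, \eqn{\ge 0}.
#' @param N0,N1 Ancestral and current effective sizes, \eqn{> 0}.
#' @param seed Integer RNG seed.
#' @return Numeric vector of \code{n} coalescence times.
#' @export
sample_coalescence_time <- function(n, t0, N0, N1, seed = 1L) {
  if (!is.finite(t0) || t0 < 0) stop("'t0' must be finite and >= 0")
  if (!is.finite(N0) || N0 <= 0 || !is.finite(N1) || N1 <= 0)
    stop("population sizes must be finite and > 0")
  withr::with_seed(seed, {
    recent <- stats::runif(n) < -expm1(-t0 / (2 * N1))
    s <- numeric(n)
    # inverse-CDF draw from Exp(mean 2*N1) truncated to [0, t0)
    nr <- sum(recent)
    if (nr > 0) {
      u <- stats::runif(nr)
      s[recent] <- -2 * N1 * log1p(u * expm1(-t0 / (2 * N1)))
    }
    s[!recent] <- t0 + stats::rexp(sum(!recent), rate = 1 / (2 * N0))
    s
  })
}

#' Simulate mismatch counts under the two-epoch coalescent
#'
#' For each pair, draws a coalescence time and then a Poisson number of
#' mutations with mean twice the mutational distance to the common
#' ancestor. Parameterised directly by the scaled parameters
#' \eqn{(\tau, \theta_0, \theta_1)}: times are drawn in mutational units
#' (the scaled time \eqn{x = 2us} has a two-epoch exponential density with
#' means \eqn{\theta_1} then \eqn{\theta_0} and boundary \eqn{\tau}), and
#' \eqn{K \sim} Poisson(\eqn{x}), so the sample depends on the demography
#' only through the three scaled parameters — no mutation rate or census
#' size is needed.
#'
#' @param params A [demography_params()] object.
#' @param n_pairs Number of pairs to simulate.
#' @param seed Integer RNG seed; the same seed reproduces the same sample.
#' @param subset_label Optional label stored in the sample.
#' @return A [mismatch_sample()] of \code{n_pairs} counts.
#' @examples
#' s <- simulate_mismatch_counts(demography_params(5, 0.5, 10), 1000, seed = 7)
#' mean(s$counts)  # close to expected_mismatches(...)
#' @export
simulate_mismatch_counts <- function(params, n_pairs, seed = 1L,
                                     subset_label = NA_character_) {
  params <- as_demography_params(params)
  if (!is.numeric(n_pairs) || n_pairs < 1) stop("'n_pairs' must be >= 1")
  # scaled units: x = 2us, so t0 -> tau, 2N1 -> theta1, 2N0 -> theta0
  x <- sample_coalescence_time(n_pairs, t0 = params$tau,
                               N0 = params$theta0 / 2,
                               N1 = params$theta1 / 2, seed = seed)
  k <- withr::with_seed(seed + 1L, stats::rpois(n_pairs, lambda = x))
  mismatch_sample(k, n_phylotypes = 2L * as.integer(n_pairs),
                  pairing_seed = as.integer(seed),
                  subset_label = subset_label)
}

#' Realise mismatch counts as aligned sequence pairs
#'
#' For each count \code{k}, generates a random ancestral sequence and a copy
#' in which \code{k} distinct, randomly chosen sites are substituted with a
#' different base, so that [count_mismatches()] on the emitted pair returns
#' exactly \code{k}. Mutations hit distinct sites (no multiple hits),
#' matching the model's identification of mismatch count with mutation
#' count; a warning is emitted when any \code{k} exceeds 20\% of the
#' sequence length, where that identification becomes biologically dubious.
#'
#' @param sample A [mismatch_sample()] or integer vector of counts.
#' @param seq_length Alignment length in sites (default 381).
#' @param seed Integer RNG seed.
#' @return A \code{DNAStringSet} of \code{2 * n_pairs} sequences named
#'   \code{pair<i>_a} / \code{pair<i>_b}.
#' @export
emit_sequence_pairs <- function(sample, seq_length = 381L, seed = 1L) {
  sample <- as_mismatch_sample(sample)
  k <- sample$counts
  if (any(k > seq_length))
    stop("mismatch count exceeds sequence length for pair(s) ",
         paste(which(k > seq_length), collapse = ", "),
         " (model saturation)")
  if (any(k > 0.2 * seq_length))
    warning("some mismatch counts exceed 20% of the sequence length; ",
            "the no-multiple-hits approximation is dubious there")
  bases <- c("A", "C", "G", "T")
  seqs <- withr::with_seed(seed, {
    out <- character(2L * length(k))
    for (i in seq_along(k)) {
      anc <- sample(bases, seq_length, replace = TRUE)
      der <- anc
      if (k[i] > 0) {
        sites <- sample.int(seq_length, k[i])
        for (s in sites)
          der[s] <- sample(setdiff(bases, anc[s]), 1L)
      }
      out[2L * i - 1L] <- paste(anc, collapse = "")
      out[2L * i] <- paste(der, collapse = "")
    }
    out
  })
  names(seqs) <- paste0("pair", rep(seq_along(k), each = 2L),
                        c("_a", "_b"))
  Biostrings::DNAStringSet(seqs)
}

#' Generate a region-presence table with configured distribution types
#'
#' Emits a long-form region table whose phylotypes classify
#' ([classify_distribution()]) into the three distribution types in the
#' configured proportions (largest-remainder rounding). Cosmopolitans are
#' detected in Antarctica, all three Arctic subregions, and the
#' mid-latitudes (so they classify as cosmopolitan under both the default
#' and the strict rule); multi-region phylotypes in a random choice of two
#' macro-regions; endemics in one random macro-region.
#'
#' @param n Number of phylotypes.
#' @param region_mix Length-3 numeric, proportions of
#'   cosmopolitan / multi-region / endemic; must sum to 1.
#' @param seed Integer RNG seed.
#' @return A long-form data frame with columns \code{phylotype_id},
#'   \code{region}.
#' @examples
#' tab <- generate_phylotype_table(100, c(0.5, 0.25, 0.25), seed = 1)
#' table(classify_table(tab)$label)
#' @export
generate_phylotype_table <- function(n, region_mix = c(1/3, 1/3, 1/3),
                                     seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (length(region_mix) != 3L || any(region_mix < 0) ||
      abs(sum(region_mix) - 1) > 1e-9)
    stop("'region_mix' must be 3 nonnegative proportions summing to 1")
  # largest-remainder apportionment of n among the three labels
  raw <- n * region_mix
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  labels <- rep(c("cosmopolitan", "multi_region", "endemic"), counts)
  withr::with_seed(seed, {
    labels <- sample(labels)
    rows <- lapply(seq_len(n), function(i) {
      regions <- switch(labels[i],
        cosmopolitan = c("Antarctica", .ARCTIC_SUBREGIONS, "mid-latitude"),
        multi_region = sample(.MACRO_REGIONS, 2L),
        endemic = sample(.MACRO_REGIONS, 1L))
      data.frame(phylotype_id = sprintf("pt%04d", i), region = regions)
    })
    do.call(rbind, rows)
  })
}
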