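#' Mismatch sample container
#'
#' A set of pairwise mismatch counts over disjoint random pairs of
#' phylotypes — the data unit of the composite likelihood. One count per
#' pair; with \code{n} phylotypes there are \code{floor(n/2)} pairs.
#'
#' @param counts Nonnegative integer mismatch counts, one per pair.
#' @param n_phylotypes Number of phylotypes that were paired (defaults to
#'   \code{2 * length(counts)}).
#' @param pairing_seed RNG seed used to form the pairs, if any.
#' @param subset_label Free-text label (e.g. \code{"cosmopolitan"}).
#' @return An object of class \code{"mismatch_sample"}.
#' @export
mismatch_sample <- function(counts, n_phylotypes = 2L * length(counts),
                            pairing_seed = NA_integer_,
                            subset_label = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("'counts' must be nonempty")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("'counts' must be nonnegative integers")
  if (length(counts) != n_phylotypes %/% 2L)
    stop("length(counts) must equal floor(n_phylotypes / 2)")
  structure(list(counts = as.integer(counts),
                 n_phylotypes = as.integer(n_phylotypes),
                 pairing_seed = pairing_seed,
                 subset_label = subset_label),
            class = "mismatch_sample")
}

#' @export
print.mismatch_sample <- function(x, ...) {
  lab <- if (is.na(x$subset_label)) "" else sprintf(" [%s]", x$subset_label)
  cat(sprintf("Mismatch sample%s: %d pairs from %d phylotypes\n",
              lab, length(x$counts), x$n_phylotypes))
  cat(sprintf("  mean k = %.3g, range %d-%d\n", mean(x$counts),
              min(x$counts), max(x$counts)))
  invisible(x)
}

as_mismatch_sample <- function(x) {
  if (inherits(x, "mismatch_sample")) return(x)
  if (is.numeric(x)) return(mismatch_sample(x))
  stop("cannot interpret 'x' as a mismatch sample")
}

#' Tabulate a mismatch sample as a histogram
#'
#' @param sample A [mismatch_sample()] (or plain integer vector of counts).
#' @return A data frame with columns \code{k} and \code{count}; the counts
#'   sum to the number of pairs.
#' @examples
#' mismatch_histogram(mismatch_sample(c(0, 0, 2)))
#' @export
mismatch_histogram <- function(sample) {
  sample <- as_mismatch_sample(sample)
  tab <- table(sample$counts)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Read / write mismatch samples and histograms as TSV
#'
#' Plain-text round-trip for pipeline artifacts: a mismatch sample is stored
#' with columns \code{pair_id} and \code{k}; a histogram with columns
#' \code{k} and \code{count}.
#'
#' @param sample A [mismatch_sample()].
#' @param path File path.
#' @return \code{write_*} return the path invisibly; \code{read_*} return
#'   the reconstructed object.
#' @export
write_mismatch_tsv <- function(sample, path) {
  sample <- as_mismatch_sample(sample)
  utils::write.table(
    data.frame(pair_id = seq_along(sample$counts), k = sample$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mismatch_tsv
#' @export
read_mismatch_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("pair_id", "k") %in% names(df)))
    stop("expected columns 'pair_id' and 'k' in ", path)
  mismatch_sample(df$k)
}

#' @rdname write_mismatch_tsv
#' @param histogram A histogram data frame as from [mismatch_histogram()].
#' @export
write_histogram_tsv <- function(histogram, path) {
  stopifnot(all(c("k", "count") %in% names(histogram)))
  utils::write.table(histogram[, c("k", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mismatch_tsv
#' @export
read_histogram_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("k", "count") %in% names(df)))
    stop("expected columns 'k' and 'count' in ", path)
  df
}
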