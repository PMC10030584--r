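# From aligned phylotype sequences and region metadata to distribution-type
# labels and mismatch samples.

.MACRO_REGIONS <- c("Antarctic", "Arctic", "mid-latitude")
.ARCTIC_SUBREGIONS <- c("Svalbard", "Greenland", "Alaska")

# map free-form region names onto the three macro-regions
.macro_region <- function(region) {
  r <- tolower(gsub("[ _]", "-", trimws(region)))
  out <- rep(NA_character_, length(r))
  out[r %in% c("antarctic", "antarctica")] <- "Antarctic"
  out[r %in% c("arctic", "svalbard", "greenland", "alaska")] <- "Arctic"
  out[r %in% c("mid-latitude", "midlatitude", "mid-latitudes")] <-
    "mid-latitude"
  if (anyNA(out))
    stop("unknown region name(s): ",
         paste(unique(region[is.na(out)]), collapse = ", "))
  out
}

#' Load an aligned phylotype FASTA file
#'
#' Reads a FASTA alignment of unique marker sequences (phylotypes),
#' uppercases them, and checks that all records share one alignment length.
#'
#' @param path Path to a FASTA file.
#' @return A \code{DNAStringSet} with uppercase sequences.
#' @export
read_phylotype_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    bad <- names(seqs)[w != w[1L]][1L]
    stop("unequal alignment lengths: record '", bad, "' has width ",
         w[w != w[1L]][1L], ", expected ", w[1L])
  }
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

.seq_matrix <- function(seqs) {
  chars <- as.character(seqs)
  chars <- chartr("u", "U", toupper(chars))
  chars <- chartr("U", "T", chars)
  n <- nchar(chars)
  if (length(unique(n)) != 1L) stop("sequences must share one length")
  matrix(unlist(strsplit(chars, "", fixed = TRUE), use.names = FALSE),
         nrow = length(chars), byrow = TRUE)
}

#' Count mismatched sites between two aligned sequences
#'
#' Number of alignment positions at which both sequences carry an
#' unambiguous base (A, C, G or T; U is read as T, comparison is
#' case-insensitive) and the bases differ. Positions where either sequence
#' has a gap or an ambiguity code are excluded (pairwise deletion).
#'
#' @param a,b Aligned sequences of equal length (character scalars or
#'   \code{DNAString}s).
#' @return Integer mismatch count.
#' @examples
#' count_mismatches("AC-T", "ACGA")  # 1: the gap column is excluded
#' @export
count_mismatches <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  m <- .seq_matrix(c(a, b))
  valid <- m[1L, ] %in% c("A", "C", "G", "T") &
    m[2L, ] %in% c("A", "C", "G", "T")
  sum(valid & m[1L, ] != m[2L, ])
}

#' Build a mismatch sample from an aligned phylotype collection
#'
#' Pairs the phylotypes at random into disjoint pairs
#' ([make_disjoint_pairs()]) and counts mismatched sites within each pair.
#' In \code{"strict"} mode (the default) every alignment column containing
#' a gap or ambiguity code in any sequence is removed collection-wide
#' before counting, emulating a global deletion of ambiguous sites; in
#' \code{"pairwise"} mode only the offending positions of each individual
#' pair are excluded.
#'
#' @param seqs A \code{DNAStringSet} or character vector of equal-length
#'   aligned sequences (at least 2).
#' @param seed Integer RNG seed for the pairing.
#' @param gap_mode \code{"strict"} or \code{"pairwise"}.
#' @return A [mismatch_sample()] with the pairing seed recorded.
#' @export
build_mismatch_sample <- function(seqs, seed = 1L,
                                  gap_mode = c("strict", "pairwise")) {
  gap_mode <- match.arg(gap_mode)
  m <- .seq_matrix(seqs)
  if (nrow(m) < 2L) stop("need at least 2 phylotypes")
  acgt <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  if (gap_mode == "strict") {
    keep <- colSums(acgt) == nrow(m)
    m <- m[, keep, drop = FALSE]
    acgt <- acgt[, keep, drop = FALSE]
  }
  pairs <- make_disjoint_pairs(nrow(m), seed)
  counts <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    valid <- acgt[i, ] & acgt[j, ]
    sum(valid & m[i, ] != m[j, ])
  }, numeric(1))
  mismatch_sample(counts, n_phylotypes = nrow(m), pairing_seed = seed)
}

#' Classify a phylotype's geographic distribution type
#'
#' Applies the three-way biogeographic typing rule to the set of regions a
#' phylotype was detected in. A phylotype present in all three
#' macro-regions — Antarctic, Arctic, and mid-latitude — is
#' \code{cosmopolitan}; one present in exactly one macro-region is
#' \code{endemic}; one present in exactly two (including "both poles only")
#' is \code{multi_region}. Arctic subregion names (Svalbard, Greenland,
#' Alaska) are folded into the Arctic macro-region; with
#' \code{strict_cosmopolitan = TRUE} a cosmopolitan must additionally have
#' been detected in all three named Arctic subregions.
#'
#' @param regions Character vector of region names where one phylotype was
#'   detected (nonempty).
#' @param strict_cosmopolitan Require all three Arctic subregions for the
#'   cosmopolitan label (default \code{FALSE}).
#' @return One of \code{"cosmopolitan"}, \code{"multi_region"},
#'   \code{"endemic"}.
#' @examples
#' classify_distribution(c("Antarctica", "Svalbard", "mid-latitude"))
#' classify_distribution("Arctic")  # endemic
#' @export
classify_distribution <- function(regions, strict_cosmopolitan = FALSE) {
  if (length(regions) == 0L) stop("'regions' must be nonempty")
  macro <- unique(.macro_region(regions))
  if (setequal(macro, .MACRO_REGIONS)) {
    if (!strict_cosmopolitan ||
        all(.ARCTIC_SUBREGIONS %in% trimws(regions)))
      return("cosmopolitan")
    return("multi_region")
  }
  if (length(macro) == 1L) return("endemic")
  "multi_region"
}

#' Classify every phylotype in a region-presence table
#'
#' @param region_table Data frame in long form with columns
#'   \code{phylotype_id} and \code{region} (one row per detection), as read
#'   by [read_region_table()].
#' @inheritParams classify_distribution
#' @return A data frame with columns \code{phylotype_id} and \code{label};
#'   one row per phylotype, so the three labels partition the collection.
#' @export
classify_table <- function(region_table, strict_cosmopolitan = FALSE) {
  stopifnot(all(c("phylotype_id", "region") %in% names(region_table)))
  ids <- unique(region_table$phylotype_id)
  labels <- vapply(ids, function(id) {
    classify_distribution(
      region_table$region[region_table$phylotype_id == id],
      strict_cosmopolitan = strict_cosmopolitan)
  }, character(1))
  data.frame(phylotype_id = ids, label = unname(labels))
}

#' Read / write region-presence tables
#'
#' Long-form TSV with columns \code{phylotype_id} and \code{region}, one
#' row per detection of a phylotype in a region; a wide table (an id column
#' followed by one logical/0-1 column per region) is melted to long form on
#' read.
#'
#' @param path File path.
#' @return A long-form data frame with columns \code{phylotype_id},
#'   \code{region}.
#' @export
read_region_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (all(c("phylotype_id", "region") %in% names(df)))
    return(df[, c("phylotype_id", "region")])
  # wide form: first column is the id
  idcol <- names(df)[1L]
  regions <- setdiff(names(df), idcol)
  if (length(regions) == 0L) stop("no region columns in ", path)
  long <- do.call(rbind, lapply(regions, function(r) {
    present <- as.logical(df[[r]])
    data.frame(phylotype_id = df[[idcol]][present],
               region = gsub("\\.", "-", r))
  }))
  long[order(long$phylotype_id), , drop = FALSE]
}

#' @rdname read_region_table
#' @param region_table Long-form region table to write.
#' @export
write_region_table <- function(region_table, path) {
  stopifnot(all(c("phylotype_id", "region") %in% names(region_table)))
  utils::write.table(region_table[, c("phylotype_id", "region")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
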