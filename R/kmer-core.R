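#' All DNA k-mers of a given length
#'
#' Returns the 4^k words over {A,C,G,T} in lexicographic order, the same
#' order used by [count_kmers()] count vectors.
#'
#' @param k word length in bp (1..13).
#' @return character vector of length 4^k.
#' @export
kmer_universe <- function(k) {
  k <- .check_k(k)
  if (k > 13L) stop("k > 13 is not supported (full enumeration only)")
  key <- paste0("universe_", k)
  if (!exists(key, envir = .kmer_cache)) {
    u <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)
    assign(key, u, envir = .kmer_cache)
  }
  get(key, envir = .kmer_cache)
}

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k))
    stop("'k' must be a single positive integer")
  as.integer(k)
}

.as_dna_set <- function(sequence, id = NULL) {
  if (methods::is(sequence, "DNAStringSet")) {
    x <- sequence
  } else if (methods::is(sequence, "DNAString")) {
    x <- Biostrings::DNAStringSet(sequence)
  } else if (is.character(sequence)) {
    x <- Biostrings::DNAStringSet(toupper(sequence))
  } else {
    stop("'sequence' must be a character vector, DNAString or DNAStringSet")
  }
  if (is.null(names(x)) && !is.null(id)) names(x) <- rep(id, length(x))
  x
}

#' Count k-mers with a 1-bp sliding window
#'
#' Scans the sequence with a window of k bp and step 1 bp and tallies each of
#' the 4^k k-mers over {A,C,G,T}. Windows containing any non-ACGT character
#' (e.g. N) are skipped and do not contribute to `n_windows`. Counting is
#' case-insensitive and single-strand (no reverse-complement merging).
#' Multi-record input is pooled: each record is scanned separately, so no
#' artificial junction k-mers are created.
#'
#' @param sequence character vector, `DNAString` or `DNAStringSet`; multiple
#'   elements/records are pooled into one table.
#' @param k window length in bp.
#' @param id sequence identifier used in messages and downstream tables.
#' @return a `kmer_count_table`: list with `k`, `counts` (named integer vector
#'   over all 4^k k-mers), `n_windows` (= sum of counts), `total_length` and
#'   `source_id`.
#' @export
count_kmers <- function(sequence, k, id = NULL) {
  k <- .check_k(k)
  id <- id %||% "sequence"
  x <- .as_dna_set(sequence, id)
  widths <- Biostrings::width(x)
  if (length(x) == 0L || sum(widths) == 0L)
    stop(sprintf("'%s': empty sequence input", id))
  if (all(widths < k))
    stop(sprintf("'%s': no record is at least k = %d bp long", id, k))
  x <- x[widths >= k]
  counts <- Biostrings::oligonucleotideFrequency(x, width = k, step = 1L)
  if (is.matrix(counts)) counts <- colSums(counts)
  storage.mode(counts) <- "integer"
  n_windows <- sum(counts)
  if (n_windows == 0L)
    stop(sprintf("'%s': no valid ACGT window of length %d", id, k))
  structure(
    list(k = k, counts = counts, n_windows = n_windows,
         total_length = sum(widths), n_records = length(x), source_id = id),
    class = "kmer_count_table"
  )
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table '%s': k = %d, %d record(s), %s bp, %s windows, %d distinct k-mers observed\n",
              x$source_id, x$k, x$n_records, format(x$total_length, big.mark = ","),
              format(x$n_windows, big.mark = ","), sum(x$counts > 0)))
  invisible(x)
}

#' Build a k-mer frequency spectrum
#'
#' A spectrum is the histogram of k-mer occurrence frequencies: for each
#' frequency value i it records N_i, the number of member k-mers occurring
#' exactly i times, and the relative motif number RMN = N_i / 4^k. The RMN
#' denominator is always 4^k, also for subsets, so subset spectra of one
#' genome share a common scale. The zero-frequency block is always present.
#'
#' @param table a `kmer_count_table` from [count_kmers()].
#' @param members `"total"` for the full k-mer universe, or a character vector
#'   of member k-mers defining a subset.
#' @param subset_label label stored with the spectrum.
#' @return a `kmer_spectrum` data frame with columns `frequency`, `n_kmers`,
#'   `rmn` and attributes `k`, `subset_label`, `n_members`.
#' @export
build_spectrum <- function(table, members = "total", subset_label = NULL) {
  stopifnot(inherits(table, "kmer_count_table"))
  counts <- table$counts
  if (identical(members, "total")) {
    sel <- counts
    label <- subset_label %||% "total"
  } else {
    if (!is.character(members) || length(members) == 0L)
      stop("'members' must be \"total\" or a non-empty character vector of k-mers")
    bad <- setdiff(members, names(counts))
    if (length(bad))
      stop(sprintf("members not in the %d-mer universe: %s ...", table$k, bad[1L]))
    sel <- counts[members]
    label <- subset_label %||% "subset"
  }
  tab <- table(sel)
  freq <- as.integer(names(tab))
  n_kmers <- as.integer(tab)
  if (!0L %in% freq) {  # materialize the zero block
    freq <- c(0L, freq)
    n_kmers <- c(0L, n_kmers)
  }
  o <- order(freq)
  out <- data.frame(frequency = freq[o], n_kmers = n_kmers[o],
                    rmn = n_kmers[o] / 4^table$k)
  attr(out, "k") <- table$k
  attr(out, "subset_label") <- label
  attr(out, "n_members") <- length(sel)
  attr(out, "n_windows") <- table$n_windows
  class(out) <- c("kmer_spectrum", "data.frame")
  out
}

#' Expected k-mer count in a random sequence
#'
#' The center frequency of the spectrum of an i.i.d. uniform sequence of
#' length L: (L - k + 1) / 4^k, the expected occurrence count of each k-mer.
#'
#' @param L sequence length in bp.
#' @param k word length in bp.
#' @return expected per-k-mer count (numeric).
#' @export
random_center_frequency <- function(L, k) {
  k <- .check_k(k)
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < k)
    stop("'L' must be a single number >= k")
  (L - k + 1) / 4^k
}

#' Minimum informative k for a sequence length
#'
#' The rule-of-thumb lower bound k = 0.7 * log4(L) below which the spectrum
#' of a length-L sequence degenerates (most k-mers saturate).
#'
#' @param L sequence length in bp (> 1).
#' @return real-valued minimum k.
#' @export
minimum_k <- function(L) {
  if (!is.numeric(L) || any(is.na(L)) || any(L <= 1))
    stop("'L' must be > 1")
  0.7 * log(L, base = 4)
}
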