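#' The 16 ordered XY dinucleotide pairs
#'
#' XY classifications are indexed by ordered dinucleotides: XY and YX are
#' distinct classifications, giving 16 in total.
#'
#' @return character vector of the 16 dinucleotides, AA..TT.
#' @export
xy_pairs <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(b, b, paste0)))
}

.check_xy <- function(xy) {
  if (!is.character(xy) || length(xy) != 1L || !xy %in% xy_pairs())
    stop("'xy' must be one of the 16 DNA dinucleotides (e.g. \"CG\")")
  xy
}

.check_scheme <- function(scheme) {
  match.arg(scheme, c("three-way", "two-way"))
}

# occurrence counting without input validation (hot path over the universe)
.count_xy <- function(kmers, xy, k = nchar(kmers[1L])) {
  n <- integer(length(kmers))
  if (k < 2L) return(n)
  for (i in seq_len(k - 1L)) n <- n + (substring(kmers, i, i + 1L) == xy)
  n
}

#' Count overlapping occurrences of a dinucleotide in k-mers
#'
#' Scans each k-mer with step 1, so occurrences may overlap: "AAA" contains
#' two occurrences of "AA". Overlap counting is what makes the theoretical
#' subset sizes come out as printed (e.g. 44,631 zero-occurrence 8-mers for a
#' same-letter pair).
#'
#' @param kmers character vector of equal-length DNA words over {A,C,G,T}.
#' @param xy a dinucleotide.
#' @return integer vector of occurrence counts.
#' @export
count_xy_occurrences <- function(kmers, xy) {
  .check_xy(xy)
  if (!is.character(kmers) || length(kmers) == 0L)
    stop("'kmers' must be a non-empty character vector")
  kmers <- toupper(kmers)
  k <- unique(nchar(kmers))
  if (length(k) != 1L)
    stop("all k-mers must have the same length")
  if (any(grepl("[^ACGT]", kmers)))
    stop("k-mers must contain only A, C, G, T")
  .count_xy(kmers, xy, k)
}

#' Classify k-mers by XY dinucleotide content
#'
#' Three-way scheme (the default for 8-mers): class 0 = no occurrence of XY,
#' class 1 = exactly one, class 2 = two or more. Two-way scheme (the default
#' for 6-mers): class 0 = none, class 1 = one or more. Either scheme can be
#' applied at any k.
#'
#' @inheritParams count_xy_occurrences
#' @param scheme `"three-way"` or `"two-way"`.
#' @return integer vector of class labels (0/1/2 or 0/1).
#' @export
classify_kmers <- function(kmers, xy, scheme = c("three-way", "two-way")) {
  scheme <- .check_scheme(scheme)
  n <- count_xy_occurrences(kmers, xy)
  pmin(n, if (scheme == "three-way") 2L else 1L)
}

#' Occurrence matrix of all 16 dinucleotides over the k-mer universe
#'
#' Cached per k. Row order matches [kmer_universe()] (and [count_kmers()]
#' count vectors); columns are the 16 ordered pairs.
#'
#' @param k word length (2..13).
#' @return integer matrix 4^k x 16 with dimnames (k-mer, pair).
#' @export
xy_occurrence_matrix <- function(k) {
  k <- .check_k(k)
  key <- paste0("occ_", k)
  if (!exists(key, envir = .kmer_cache)) {
    u <- kmer_universe(k)
    pairs <- xy_pairs()
    m <- matrix(0L, nrow = length(u), ncol = length(pairs),
                dimnames = list(u, pairs))
    if (k >= 2L) {
      # share the substring pass across the 16 pairs
      dn <- vapply(seq_len(k - 1L), function(i) substring(u, i, i + 1L),
                   character(length(u)))
      for (p in pairs) m[, p] <- as.integer(rowSums(dn == p))
    }
    assign(key, m, envir = .kmer_cache)
  }
  get(key, envir = .kmer_cache)
}

#' Exact subset sizes of an XY classification
#'
#' Enumerates all 4^k k-mers and tabulates the classes. For k = 8, three-way,
#' this reproduces the theoretical sizes 40,545 / 21,468 / 3,523 (X != Y) and
#' 44,631 / 14,931 / 5,974 (X = Y); for k = 6, two-way, 2,911 / 1,185 and
#' 3,105 / 991.
#'
#' @param k word length (2..13).
#' @param xy a dinucleotide.
#' @param scheme `"three-way"` or `"two-way"`.
#' @return named integer vector, e.g. `c(CG0 = ..., CG1 = ..., CG2 = ...)`.
#' @export
partition_sizes <- function(k, xy, scheme = c("three-way", "two-way")) {
  k <- .check_k(k)
  .check_xy(xy)
  scheme <- .check_scheme(scheme)
  cap <- if (scheme == "three-way") 2L else 1L
  cls <- pmin(xy_occurrence_matrix(k)[, xy], cap)
  sizes <- vapply(0:cap, function(cl) sum(cls == cl), integer(1L))
  names(sizes) <- paste0(xy, 0:cap)
  sizes
}

#' Zero-class size by linear recurrence
#'
#' Independent oracle for the number of k-mers avoiding a dinucleotide XY.
#' For X != Y: b(1) = 4, b(2) = 15, b(k) = 4 b(k-1) - b(k-2). For X = Y:
#' a(1) = 4, a(2) = 15, a(k) = 3 a(k-1) + 3 a(k-2). Must agree with the
#' enumerated XY0 size.
#'
#' @param k word length (>= 1).
#' @param xy a dinucleotide.
#' @return integer count of XY0 k-mers.
#' @export
zero_class_size_recurrence <- function(k, xy) {
  k <- .check_k(k)
  .check_xy(xy)
  same <- substr(xy, 1L, 1L) == substr(xy, 2L, 2L)
  if (k == 1L) return(4)
  prev2 <- 4; prev1 <- 15
  if (k == 2L) return(prev1)
  for (i in 3:k) {
    cur <- if (same) 3 * prev1 + 3 * prev2 else 4 * prev1 - prev2
    prev2 <- prev1
    prev1 <- cur
  }
  prev1
}

#' Theoretical mean G+C content of an XY subset
#'
#' Averages 100 * (#G + #C) / k over the k-mers of one class of an XY
#' classification. For 6-mers, two-way: CG1 = 65.34%, CG0 = 43.75%,
#' TA1 = 34.66%, TA0 = 56.25%.
#'
#' @inheritParams partition_sizes
#' @param class class label (0, 1, or 2 for three-way).
#' @return mean G+C content of the class, in percent.
#' @export
theoretical_subset_gc <- function(k, xy, class, scheme = c("three-way", "two-way")) {
  k <- .check_k(k)
  .check_xy(xy)
  scheme <- .check_scheme(scheme)
  cap <- if (scheme == "three-way") 2L else 1L
  if (!class %in% 0:cap)
    stop(sprintf("'class' must be in 0..%d for the %s scheme", cap, scheme))
  cls <- pmin(xy_occurrence_matrix(k)[, xy], cap)
  members <- kmer_universe(k)[cls == class]
  if (length(members) == 0L)
    stop(sprintf("class %s%d is empty at k = %d", xy, class, k))
  mean(100 * .gc_count(members) / k)
}

# number of G/C letters per word
.gc_count <- function(words) {
  nchar(words) - nchar(gsub("[GC]", "", words))
}
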