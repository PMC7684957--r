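#' Square-root transform of spectrum frequencies
#'
#' K-mer spectra of real genomes are right-skewed (chi-square-like); taking
#' the square root of every frequency brings them close to normal, so the
#' mean and SD describe location and spread independently. All separability /
#' conservatism statistics are computed on this scale by default.
#'
#' @param x non-negative numeric vector of k-mer frequencies.
#' @return element-wise square root.
#' @export
sqrt_transform <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (any(is.na(x)) || any(x < 0)) stop("frequencies must be non-negative")
  sqrt(x)
}

#' Mean and sample SD of a spectrum
#'
#' @param values numeric vector of (possibly transformed) frequencies, N >= 2.
#' @return named numeric `c(mean = , sd = )`; SD uses the N-1 divisor.
#' @export
spectrum_mean_sd <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need at least 2 values")
  c(mean = mean(values), sd = stats::sd(values))
}

#' Separability of a subset spectrum
#'
#' delta = (total-set mean) / (subset mean). A subset whose k-mers are
#' depleted relative to the whole genome has delta > 1. Dimensionless and
#' invariant under rescaling all counts by a common factor.
#'
#' @param total_mean mean of the total-set spectrum.
#' @param subset_mean mean of the subset spectrum.
#' @return the ratio, or `NA_real_` when the subset mean is zero or missing
#'   (undefined, never infinite).
#' @export
separability <- function(total_mean, subset_mean) {
  out <- total_mean / subset_mean
  out[!is.finite(out) | subset_mean <= 0] <- NA_real_
  out
}

#' Conservatism of a subset spectrum
#'
#' rho = (total-set SD) / (subset SD). A subset whose frequencies are tightly
#' concentrated has rho > 1.
#'
#' @param total_sd SD of the total-set spectrum.
#' @param subset_sd SD of the subset spectrum.
#' @return the ratio, or `NA_real_` when the subset SD is zero or missing.
#' @export
conservatism <- function(total_sd, subset_sd) {
  out <- total_sd / subset_sd
  out[!is.finite(out) | subset_sd <= 0] <- NA_real_
  out
}

#' Profile a genome: spectrum statistics for all XY subsets
#'
#' Counts k-mers once, then for the total k-mer set and for every class of
#' all 16 XY classifications computes the (square-root-transformed) spectrum
#' mean and SD, the separability delta and the conservatism rho against the
#' total set. Also computes the G+C content, the background selection
#' intensity (mean delta of the 14 XY1 spectra other than CG1 and TA1) and
#' the CG/TA selection flags.
#'
#' @param sequence character vector, `DNAString`/`DNAStringSet`, or a
#'   precomputed `kmer_count_table` (in which case `gc_content` must be
#'   supplied if wanted).
#' @param k word length; default 6.
#' @param scheme `"three-way"` or `"two-way"`; default three-way for k >= 7,
#'   two-way below (mirroring 8-mer vs 6-mer usage).
#' @param id genome identifier.
#' @param sqrt_transform transform frequencies before mean/SD (default TRUE).
#' @param include_zeros include zero-count k-mers of each subset in N
#'   (default TRUE); FALSE restricts every spectrum, including the total, to
#'   k-mers observed at least once.
#' @param margin strong-inhibition margin passed to [selection_flags()].
#' @param gc_content override/provide G+C content (percent) when `sequence`
#'   is a count table.
#' @return a `genome_profile`: list with `genome_id`, `k`, `scheme`,
#'   `gc_content`, `n_windows`, `total_length`, `stats` (one row per subset:
#'   `subset`, `class`, `n_members`, `mean`, `sd`, `delta`, `rho`),
#'   `background_delta1`, `flags`, `params`.
#' @export
profile_genome <- function(sequence, k = 6, scheme = NULL, id = NULL,
                           sqrt_transform = TRUE, include_zeros = TRUE,
                           margin = 0.05, gc_content = NULL) {
  k <- .check_k(k)
  scheme <- if (is.null(scheme)) {
    if (k >= 7L) "three-way" else "two-way"
  } else .check_scheme(scheme)

  if (inherits(sequence, "kmer_count_table")) {
    tab <- sequence
    if (tab$k != k) stop("count table was built with a different k")
    id <- id %||% tab$source_id
    gc <- gc_content %||% NA_real_
  } else {
    id <- id %||% "genome"
    x_dna <- .as_dna_set(sequence, id)
    tab <- count_kmers(x_dna, k, id = id)
    gc <- gc_content %||% .sequence_gc(x_dna)
  }

  raw <- as.numeric(tab$counts)
  keep <- if (include_zeros) rep(TRUE, length(raw)) else raw > 0
  vals <- if (sqrt_transform) sqrt(raw) else raw

  occ <- xy_occurrence_matrix(k)
  # align classification rows with the count vector (both lexicographic, but
  # never rely on it silently)
  if (!identical(rownames(occ), names(tab$counts)))
    occ <- occ[names(tab$counts), , drop = FALSE]

  cap <- if (scheme == "three-way") 2L else 1L
  tot <- vals[keep]
  tot_ms <- spectrum_mean_sd(tot)

  pairs <- xy_pairs()
  n_sub <- length(pairs) * (cap + 1L)
  stats_df <- data.frame(
    subset = c("total", rep(pairs, each = cap + 1L)),
    class = c(NA_integer_, rep(0:cap, times = length(pairs))),
    n_members = NA_integer_, mean = NA_real_, sd = NA_real_,
    delta = NA_real_, rho = NA_real_
  )
  stats_df[1L, c("n_members", "mean", "sd", "delta", "rho")] <-
    list(length(tot), tot_ms[["mean"]], tot_ms[["sd"]],
         tot_ms[["mean"]] / tot_ms[["mean"]], tot_ms[["sd"]] / tot_ms[["sd"]])

  row <- 2L
  for (p in pairs) {
    cls <- pmin(occ[, p], cap)
    for (cl in 0:cap) {
      v <- vals[keep & cls == cl]
      stats_df$n_members[row] <- length(v)
      if (length(v) >= 2L) {
        ms <- spectrum_mean_sd(v)
        stats_df$mean[row] <- ms[["mean"]]
        stats_df$sd[row] <- ms[["sd"]]
        stats_df$delta[row] <- separability(tot_ms[["mean"]], ms[["mean"]])
        stats_df$rho[row] <- conservatism(tot_ms[["sd"]], ms[["sd"]])
      }
      row <- row + 1L
    }
  }

  bg_pairs <- setdiff(pairs, c("CG", "TA"))
  d1 <- stats_df$delta[stats_df$subset %in% bg_pairs & stats_df$class == 1L]
  background_delta1 <- if (all(is.na(d1))) NA_real_ else mean(d1, na.rm = TRUE)

  d_cg1 <- stats_df$delta[stats_df$subset == "CG" & stats_df$class == 1L]
  d_ta1 <- stats_df$delta[stats_df$subset == "TA" & stats_df$class == 1L]
  flags <- selection_flags(delta_cg1 = d_cg1, delta_ta1 = d_ta1,
                           background = background_delta1, margin = margin)

  structure(
    list(genome_id = id, k = k, scheme = scheme, gc_content = gc,
         n_windows = tab$n_windows, total_length = tab$total_length %||% NA,
         stats = stats_df, background_delta1 = background_delta1,
         flags = flags,
         params = list(sqrt_transform = sqrt_transform,
                       include_zeros = include_zeros, margin = margin)),
    class = "genome_profile"
  )
}

.sequence_gc <- function(x_dna) {
  lf <- Biostrings::letterFrequency(x_dna, letters = c("A", "C", "G", "T"))
  tot <- colSums(lf)
  if (sum(tot) == 0) return(NA_real_)
  100 * (tot[["C"]] + tot[["G"]]) / sum(tot)
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("genome_profile '%s': k = %d (%s), G+C = %s%%, %s windows\n",
              x$genome_id, x$k, x$scheme,
              ifelse(is.na(x$gc_content), "NA", sprintf("%.2f", x$gc_content)),
              format(x$n_windows, big.mark = ",")))
  d <- function(xy, cl) profile_value(x, "delta", xy, cl)
  cat(sprintf("  delta_CG1 = %.4f, delta_TA1 = %.4f, background delta1 = %.4f\n",
              d("CG", 1), d("TA", 1), x$background_delta1))
  set <- names(x$flags)[vapply(x$flags, isTRUE, logical(1L))]
  cat("  flags:", if (length(set)) paste(set, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Extract one statistic from a genome profile
#'
#' @param profile a `genome_profile`.
#' @param stat `"delta"`, `"rho"`, `"mean"`, `"sd"` or `"n_members"`.
#' @param xy a dinucleotide pair, or `"total"`.
#' @param class class label (ignored for `"total"`).
#' @return scalar value.
#' @export
profile_value <- function(profile, stat = c("delta", "rho", "mean", "sd", "n_members"),
                          xy = "total", class = NULL) {
  stopifnot(inherits(profile, "genome_profile"))
  stat <- match.arg(stat)
  s <- profile$stats
  i <- if (identical(xy, "total")) which(s$subset == "total")
       else which(s$subset == xy & s$class == class)
  if (length(i) != 1L) stop("no such subset in this profile")
  s[[stat]][i]
}

#' Count the modes of a spectrum
#'
#' Heuristic peak count for labelling spectra as unimodal, bimodal or
#' tri-modal: the RMN histogram is placed on the full integer frequency grid,
#' smoothed with a centered moving average, and local maxima are kept when
#' their topographic prominence exceeds a fraction of the global maximum.
#'
#' @param spectrum a `kmer_spectrum`, or a numeric vector of histogram
#'   heights on a regular grid.
#' @param bandwidth moving-average window width in frequency units (rounded
#'   up to odd). Default `NULL`: 5% of the grid length, at least 3, so the
#'   smoothing scale tracks the spectrum's frequency range.
#' @param min_prominence minimum peak prominence as a fraction of the maximum
#'   smoothed height (default 0.05).
#' @return integer number of peaks (>= 1 for any non-empty spectrum).
#' @export
modality <- function(spectrum, bandwidth = NULL, min_prominence = 0.05) {
  if (inherits(spectrum, "kmer_spectrum")) {
    grid <- 0:max(spectrum$frequency)
    y <- numeric(length(grid))
    y[spectrum$frequency + 1L] <- spectrum$rmn
  } else if (is.numeric(spectrum) && length(spectrum) > 0L) {
    y <- as.numeric(spectrum)
  } else {
    stop("'spectrum' must be a kmer_spectrum or a numeric vector")
  }
  if (all(y == 0)) return(0L)
  w <- if (is.null(bandwidth)) max(3L, as.integer(ceiling(0.05 * length(y))))
       else max(1L, as.integer(bandwidth))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L) {
    # keep the zero padding when locating peaks: heights outside the observed
    # frequency range are genuinely zero, and an edge spike (e.g. the
    # zero-frequency block of a depleted subset) must keep its prominence
    half <- (w - 1L) %/% 2L
    padded <- c(numeric(2L * half), y, numeric(2L * half))
    sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
    y <- sm[!is.na(sm)]
  }
  pk <- .peak_prominences(y)
  sum(pk$prominence >= min_prominence * max(y))
}

# run-level local maxima and their topographic prominence
.peak_prominences <- function(y) {
  r <- rle(y)
  v <- r$values
  n <- length(v)
  if (n == 1L) return(list(height = v, prominence = v))
  left <- c(-Inf, v[-n])
  right <- c(v[-1L], -Inf)
  is_peak <- v > left & v > right
  idx <- which(is_peak)
  prom <- vapply(idx, function(i) {
    h <- v[i]
    key_side <- function(side) {
      lo <- h
      js <- if (side == "l") rev(seq_len(i - 1L)) else seq.int(i + 1L, length.out = n - i)
      if (length(js) == 0L) return(-Inf)  # edge peak: that side does not bound it
      for (j in js) {
        if (v[j] > h) return(lo)
        if (v[j] < lo) lo <- v[j]
      }
      lo
    }
    h - max(key_side("l"), key_side("r"))
  }, numeric(1L))
  list(height = v[idx], prominence = prom)
}
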