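# Independent oracles and fixture builders used across the suite.

# character-by-character sliding-window k-mer counter (the counting oracle)
naive_count_kmers <- function(sequence, k) {
  sequence <- toupper(sequence)
  u <- kmer_universe(k)
  counts <- stats::setNames(integer(length(u)), u)
  for (s in sequence) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("^[ACGT]+$", w)) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# scan-with-step-1 dinucleotide occurrence oracle
naive_xy_count <- function(kmer, xy) {
  n <- 0L
  for (i in seq_len(nchar(kmer) - 1L))
    if (substr(kmer, i, i + 1L) == xy) n <- n + 1L
  n
}

random_dna <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# Minimal genome_profile with prescribed statistics, for group-level tests
# that exercise the analysis layer without simulating sequences.
fake_profile <- function(id, overrides = list(), gc = 50, scheme = "three-way",
                         k = 8) {
  cap <- if (scheme == "three-way") 2L else 1L
  pairs <- kmerselect::xy_pairs()
  stats_df <- data.frame(
    subset = c("total", rep(pairs, each = cap + 1L)),
    class = c(NA_integer_, rep(0:cap, times = length(pairs))),
    n_members = 100L, mean = 1, sd = 1, delta = 1, rho = 1
  )
  for (nm in names(overrides)) {
    parts <- strsplit(nm, "_")[[1L]]  # e.g. "delta_CG1"
    stat <- parts[1L]
    xy <- substr(parts[2L], 1L, 2L)
    cl <- as.integer(substr(parts[2L], 3L, 3L))
    i <- which(stats_df$subset == xy & stats_df$class == cl)
    stats_df[[stat]][i] <- overrides[[nm]]
  }
  bg_pairs <- setdiff(pairs, c("CG", "TA"))
  bg <- mean(stats_df$delta[stats_df$subset %in% bg_pairs & stats_df$class == 1L])
  structure(
    list(genome_id = id, k = k, scheme = scheme, gc_content = gc,
         n_windows = NA, total_length = NA, stats = stats_df,
         background_delta1 = bg,
         flags = c(cg_obvious = NA, ta_obvious = NA,
                   strong_cg_inhibition = NA, strong_ta_inhibition = NA),
         params = list(sqrt_transform = TRUE, include_zeros = TRUE,
                       margin = 0.05)),
    class = "genome_profile"
  )
}
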