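#' Specification of a first-order Markov genome
#'
#' Builds the transition matrix of a genome-like sequence whose dinucleotide
#' composition is tunably depleted in CG and/or TA. Starting from the
#' independence matrix matched to a target base composition (all rows equal
#' to the base distribution implied by `gc_target`), the C->G entry is
#' multiplied by `cg_factor` and the T->A entry by `ta_factor`, and rows are
#' renormalized. First-order structure is the minimal model that controls
#' dinucleotide content; the realized stationary composition (which shifts
#' slightly under depletion) is recorded in the spec.
#'
#' @param length sequence length in bp (>= 2).
#' @param cg_factor,ta_factor multiplicative depletion factors in (0, 1]
#'   applied to the C->G and T->A transitions; 1 = no depletion.
#' @param gc_target pre-depletion stationary G+C fraction, in (0.2, 0.8).
#' @param seed RNG seed (mandatory; every spec is reproducible).
#' @return a `markov_spec`: list with `length`, `transition` (4x4
#'   row-stochastic), `initial` (= stationary distribution), `cg_factor`,
#'   `ta_factor`, `gc_target`, `stationary`, `realized_gc`, `seed`.
#' @export
markov_spec <- function(length, cg_factor = 1, ta_factor = 1,
                        gc_target = 0.5, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory and must be a single number")
  if (!is.numeric(length) || length < 2)
    stop("'length' must be >= 2")
  for (f in c(cg_factor, ta_factor))
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1)
      stop("depletion factors must lie in (0, 1]")
  if (!is.numeric(gc_target) || gc_target <= 0.2 || gc_target >= 0.8)
    stop("'gc_target' must lie in (0.2, 0.8); more extreme compositions are not supported")

  bases <- c("A", "C", "G", "T")
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  P <- matrix(rep(p, each = 4L), nrow = 4L, dimnames = list(bases, bases))
  P["C", "G"] <- P["C", "G"] * cg_factor
  P["T", "A"] <- P["T", "A"] * ta_factor
  P <- P / rowSums(P)

  stat <- .stationary_distribution(P)
  structure(
    list(length = as.integer(length), transition = P, initial = stat,
         cg_factor = cg_factor, ta_factor = ta_factor, gc_target = gc_target,
         stationary = stat, realized_gc = unname(stat[["C"]] + stat[["G"]]),
         seed = as.integer(seed)),
    class = "markov_spec"
  )
}

.stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(P))
}

#' @export
print.markov_spec <- function(x, ...) {
  cat(sprintf(
    "markov_spec: %s bp, cg_factor = %.3g, ta_factor = %.3g, gc_target = %.2f (realized %.4f), seed = %d\n",
    format(x$length, big.mark = ","), x$cg_factor, x$ta_factor,
    x$gc_target, x$realized_gc, x$seed))
  invisible(x)
}

#' Generate a Markov genome sequence
#'
#' Simulates a first-order Markov chain over {A,C,G,T} from a [markov_spec()].
#' The first base is drawn from the stationary distribution. Deterministic
#' given the spec's seed.
#'
#' @param spec a `markov_spec`.
#' @return a single character string of length `spec$length`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  set.seed(spec$seed)
  cum_trans <- t(apply(spec$transition, 1L, cumsum))
  cum_init <- cumsum(spec$initial)
  markov_sim_cpp(cum_trans, cum_init, spec$length)
}

#' Generate a graded group of synthetic genomes
#'
#' Builds n Markov genomes whose CG (and optionally TA) depletion factors
#' are evenly spaced across given ranges — the synthetic analogue of a
#' species group with graded selection intensity. Per-genome seeds are
#' derived deterministically from the group seed, and the true generating
#' parameters are returned for parameter-recovery checks.
#'
#' @param n number of genomes (>= 3).
#' @param cg_range length-2 numeric: cg_factor for the first and last genome
#'   (a scalar gives a constant factor).
#' @param ta_range as `cg_range`, for ta_factor.
#' @param length sequence length per genome in bp.
#' @param seed group seed.
#' @param anti_correlate reverse the ta_factor grading relative to the
#'   cg_factor grading (mutual-inhibition scenario).
#' @param gc_target pre-depletion G+C fraction for every genome.
#' @return a `genome_group`: list with `sequences` (named list of character
#'   strings), `truth` (data frame: `genome_id`, `cg_factor`, `ta_factor`,
#'   `seed`, `realized_gc`) and `specs`.
#' @export
make_group <- function(n, cg_range = c(1, 0.2), ta_range = 1, length = 1e6,
                       seed = 1, anti_correlate = FALSE, gc_target = 0.5) {
  if (!is.numeric(n) || n < 3) stop("'n' must be >= 3")
  n <- as.integer(n)
  grade <- function(r) {
    if (length(r) == 1L) rep(r, n) else seq(r[1L], r[2L], length.out = n)
  }
  cg <- grade(cg_range)
  ta <- grade(ta_range)
  if (anti_correlate) ta <- rev(ta)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("synthetic_g%02d", seq_len(n))
  specs <- lapply(seq_len(n), function(i)
    markov_spec(length = length, cg_factor = cg[i], ta_factor = ta[i],
                gc_target = gc_target, seed = seeds[i]))
  sequences <- stats::setNames(lapply(specs, generate_genome), ids)
  truth <- data.frame(
    genome_id = ids, cg_factor = cg, ta_factor = ta, seed = seeds,
    realized_gc = vapply(specs, function(s) s$realized_gc, numeric(1L))
  )
  structure(list(sequences = sequences, truth = truth,
                 specs = stats::setNames(specs, ids)),
            class = "genome_group")
}

#' @export
print.genome_group <- function(x, ...) {
  cat(sprintf("genome_group: %d genomes of %s bp, cg_factor %.3g..%.3g, ta_factor %.3g..%.3g\n",
              nrow(x$truth), format(x$specs[[1L]]$length, big.mark = ","),
              x$truth$cg_factor[1L], x$truth$cg_factor[nrow(x$truth)],
              x$truth$ta_factor[1L], x$truth$ta_factor[nrow(x$truth)]))
  invisible(x)
}

#' Write a genome group as FASTA plus a parameter sidecar
#'
#' One FASTA per genome (spec parameters in the header line) and one
#' `group.json` recording the true generating parameters.
#'
#' @param group a `genome_group`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_group <- function(group, dir) {
  stopifnot(inherits(group, "genome_group"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  for (i in seq_len(nrow(group$truth))) {
    id <- group$truth$genome_id[i]
    sp <- group$specs[[id]]
    x <- Biostrings::DNAStringSet(group$sequences[[id]])
    names(x) <- sprintf("%s cg_factor=%g ta_factor=%g gc_target=%g seed=%d",
                        id, sp$cg_factor, sp$ta_factor, sp$gc_target, sp$seed)
    fa <- file.path(dir, paste0(id, ".fasta"))
    Biostrings::writeXStringSet(x, fa)
    paths <- c(paths, fa)
  }
  js <- file.path(dir, "group.json")
  jsonlite::write_json(group$truth, js, dataframe = "rows", digits = NA)
  invisible(c(paths, js))
}
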