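#' CG/TA selection flags for one genome
#'
#' CG (resp. TA) independent selection is called *obvious* when the CG1
#' (TA1) separability exceeds the background value, the mean separability of
#' the other 14 XY1 spectra. *Strong inhibition* of one selection is called
#' when its separability falls a configurable margin below the background.
#'
#' @param delta_cg1,delta_ta1 separability of the CG1 / TA1 spectra, or a
#'   `genome_profile` as the first argument.
#' @param background background separability (mean of the other 14 XY1).
#' @param margin strong-inhibition margin m: strong inhibition when
#'   delta < background * (1 - m). Default 0.05. The raw deltas always
#'   accompany the flags so results can be re-thresholded.
#' @return named logical vector (`cg_obvious`, `ta_obvious`,
#'   `strong_cg_inhibition`, `strong_ta_inhibition`), NA where inputs are
#'   undefined, with the inputs attached as attribute `"values"`.
#' @export
selection_flags <- function(delta_cg1, delta_ta1 = NULL, background = NULL,
                            margin = 0.05) {
  if (inherits(delta_cg1, "genome_profile")) {
    p <- delta_cg1
    background <- p$background_delta1
    delta_ta1 <- profile_value(p, "delta", "TA", 1L)
    delta_cg1 <- profile_value(p, "delta", "CG", 1L)
  }
  stopifnot(is.numeric(margin), length(margin) == 1L, margin >= 0)
  flag <- function(x) if (is.null(x) || is.na(x) || is.null(background) ||
                          is.na(background)) c(NA, NA) else
    c(x > background, x < background * (1 - margin))
  cg <- flag(delta_cg1)
  ta <- flag(delta_ta1)
  out <- c(cg_obvious = cg[1L], ta_obvious = ta[1L],
           strong_cg_inhibition = cg[2L], strong_ta_inhibition = ta[2L])
  attr(out, "values") <- c(delta_cg1 = delta_cg1 %||% NA_real_,
                           delta_ta1 = delta_ta1 %||% NA_real_,
                           background = background %||% NA_real_,
                           margin = margin)
  out
}

#' Wide per-genome table of profile statistics
#'
#' One row per genome with `genome_id`, `gc_content`, `background_delta1`
#' and a `delta_XYc` / `rho_XYc` column for every subset (plus
#' `delta_total`, `rho_total`).
#'
#' @param profiles list of `genome_profile` objects.
#' @return data frame with one row per profile.
#' @export
profiles_table <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1L), "genome_profile")))
  rows <- lapply(profiles, function(p) {
    s <- p$stats
    lab <- ifelse(s$subset == "total", "total", paste0(s$subset, s$class))
    out <- c(as.list(stats::setNames(s$delta, paste0("delta_", lab))),
             as.list(stats::setNames(s$rho, paste0("rho_", lab))))
    c(list(genome_id = p$genome_id, gc_content = p$gc_content,
           background_delta1 = p$background_delta1), out)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Pearson r with two-tailed p on pairwise-complete observations
.cor_row <- function(x, y, min_n = 3L) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n)
    return(list(n = n, r = NA_real_, p = NA_real_,
                note = sprintf("fewer than %d complete pairs", min_n)))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(n = n, r = NA_real_, p = NA_real_, note = "zero variance"))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = "two.sided")
  list(n = n, r = unname(ct$estimate), p = ct$p.value, note = "")
}

#' Separability-conservatism correlations across a genome group
#'
#' For CG and TA, computes the Pearson correlations (two-tailed) between the
#' statistics that characterize the selection pattern: delta1-rho1 and
#' delta2-rho2 (evolution correlation), delta1-delta2 and rho1-rho2
#' (evolution homoplasy), and delta0-rho0; plus the cross pair
#' delta_CG1-delta_TA1 (mutual inhibition).
#'
#' @param profiles list of `genome_profile` objects (>= 3).
#' @return data frame: `pair`, `var_x`, `var_y`, `n`, `r`, `p`, `note`.
#' @export
group_correlations <- function(profiles) {
  tab <- profiles_table(profiles)
  if (nrow(tab) < 3L) stop("need at least 3 profiles")
  pairs <- list()
  for (xy in c("CG", "TA")) {
    pairs <- c(pairs, list(
      c(paste0("delta_", xy, "1"), paste0("rho_", xy, "1")),
      c(paste0("delta_", xy, "2"), paste0("rho_", xy, "2")),
      c(paste0("delta_", xy, "1"), paste0("delta_", xy, "2")),
      c(paste0("rho_", xy, "1"), paste0("rho_", xy, "2")),
      c(paste0("delta_", xy, "0"), paste0("rho_", xy, "0"))
    ))
  }
  pairs <- c(pairs, list(c("delta_CG1", "delta_TA1")))
  pairs <- Filter(function(p) all(p %in% names(tab)), pairs)
  out <- lapply(pairs, function(p) {
    cr <- .cor_row(tab[[p[1L]]], tab[[p[2L]]])
    data.frame(pair = paste(p[1L], p[2L], sep = " ~ "),
               var_x = p[1L], var_y = p[2L],
               n = cr$n, r = cr$r, p = cr$p, note = cr$note)
  })
  do.call(rbind, out)
}

#' Variance screen of XY separabilities with F-tests
#'
#' Computes the variance of each of the 16 XY separabilities (one class)
#' across the group, then two-tailed variance-ratio F-tests of CG against
#' each of GC/CC/GG and TA against each of AT/AA/TT, with the larger variance
#' in the numerator.
#'
#' @param profiles list of `genome_profile` objects (>= 3).
#' @param class which class's separability to screen (default 1).
#' @return list with `variances` (named numeric, one per XY pair) and
#'   `f_tests` (data frame: `comparison`, `var_a`, `var_b`, `statistic`,
#'   `df1`, `df2`, `p`, `note`).
#' @export
separability_variance_screen <- function(profiles, class = 1L) {
  tab <- profiles_table(profiles)
  if (nrow(tab) < 3L) stop("need at least 3 profiles")
  pairs <- xy_pairs()
  cols <- paste0("delta_", pairs, class)
  missing <- !cols %in% names(tab)
  if (any(missing))
    stop(sprintf("class %d separabilities not present (scheme?)", class))
  vals <- lapply(cols, function(cl) tab[[cl]][is.finite(tab[[cl]])])
  names(vals) <- pairs
  variances <- vapply(vals, function(v) if (length(v) >= 2L) stats::var(v) else NA_real_,
                      numeric(1L))
  comparisons <- rbind(
    c("CG", "GC"), c("CG", "CC"), c("CG", "GG"),
    c("TA", "AT"), c("TA", "AA"), c("TA", "TT")
  )
  f_tests <- do.call(rbind, lapply(seq_len(nrow(comparisons)), function(i) {
    a <- comparisons[i, 1L]; b <- comparisons[i, 2L]
    va <- variances[[a]]; vb <- variances[[b]]
    na <- length(vals[[a]]); nb <- length(vals[[b]])
    base <- data.frame(comparison = paste(a, "vs", b), var_a = va, var_b = vb,
                       statistic = NA_real_, df1 = NA_integer_,
                       df2 = NA_integer_, p = NA_real_, note = "")
    if (is.na(va) || is.na(vb)) { base$note <- "insufficient data"; return(base) }
    if (va == 0 && vb == 0) { base$note <- "both variances zero"; return(base) }
    # larger variance in the numerator, two-tailed p
    if (va >= vb) { f <- va / vb; df1 <- na - 1L; df2 <- nb - 1L }
    else          { f <- vb / va; df1 <- nb - 1L; df2 <- na - 1L }
    base$statistic <- f; base$df1 <- df1; base$df2 <- df2
    base$p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
    base
  }))
  list(variances = variances, f_tests = f_tests)
}

#' Group means with t-based confidence intervals
#'
#' Mean and two-sided confidence interval (t distribution, n-1 df) of every
#' delta and rho statistic across the group.
#'
#' @param profiles list of `genome_profile` objects (>= 2).
#' @param conf.level confidence level (default 0.95).
#' @return data frame: `param`, `n`, `mean`, `lower`, `upper`.
#' @export
group_point_estimates <- function(profiles, conf.level = 0.95) {
  tab <- profiles_table(profiles)
  if (nrow(tab) < 2L) stop("need at least 2 profiles")
  params <- grep("^(delta|rho)_", names(tab), value = TRUE)
  out <- lapply(params, function(pm) {
    v <- tab[[pm]][is.finite(tab[[pm]])]
    n <- length(v)
    if (n < 2L)
      return(data.frame(param = pm, n = n, mean = if (n) mean(v) else NA_real_,
                        lower = NA_real_, upper = NA_real_))
    m <- mean(v)
    half <- stats::qt(1 - (1 - conf.level) / 2, df = n - 1L) * stats::sd(v) / sqrt(n)
    data.frame(param = pm, n = n, mean = m, lower = m - half, upper = m + half)
  })
  do.call(rbind, out)
}

#' Correlation of selection intensities with G+C content
#'
#' Pearson correlation (two-tailed) of delta/rho for the CG1, CG2, TA1, TA2
#' spectra against genome G+C content across the group.
#'
#' @param profiles list of `genome_profile` objects (>= 3).
#' @return data frame: `param`, `n`, `r`, `p`, `note`.
#' @export
gc_correlation <- function(profiles) {
  tab <- profiles_table(profiles)
  if (nrow(tab) < 3L) stop("need at least 3 profiles")
  params <- c("delta_CG1", "delta_CG2", "rho_CG1", "rho_CG2",
              "delta_TA1", "delta_TA2", "rho_TA1", "rho_TA2")
  params <- intersect(params, names(tab))
  out <- lapply(params, function(pm) {
    cr <- .cor_row(tab[[pm]], tab$gc_content)
    data.frame(param = pm, n = cr$n, r = cr$r, p = cr$p, note = cr$note)
  })
  do.call(rbind, out)
}

#' Order genomes by CG1 separability
#'
#' The display convention for intensity distributions: genomes arranged by
#' their delta_CG1 value from small to large.
#'
#' @param profiles list of `genome_profile` objects.
#' @return character vector of genome ids, ascending in delta_CG1 (NA last).
#' @export
arrange_by_cg1 <- function(profiles) {
  tab <- profiles_table(profiles)
  tab$genome_id[order(tab$delta_CG1, na.last = TRUE)]
}
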