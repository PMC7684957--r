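#' Read a FASTA file
#'
#' Thin wrapper around `Biostrings::readDNAStringSet` (gzip-transparent).
#' Record order is preserved; ambiguity codes are kept and handled later by
#' the window-skipping rule in [count_kmers()].
#'
#' @param path path to a FASTA or gzipped FASTA file.
#' @return a `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("FASTA file not found: %s", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                 path, conditionMessage(e))))
  if (length(x) == 0L) stop(sprintf("empty FASTA input: %s", path))
  x
}

.meta_header <- function(fields) {
  paste0("# ", names(fields), " = ", unlist(fields))
}

#' Write a spectrum as TSV with a metadata header
#'
#' Two data columns of interest (frequency, rmn) plus n_kmers; '#'-prefixed
#' metadata lines record k, subset label, member count and window count.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  meta <- .meta_header(list(k = attr(spectrum, "k"),
                            subset_label = attr(spectrum, "subset_label"),
                            n_members = attr(spectrum, "n_members"),
                            n_windows = attr(spectrum, "n_windows")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.table(as.data.frame(spectrum), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a genome profile as TSV plus JSON metadata
#'
#' The TSV holds one row per (subset, class) with n_members, mean, sd, delta
#' and rho; the JSON sidecar holds genome-level values (G+C content,
#' background delta1, flags) and the run parameters.
#'
#' @param profile a `genome_profile`.
#' @param path_tsv,path_json output paths; `path_json` defaults to
#'   `path_tsv` with a `.json` extension.
#' @return invisibly, the two paths.
#' @export
write_profile <- function(profile, path_tsv,
                          path_json = sub("\\.tsv$", ".json", path_tsv)) {
  stopifnot(inherits(profile, "genome_profile"))
  meta <- .meta_header(list(genome_id = profile$genome_id, k = profile$k,
                            scheme = profile$scheme,
                            sqrt_transform = profile$params$sqrt_transform,
                            include_zeros = profile$params$include_zeros))
  con <- file(path_tsv, "w")
  writeLines(meta, con)
  write.table(profile$stats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  fl <- as.list(profile$flags)
  jsonlite::write_json(
    list(genome_id = profile$genome_id, k = profile$k, scheme = profile$scheme,
         gc_content = profile$gc_content, n_windows = profile$n_windows,
         background_delta1 = profile$background_delta1, flags = fl,
         params = profile$params),
    path_json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(path_tsv, path_json))
}

#' Write group-level reports
#'
#' Writes the correlation table, the variance screen with F-tests, the
#' point-estimate table and the genome ordering (ascending delta_CG1) as
#' TSV files into a directory.
#'
#' @param profiles list of `genome_profile` objects.
#' @param dir output directory (created if needed).
#' @param class class used for the variance screen (default 1).
#' @return invisibly, the paths written.
#' @export
write_group_report <- function(profiles, dir, class = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    tsv(group_correlations(profiles), "correlations.tsv"),
    tsv(gc_correlation(profiles), "gc_correlations.tsv"),
    tsv(group_point_estimates(profiles), "point_estimates.tsv"),
    tsv(data.frame(genome_id = arrange_by_cg1(profiles)), "genome_order.tsv")
  )
  vs <- separability_variance_screen(profiles, class = class)
  paths <- c(paths,
             tsv(data.frame(xy = names(vs$variances), variance = vs$variances),
                 "variances.tsv"),
             tsv(vs$f_tests, "f_tests.tsv"))
  invisible(paths)
}
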