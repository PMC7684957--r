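Package: kmerselect
Title: K-mer Spectrum Statistics for CG and TA Dinucleotide Selection in Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free characterization of genome sequences through k-mer
    frequency spectra. Counts k-mers with a 1-bp sliding window, partitions the
    k-mer universe by the number of overlapping occurrences of a fixed XY
    dinucleotide (XY0/XY1/XY2 subsets), and computes square-root-normalized
    spectrum statistics -- mean, standard deviation, separability and
    conservatism -- that quantify directional depletion of CG- and TA-containing
    k-mers. Includes exact combinatorial oracles for subset sizes and subset G+C
    content, group-level correlation, variance-screen and confidence-interval
    analyses across genomes, a peak-count heuristic for spectrum modality, and a
    first-order Markov genome simulator with tunable CG/TA depletion for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
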