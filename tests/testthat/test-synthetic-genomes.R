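test_that("markov specs are row-stochastic and validated", {
  sp <- markov_spec(1000, cg_factor = 0.3, ta_factor = 0.7, gc_target = 0.45,
                    seed = 1)
  expect_equal(unname(rowSums(sp$transition)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(sp$transition >= 0))
  expect_equal(sum(sp$stationary), 1, tolerance = 1e-12)

  # no depletion at gc 0.5: i.i.d. uniform
  spu <- markov_spec(1000, seed = 2)
  expect_equal(unname(spu$transition), matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(spu$realized_gc, 0.5, tolerance = 1e-12)

  expect_error(markov_spec(1000, cg_factor = 0, seed = 1), "\\(0, 1\\]")
  expect_error(markov_spec(1000, cg_factor = 1.5, seed = 1), "\\(0, 1\\]")
  expect_error(markov_spec(1000, gc_target = 0.1, seed = 1), "0.2")
  expect_error(markov_spec(1000, cg_factor = 0.5), "seed")
})

test_that("depletion suppresses the CG dinucleotide below independence", {
  sp <- markov_spec(1e6, cg_factor = 0.2, seed = 3)
  # Hand-derived stationary solution at cg_factor = 0.2, gc_target = 0.5:
  # P[C,G] = (0.25 * 0.2) / 0.8 = 1/16; balance gives pi_C = 4/15 and
  # pi_G = 1/5, so the depletion ratio is P[C,G] / pi_G = 5/16 = 0.3125
  # (row renormalization gives back some of the removed mass).
  cg_freq <- sp$stationary[["C"]] * sp$transition["C", "G"]
  indep <- sp$stationary[["C"]] * sp$stationary[["G"]]
  expect_equal(sp$transition["C", "G"], 1 / 16, tolerance = 1e-12)
  expect_equal(sp$stationary[["C"]], 4 / 15, tolerance = 1e-8)
  expect_equal(cg_freq / indep, 0.3125, tolerance = 1e-6)
  expect_lt(cg_freq, 0.5 * indep)
})

test_that("generation is seed-deterministic and matches its transition matrix", {
  sp <- markov_spec(2e5, cg_factor = 0.4, gc_target = 0.55, seed = 41)
  g1 <- generate_genome(sp)
  g2 <- generate_genome(sp)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 2e5)
  g3 <- generate_genome(markov_spec(2e5, cg_factor = 0.4, gc_target = 0.55,
                                    seed = 42))
  expect_false(identical(g1, g3))

  # empirical dinucleotide frequencies within 3 binomial SEs of the model
  dn <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(g1))
  n <- sum(dn)
  base_n <- Biostrings::letterFrequency(Biostrings::DNAString(g1),
                                        c("A", "C", "G", "T"))
  for (a in c("A", "C", "G", "T")) {
    for (b in c("A", "C", "G", "T")) {
      p_model <- sp$transition[a, b]
      n_a <- base_n[[a]]
      se <- sqrt(p_model * (1 - p_model) / n_a)
      p_obs <- dn[[paste0(a, b)]] / n_a
      expect_lt(abs(p_obs - p_model), 4 * se + 2 / n_a,
                label = sprintf("dinucleotide %s%s", a, b))
    }
  }
})

test_that("a uniform spec gives near-uniform dinucleotide usage", {
  g <- generate_genome(markov_spec(2e5, seed = 55))
  dn <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(g))
  p <- dn / sum(dn)
  se <- sqrt((1 / 16) * (15 / 16) / sum(dn))
  expect_true(all(abs(p - 1 / 16) < 4 * se))
})

test_that("graded groups are reproducible and carry their true parameters", {
  grp <- make_group(3, cg_range = c(1, 0.5), length = 2e4, seed = 7)
  expect_equal(nrow(grp$truth), 3)
  expect_equal(grp$truth$cg_factor, c(1, 0.75, 0.5))
  expect_equal(grp$truth$ta_factor, rep(1, 3))
  grp2 <- make_group(3, cg_range = c(1, 0.5), length = 2e4, seed = 7)
  expect_identical(grp$sequences, grp2$sequences)

  anti <- make_group(4, cg_range = c(1, 0.2), ta_range = c(1, 0.2),
                     length = 1e3, seed = 8, anti_correlate = TRUE)
  expect_equal(anti$truth$ta_factor, rev(anti$truth$cg_factor))
  expect_error(make_group(2, length = 1e3, seed = 1), ">= 3")

  # minimal group runs end-to-end through the analysis layer
  profs <- mapply(function(s, id) profile_genome(s, k = 4, id = id),
                  grp$sequences, grp$truth$genome_id, SIMPLIFY = FALSE)
  expect_s3_class(group_correlations(profs), "data.frame")
})

test_that("uniform genomes do not trigger false strong-selection signals", {
  set.seed(123)
  seeds <- sample.int(1e6, 30)
  fired <- logical(length(seeds))
  dev <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    g <- generate_genome(markov_spec(1e5, seed = seeds[i]))
    p <- profile_genome(g, k = 6)
    fired[i] <- isTRUE(p$flags[["cg_obvious"]])
    dev[i] <- abs(profile_value(p, "delta", "CG", 1) - 1)
  }
  # under the null the obvious-flag is a coin flip against the background;
  # it must not fire systematically, and delta_CG1 must hug 1
  expect_lte(mean(fired), 0.6)
  expect_lt(max(dev), 0.03)
})

test_that("rank order of true depletion is recovered by delta_CG1", {
  grp <- make_group(8, cg_range = c(1, 0.2), length = 2e5, seed = 77)
  d <- vapply(seq_len(8), function(i)
    profile_value(profile_genome(grp$sequences[[i]], k = 6), "delta", "CG", 1),
    numeric(1))
  expect_equal(cor(d, grp$truth$cg_factor, method = "spearman"), -1)
})
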