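test_that("selection flags follow the background criterion with a margin", {
  fl <- selection_flags(delta_cg1 = 1.4, delta_ta1 = 0.9, background = 1.0)
  expect_true(fl[["cg_obvious"]])
  expect_false(fl[["ta_obvious"]])
  expect_true(fl[["strong_ta_inhibition"]])
  expect_false(fl[["strong_cg_inhibition"]])

  fl <- selection_flags(delta_cg1 = 1.0, delta_ta1 = 1.0, background = 1.0)
  expect_false(any(fl))

  # margin controls the strong-inhibition threshold
  expect_false(selection_flags(1.2, 0.96, 1.0, margin = 0.05)[["strong_ta_inhibition"]])
  expect_true(selection_flags(1.2, 0.96, 1.0, margin = 0.02)[["strong_ta_inhibition"]])

  # undefined inputs give NA flags, not FALSE
  fl <- selection_flags(NA_real_, 0.9, 1.0)
  expect_true(is.na(fl[["cg_obvious"]]))
  expect_false(is.na(fl[["ta_obvious"]]))
  fl <- selection_flags(1.2, 0.9, NA_real_)
  expect_true(all(is.na(fl)))
})

test_that("group correlations recover exact and degenerate relationships", {
  vals <- seq(1, 2, length.out = 10)
  profs <- lapply(seq_along(vals), function(i)
    fake_profile(paste0("g", i),
                 list(delta_CG1 = vals[i], rho_CG1 = vals[i],
                      delta_CG2 = 3 - vals[i])))
  gc <- group_correlations(profs)
  r_d1r1 <- gc$r[gc$pair == "delta_CG1 ~ rho_CG1"]
  expect_equal(r_d1r1, 1)
  expect_equal(gc$r[gc$pair == "delta_CG1 ~ delta_CG2"], -1)
  # constant columns are reported as undefined, not as spurious correlations
  expect_true(is.na(gc$r[gc$pair == "delta_TA1 ~ rho_TA1"]))
  expect_match(gc$note[gc$pair == "delta_TA1 ~ rho_TA1"], "zero variance")
  expect_error(group_correlations(profs[1:2]), "at least 3")
})

test_that("correlation p-values agree with a permutation estimate", {
  set.seed(77)
  n <- 20
  x <- rnorm(n)
  y <- 0.55 * x + rnorm(n, sd = 0.9)
  profs <- lapply(seq_len(n), function(i)
    fake_profile(paste0("g", i), list(delta_CG1 = x[i], rho_CG1 = y[i])))
  gc <- group_correlations(profs)
  r_obs <- gc$r[gc$pair == "delta_CG1 ~ rho_CG1"]
  p_obs <- gc$p[gc$pair == "delta_CG1 ~ rho_CG1"]
  B <- 1000
  r_perm <- replicate(B, abs(cor(x, sample(y))))
  p_perm <- (1 + sum(r_perm >= abs(r_obs))) / (B + 1)
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_obs - p_perm), 3 * mc_se + 0.01)
})

test_that("point estimates use the t distribution with n-1 df", {
  profs <- lapply(1:3, function(i) fake_profile(paste0("g", i)))
  pe <- group_point_estimates(profs)
  row <- pe[pe$param == "delta_CG1", ]
  expect_equal(row$mean, 1)
  expect_equal(row$upper - row$lower, 0)

  profs2 <- lapply(1:2, function(i)
    fake_profile(paste0("g", i), list(delta_CG1 = c(0, 2)[i])))
  pe2 <- group_point_estimates(profs2)
  row2 <- pe2[pe2$param == "delta_CG1", ]
  expect_equal(row2$mean, 1)
  expect_equal(row2$upper, 1 + 12.706, tolerance = 1e-4)
  expect_equal(row2$lower, 1 - 12.706, tolerance = 1e-4)
  expect_true(all(pe2$lower <= pe2$mean & pe2$mean <= pe2$upper, na.rm = TRUE))
})

test_that("confidence intervals cover the generating mean at the nominal rate", {
  set.seed(31)
  hits <- 0L
  for (rep in 1:100) {
    v <- rnorm(8, mean = 1.3, sd = 0.2)
    m <- mean(v)
    half <- qt(0.975, 7) * sd(v) / sqrt(8)
    if (m - half <= 1.3 && 1.3 <= m + half) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("variance screen flags heterogeneity and handles degenerate groups", {
  # identical profiles: all variances zero, tests undefined
  profs <- lapply(1:5, function(i) fake_profile(paste0("g", i)))
  vs <- separability_variance_screen(profs)
  expect_true(all(vs$variances == 0))
  expect_true(all(is.na(vs$f_tests$p)))
  expect_match(vs$f_tests$note[1], "both variances zero")

  # equal-variance null: F near 1, not significant
  set.seed(13)
  n <- 30
  profs2 <- lapply(seq_len(n), function(i)
    fake_profile(paste0("g", i),
                 list(delta_CG1 = rnorm(1, 1, 0.1), delta_GC1 = rnorm(1, 1, 0.1))))
  vs2 <- separability_variance_screen(profs2)
  f <- vs2$f_tests$statistic[vs2$f_tests$comparison == "CG vs GC"]
  expect_gte(f, 1)  # larger variance in the numerator by construction
  expect_lt(f, 3)
  expect_gt(vs2$f_tests$p[vs2$f_tests$comparison == "CG vs GC"], 0.01)

  # group varying only in CG: var(CG1) dominates, p < 0.05
  set.seed(14)
  profs3 <- lapply(seq_len(n), function(i)
    fake_profile(paste0("g", i),
                 list(delta_CG1 = runif(1, 1, 2), delta_GC1 = rnorm(1, 1, 0.02))))
  vs3 <- separability_variance_screen(profs3)
  expect_gt(vs3$variances[["CG"]], vs3$variances[["GC"]])
  expect_lt(vs3$f_tests$p[vs3$f_tests$comparison == "CG vs GC"], 0.05)
})

test_that("G+C correlations report undefined when G+C is constant", {
  profs <- lapply(1:5, function(i)
    fake_profile(paste0("g", i), list(delta_CG1 = i), gc = 50))
  g <- gc_correlation(profs)
  expect_true(all(is.na(g$r)))
  expect_match(g$note[g$param == "delta_CG1"], "zero variance")
})

test_that("genomes are arranged by ascending CG1 separability", {
  d <- c(1.4, 0.9, 1.1)
  profs <- lapply(1:3, function(i)
    fake_profile(paste0("g", i), list(delta_CG1 = d[i])))
  expect_equal(arrange_by_cg1(profs), c("g2", "g3", "g1"))
})
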