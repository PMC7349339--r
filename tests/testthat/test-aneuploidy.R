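test_that("binning assigns fragments by start position and conserves totals", {
  ref <- make_reference(sim_config(seed = 81, chrom_lengths = c(chrA = 1e6),
                                   n_snps = 5))
  one <- data.frame(chrom = "chrA", start = 100L, end = 144L)
  bm <- bin_counts(one, 50000, ref)
  expect_identical(sum(bm$counts), 1L)
  expect_identical(unname(bm$counts[1, 1]), 1L)
  expect_identical(bm$state, "raw")

  cfg <- sim_config(seed = 81, chrom_lengths = c(chrA = 1e6),
                    n_cfdna_fragments = 1e5)
  fr <- simulate_cfdna(ref, cfg, seed = 81)
  bm2 <- bin_counts(fr, 50000, ref)
  expect_identical(sum(bm2$counts), nrow(fr))
  expect_identical(ncol(bm2$counts), 20L)
  expect_true(all(abs(bm2$counts - 5000) < 3 * sqrt(5000)))

  expect_error(bin_counts(data.frame(chrom = "chrA", start = 2e6, end = 2e6 + 44),
                          50000, ref), "beyond chromosome end")
})

test_that("peak correction resets only outlier bins", {
  ref <- make_reference(sim_config(seed = 82, chrom_lengths = c(chrA = 1e5),
                                   n_snps = 5))
  bm <- bin_counts(data.frame(chrom = "chrA", start = 0L, end = 44L), 1000,
                   ref)
  bm$counts[1, ] <- 100L
  bm$counts[1, 7] <- 1000L
  out <- peak_correction(bm)
  expect_equal(unname(out$counts[1, 7]), mean(c(rep(100, 99), 1000)))
  expect_true(all(out$counts[1, -7] == 100))
  expect_lte(sum(out$counts), sum(bm$counts))

  flat <- bm; flat$counts[1, ] <- 100L
  expect_equal(peak_correction(flat)$counts, flat$counts)
  expect_identical(peak_correction(flat)$state, "peak_corrected")
})

test_that("GC correction equalises stratum means", {
  ref <- make_reference(sim_config(seed = 83, chrom_lengths = c(chrA = 4e4),
                                   n_snps = 5))
  bm <- bin_counts(data.frame(chrom = "chrA", start = 0L, end = 44L), 1000,
                   ref)
  # hand-build two GC strata of 20 bins with means m and 2m
  bm$bins$gc <- rep(c(0.40, 0.50), each = 20)
  bm$counts[1, ] <- rep(c(100L, 200L), each = 20)
  bm$state <- "peak_corrected"
  out <- gc_correct(bm)
  expect_true(all(abs(out$counts[1, ] - 150) < 1e-9))
  expect_equal(mean(out$counts[1, ]), mean(bm$counts[1, ]))

  # uniform GC: identity
  flat <- bm; flat$bins$gc <- 0.45
  expect_equal(gc_correct(flat)$counts, flat$counts)

  # small strata are left alone
  tiny_strat <- bm
  tiny_strat$bins$gc <- c(rep(0.40, 37), 0.61, 0.62, 0.63)
  before <- tiny_strat$counts[1, 38:40]
  expect_equal(gc_correct(tiny_strat)$counts[1, 38:40], before)
})

test_that("chi-squared reduction matches the hand-computed statistic", {
  ref <- make_reference(sim_config(seed = 84, chrom_lengths = c(chrA = 1e4),
                                   n_snps = 5))
  base <- bin_counts(data.frame(chrom = "chrA", start = 0L, end = 44L), 1000,
                     ref)
  counts <- matrix(100, nrow = 4, ncol = 10,
                   dimnames = list(paste0("c", 1:4), NULL))
  # bin 3: half the controls at 2c, half at 0 -> reduced chi2 = N*c/(N-1);
  # bin 10 mirrors it so every control keeps the same total (the statistic
  # is computed after scaling controls to a common total)
  counts[, 3] <- c(200, 200, 0, 0)
  counts[, 10] <- c(0, 0, 200, 200)
  cm <- chimeraNIPT:::.new_binmatrix(base$bins, counts, "gc_corrected")
  out <- chi2_variation_reduction(cm, cm, reduced_chi2_cutoff = 3.5)
  red <- attr(out, "reduced_chi2")
  expect_equal(unname(red[c(3, 10)]), rep(4 * 100 / 3, 2))
  expect_equal(unname(red[-c(3, 10)]), rep(0, 8))
  expect_equal(out$counts[, 3], counts[, 3] / red[3])
  expect_equal(out$counts[, -c(3, 10)], counts[, -c(3, 10)])

  # identical controls: identity
  flat <- chimeraNIPT:::.new_binmatrix(base$bins,
                                       matrix(100, 4, 10,
                                              dimnames = list(paste0("c", 1:4),
                                                              NULL)),
                                       "gc_corrected")
  out_flat <- chi2_variation_reduction(flat, flat)
  expect_equal(out_flat$counts, flat$counts)

  # zero-mean bins are masked everywhere downstream
  zero <- flat; zero$counts[, 5] <- 0
  out_zero <- chi2_variation_reduction(zero, zero)
  expect_true(out_zero$mask[5])
  expect_false(any(out_zero$mask[-5]))
})

test_that("match QC accepts control-like profiles and its own controls", {
  set.seed(85)
  ref <- make_reference(sim_config(seed = 85, chrom_lengths = c(chrA = 5e4),
                                   n_snps = 5))
  base <- bin_counts(data.frame(chrom = "chrA", start = 0L, end = 44L), 1000,
                     ref)
  counts <- matrix(rpois(10 * 50, 500), nrow = 10,
                   dimnames = list(paste0("c", 1:10), NULL))
  cm <- chimeraNIPT:::.new_binmatrix(base$bins, counts, "chi2_corrected")

  mean_profile <- colMeans(counts / rowSums(counts)) * 25000
  expect_true(match_qc(mean_profile, cm)$pass)
  expect_equal(match_qc(colMeans(counts), cm)$score,
               sum((colMeans(counts) / sum(colMeans(counts)) -
                      colMeans(counts / rowSums(counts)))^2))

  # leave-one-out: every control passes QC against the others
  loo_pass <- vapply(1:10, function(i) {
    others <- chimeraNIPT:::.new_binmatrix(base$bins,
                                           counts[-i, , drop = FALSE],
                                           "chi2_corrected")
    match_qc(counts[i, ], others)$pass
  }, logical(1))
  expect_true(all(loo_pass))

  # a permuted profile scores worse than the control mean profile
  perm <- counts[1, sample(50)]
  expect_gt(match_qc(perm, cm)$score, match_qc(mean_profile, cm)$score)

  two <- chimeraNIPT:::.new_binmatrix(base$bins, counts[1:2, ],
                                      "chi2_corrected")
  expect_warning(res <- match_qc(counts[3, ], two), "fewer than 3")
  expect_true(is.na(res$pass))
})

test_that("chromosomal fractions use the fixed denominator and honour masks", {
  cfg <- sim_config(seed = 86, chrom_lengths = toy_chrom_lengths(1 / 5000),
                    n_cfdna_fragments = 5e4)
  fr <- simulate_cfdna(toy_ref, cfg, seed = 86)
  bm <- bin_counts(fr, default_bin_size(toy_ref), toy_ref)
  frac <- chromosomal_fraction(bm, "chr21")
  denom_chroms <- setdiff(paste0("chr", 1:22), c("chr13", "chr18", "chr21"))
  manual <- sum(bm$counts[1, bm$bins$chrom == "chr21"]) /
    sum(bm$counts[1, bm$bins$chrom %in% denom_chroms])
  expect_equal(unname(frac[1]), manual)

  # masked bins leave every sample's totals
  bm2 <- bm
  bm2$mask[which(bm2$bins$chrom == "chr21")[1]] <- TRUE
  expect_lt(chromosomal_fraction(bm2, "chr21")[1], frac[1])

  only_target <- bm
  only_target$counts[1, bm$bins$chrom != "chr21"] <- 0L
  expect_error(chromosomal_fraction(only_target, "chr21"),
               "zero denominator")
})

test_that("z-scores standardise against controls with a strict > 3 call", {
  ctrl <- c(0.0175, 0.0177, 0.0179, 0.0176, 0.0178)
  mu <- mean(ctrl); s <- sd(ctrl)

  at_3sd <- z_score(mu + 3 * s, ctrl)
  expect_equal(at_3sd$z, 3)
  expect_identical(at_3sd$call, "euploid")   # strict >
  expect_identical(z_score(mu + 3.0001 * s, ctrl)$call, "aneuploid")
  expect_equal(z_score(mu, ctrl)$z, 0)

  expect_error(z_score(0.018, rep(0.0177, 4)), "sd = 0")
  expect_error(z_score(0.018, 0.0177), ">= 2 controls")

  # leave-one-out standardisation of controls: mean ~ 0, sd ~ 1
  set.seed(87)
  ctrl_big <- rnorm(40, 0.0177, 1e-4)
  loo_z <- vapply(seq_along(ctrl_big), function(i)
    z_score(ctrl_big[i], ctrl_big[-i])$z, numeric(1))
  expect_lt(abs(mean(loo_z)), 0.3)
  expect_gt(sd(loo_z), 0.7)
  expect_lt(sd(loo_z), 1.3)
})

test_that("cross-validation reproduces the cohort arithmetic and AUC oracle", {
  set.seed(88)
  fr <- c(rnorm(48, 0.0177, 1e-4), rnorm(25, 0.0186, 1e-4))
  names(fr) <- c(sprintf("n%02d", 1:48), sprintf("t%02d", 1:25))
  is_case <- c(rep(FALSE, 48), rep(TRUE, 25))

  cv <- cross_validate(fr, is_case, n_runs = 50, seed = 88)
  expect_identical(cv$n_test, 50L)
  expect_identical(cv$n_train, 23L)

  cv_a <- cross_validate(fr, is_case, n_runs = 20, seed = 5)
  cv_b <- cross_validate(fr, is_case, n_runs = 20, seed = 5)
  expect_identical(cv_a, cv_b)

  # perfect separation
  sep <- c(rnorm(20, 0, 0.1), rnorm(5, 50, 0.1))
  cv_sep <- cross_validate(sep, c(rep(FALSE, 20), rep(TRUE, 5)),
                           n_runs = 30, seed = 1)
  expect_equal(cv_sep$sensitivity, 1)
  expect_equal(cv_sep$specificity, 1)
  expect_equal(cv_sep$auc, 1)
  expect_equal(cv_sep$auc_sd, 0)

  expect_error(cross_validate(fr[1:30], c(rep(FALSE, 15), rep(TRUE, 15)),
                              n_runs = 5), "more controls than cases")

  # AUC: rank statistic equals brute-force pairwise counting, ties at 0.5
  set.seed(89)
  for (i in 1:20) {
    pos <- sample(1:10, 7, replace = TRUE) + rnorm(7, 0, 0.01)
    neg <- sample(1:10, 9, replace = TRUE) + rnorm(9, 0, 0.01)
    if (i %% 2 == 0) { pos <- round(pos); neg <- round(neg) }  # force ties
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(chimeraNIPT:::.auc_rank(pos, neg), brute)
  }
})

test_that("pROC agrees with the package AUC on a random fixture", {
  skip_if_not_installed("pROC")
  set.seed(90)
  z <- c(rnorm(30, 0, 1), rnorm(10, 2, 1))
  lab <- c(rep(0, 30), rep(1, 10))
  ours <- chimeraNIPT:::.auc_rank(z[lab == 1], z[lab == 0])
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, z, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the minimum-fragment sweep evaluates the printed thresholds", {
  set.seed(91)
  n <- 60
  n_filtered <- runif(n, 0.8e6, 3.5e6)
  trisomy <- c(rep("none", 45), rep("chr21", 10), rep("chr18", 5))
  # noise shrinks with depth so higher thresholds cannot hurt sensitivity
  noise <- 1e-4 * sqrt(2.5e6 / n_filtered)
  fr21 <- ifelse(trisomy == "chr21", 0.0186, 0.0177) + rnorm(n, 0, noise)
  fr18 <- ifelse(trisomy == "chr18", 0.0305, 0.0290) + rnorm(n, 0, noise)
  names(fr21) <- names(fr18) <- sprintf("s%02d", 1:n)

  sw <- min_fragment_sweep(list(chr21 = fr21, chr18 = fr18), trisomy,
                           n_filtered, n_runs = 25, seed = 91)
  expect_identical(unique(sw$threshold), c(1.0e6, 1.5e6, 2.0e6, 2.5e6, 3.0e6))
  expect_identical(nrow(sw), 10L)

  # qualifying-sample counts are monotone non-increasing in the threshold
  for (ch in c("chr21", "chr18")) {
    sub <- sw[sw$chrom == ch, ]
    expect_true(all(diff(sub$n_cases + sub$n_controls) <= 0))
  }

  # a cell with no qualifying cases is NA, not zero
  sw2 <- min_fragment_sweep(list(chr13 = fr21), trisomy, n_filtered,
                            n_runs = 5)
  expect_true(all(is.na(sw2$sensitivity)))
})

test_that("case z grows with fetal fraction as dosage predicts", {
  lens <- toy_chrom_lengths(1 / 5000)
  ref <- toy_ref
  bin <- default_bin_size(ref)
  sim_frac <- function(ff, trisomy, seed, n = 2e5) {
    cfg <- sim_config(seed = seed, chrom_lengths = lens, fetal_fraction = ff,
                      trisomy_chrom = trisomy, n_cfdna_fragments = n)
    fr <- simulate_cfdna(ref, cfg, seed = seed)
    bm <- bin_counts(fr, bin, ref)
    unname(chromosomal_fraction(bm, "chr21"))
  }
  ctrl <- vapply(1:20, function(i) sim_frac(0.10, NULL, 1000 + i), numeric(1))
  mu <- mean(ctrl); s <- sd(ctrl)
  mean_z <- vapply(c(0.04, 0.08, 0.12), function(ff) {
    zs <- vapply(1:8, function(i)
      (sim_frac(ff, "chr21", 2000 + round(1e3 * ff) + i) - mu) / s,
      numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_z) > 0))
  # expected z = mu*(ff/2)/sd at each ff, within sampling slack
  # (SE of each mean z is ~1/sqrt(8))
  expected <- mu * c(0.04, 0.08, 0.12) / 2 / s
  expect_lt(max(abs(mean_z - expected)), 1.2)
})
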