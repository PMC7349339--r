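test_that("reference generation is deterministic and respects the repeat budget", {
  cfg <- sim_config(seed = 7, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                    repeat_fraction = 0.5, n_snps = 20)
  ref1 <- make_reference(cfg)
  ref2 <- make_reference(cfg)
  expect_identical(as.character(ref1$seqs), as.character(ref2$seqs))
  expect_identical(as.data.frame(ref1$repeats), as.data.frame(ref2$repeats))
  expect_identical(ref1$snps, ref2$snps)

  # repeat coverage within 2% of the requested fraction
  expect_lt(abs(interval_bp(ref1$repeats) / 2e6 - 0.5), 0.02)

  # SNP sites never fall inside repeats
  snp_gr <- GenomicRanges::GRanges(ref1$snps$chrom,
                                   IRanges::IRanges(ref1$snps$pos, width = 1))
  expect_false(any(IRanges::overlapsAny(snp_gr, ref1$repeats)))

  # GC track values are proper fractions
  bins <- data.frame(chrom = "chr1", start = seq(0, 9e5, 1e5),
                     end = seq(1e5, 1e6, 1e5))
  gc <- gc_of_bins(ref1, bins)
  expect_true(all(gc > 0 & gc < 1))

  no_rep <- make_reference(sim_config(seed = 7,
                                      chrom_lengths = c(chr1 = 1e5),
                                      repeat_fraction = 0, n_snps = 5))
  expect_length(no_rep$repeats, 0)

  expect_error(sim_config(chrom_lengths = c(chr1 = 0)), "zero-length")
})

test_that("cfDNA mixture has binomial fetal share and trisomy dosage 1 + ff/2", {
  cfg <- sim_config(seed = 31, chrom_lengths = toy_chrom_lengths(1 / 5000),
                    fetal_fraction = 0.10, n_cfdna_fragments = 1e5)
  fr <- simulate_cfdna(toy_ref, cfg, seed = 31)
  n_fet <- sum(fr$origin == "fetal")
  expect_lt(abs(n_fet - 1e4), 3 * sqrt(1e5 * 0.1 * 0.9))

  # lengths: origin-specific means, truncated at 20 bp
  len <- fr$end - fr$start
  expect_true(all(len >= 20))
  expect_lt(abs(mean(len[fr$origin == "maternal"]) - 166), 1)
  expect_lt(abs(mean(len[fr$origin == "fetal"]) - 143), 1)

  # dosage: closed-form expected chr21 share under the copy-number model
  cfg_t <- sim_config(seed = 32, chrom_lengths = toy_chrom_lengths(1 / 5000),
                      fetal_fraction = 0.10, trisomy_chrom = "chr21",
                      n_cfdna_fragments = 1e6)
  fr_t <- simulate_cfdna(toy_ref, cfg_t, seed = 32)
  lens <- toy_ref$chrom_lengths
  w_mat <- lens; w_mat["chrY"] <- 0
  w_fet <- lens; w_fet[c("chrX", "chrY")] <- w_fet[c("chrX", "chrY")] / 2
  w_fet["chr21"] <- 1.5 * w_fet["chr21"]
  p_expect <- 0.9 * w_mat[["chr21"]] / sum(w_mat) +
    0.1 * w_fet[["chr21"]] / sum(w_fet)
  p_obs <- mean(fr_t$chrom == "chr21")
  se <- sqrt(p_expect * (1 - p_expect) / 1e6)
  expect_lt(abs(p_obs - p_expect), 3 * se)
  # and the dosage inflation is ~1 + ff/2 relative to the disomic share
  p_disomic <- 0.9 * w_mat[["chr21"]] / sum(w_mat) +
    0.1 * (w_fet[["chr21"]] / 1.5) / (sum(w_fet) - w_fet[["chr21"]] / 3)
  expect_lt(abs(p_expect / p_disomic - (1 + 0.10 / 2)), 0.002)

  # ff = 0: no fetal fragments, chromosome share matches maternal weights
  cfg0 <- sim_config(seed = 33, chrom_lengths = toy_chrom_lengths(1 / 5000),
                     fetal_fraction = 0, n_cfdna_fragments = 2e5)
  fr0 <- simulate_cfdna(toy_ref, cfg0, seed = 33)
  expect_identical(sum(fr0$origin == "fetal"), 0L)
  p21 <- w_mat[["chr21"]] / sum(w_mat)
  expect_lt(abs(mean(fr0$chrom == "chr21") - p21),
            3 * sqrt(p21 * (1 - p21) / 2e5))

  bad <- sim_config(seed = 1, chrom_lengths = c(chrA = 1e5))
  bad$trisomy_chrom <- "chrZZ"
  expect_error(simulate_cfdna(tiny_ref, bad), "chrZZ")
})

test_that("fragmentase pieces stay inside parents and inside the window", {
  cfg <- sim_config(seed = 41, chrom_lengths = c(chrA = 1e6),
                    n_cfdna_fragments = 1e5)
  ref <- make_reference(sim_config(seed = 41, chrom_lengths = c(chrA = 1e6),
                                   n_snps = 10))
  parents <- simulate_cfdna(ref, cfg, seed = 41)
  sub <- fragmentase_and_select(parents, cfg, seed = 42)

  len <- sub$end - sub$start
  expect_true(all(len >= 40 & len <= 50))

  # containment: every piece lies within its parent interval
  expect_true(all(sub$start >= parents$start[sub$parent]))
  expect_true(all(sub$end <= parents$end[sub$parent]))

  # conservation: emitted bp never exceeds parent bp
  expect_lte(sum(len), sum(parents$end - parents$start))

  # retained-piece mean under the Poisson cut model: ~44.8 bp (the hard
  # 40-50 bp window pins the conditional mean near the window midpoint;
  # independently computed by Monte Carlo from the cut model)
  expect_lt(abs(mean(len) - 44.8), 0.3)
})

test_that("self-ligation closes molecules just past the length floor", {
  # 10 parts of 44 bp with a 300 bp floor: 7 parts close one molecule
  parts <- make_frags("chrA", seq(0, 900, 100), seq(44, 944, 100))
  parts <- data.frame(chrom = parts$chrom, start = parts$start,
                      end = parts$end, origin = "maternal")
  cfg <- sim_config(seed = 51, chrom_lengths = c(chrA = 1e4))
  ch <- ligate_chimeras(parts, cfg, seed = 51)
  expect_identical(nrow(ch$molecules), 1L)
  expect_identical(ch$molecules$n_parts, 7L)
  expect_identical(ch$molecules$total_len, 308L)

  # determinism
  ch2 <- ligate_chimeras(parts, cfg, seed = 51)
  expect_identical(ch, ch2)

  # every molecule exceeds the floor; junction offsets tile with no gaps
  cfg2 <- sim_config(seed = 52, chrom_lengths = c(chrA = 1e6),
                     n_cfdna_fragments = 3e4)
  ref <- make_reference(sim_config(seed = 52, chrom_lengths = c(chrA = 1e6),
                                   n_snps = 10))
  sub <- fragmentase_and_select(simulate_cfdna(ref, cfg2, seed = 1), cfg2,
                                seed = 2)
  ch3 <- ligate_chimeras(sub, cfg2, seed = 3)
  expect_true(all(ch3$molecules$total_len > 300))
  by_mol <- split(ch3$parts, ch3$parts$molecule_id)
  tiled <- vapply(by_mol, function(p) {
    p <- p[order(p$part_index), ]
    all(p$mol_offset == cumsum(c(0, utils::head(p$end - p$start, -1))))
  }, logical(1))
  expect_true(all(tiled))

  # renewal approximation for parts per molecule at a 460 bp floor
  cfg4 <- sim_config(seed = 53, chrom_lengths = c(chrA = 1e6),
                     n_cfdna_fragments = 3e4, chimera_min_len = 460)
  ch4 <- ligate_chimeras(sub, cfg4, seed = 4)
  L <- sub$end - sub$start
  mu <- mean(L)
  expected_n <- (460 + mean(L^2) / (2 * mu)) / mu
  expect_lt(abs(mean(ch4$molecules$n_parts) - expected_n), 0.4)
})

test_that("paired reads follow PE geometry and are error-free at rate 0", {
  cfg <- tiny_cfg
  fr <- simulate_cfdna(tiny_ref, cfg, seed = 61)
  sub <- fragmentase_and_select(fr, cfg, seed = 62)
  ch <- ligate_chimeras(sub, cfg, seed = 63)
  reads <- generate_reads(ch, tiny_ref, cfg)
  mol_len <- ch$molecules$total_len

  expect_identical(unname(Biostrings::width(reads$r1)),
                   as.integer(pmin(mol_len, 250)))
  # a 300-320 bp molecule read as PE250: R1/R2 overlap reverse-complement
  # consistently over length r1 + r2 - molecule
  short <- which(mol_len <= 320)[1]
  ov <- 2 * 250 - mol_len[short]
  r1 <- as.character(reads$r1[[short]])
  rc2 <- as.character(Biostrings::reverseComplement(reads$r2[[short]]))
  expect_identical(substr(r1, 250 - ov + 1, 250), substr(rc2, 1, ov))

  # long molecules: R1 and R2 cover disjoint molecule windows
  if (any(mol_len > 500)) {
    i <- which(mol_len > 500)[1]
    mseq <- chimeraNIPT:::.molecule_seqs(ch, tiny_ref)[[i]]
    expect_identical(as.character(reads$r1[[i]]), substr(mseq, 1, 250))
    expect_identical(as.character(reads$r2[[i]]),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(
                         substr(mseq, nchar(mseq) - 249, nchar(mseq))))))
  }

  # substitution errors appear at roughly the configured rate
  cfg_err <- tiny_cfg
  cfg_err$seq_error_rate <- 0.01
  reads_err <- generate_reads(ch, tiny_ref, cfg_err, seed = 64)
  nd <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, as.character(reads$r1), as.character(reads_err$r1)))
  tot <- sum(Biostrings::width(reads$r1))
  expect_lt(abs(nd / tot - 0.01), 3 * sqrt(0.01 * 0.99 / tot) + 1e-4)
})

test_that("amplifet counts follow the genotype and coverage model", {
  cfg <- sim_config(seed = 71, chrom_lengths = toy_chrom_lengths(1 / 5000),
                    fetal_fraction = 0.12, n_snps = 60,
                    amplifet_coverage_mean = 5000)
  ac <- simulate_amplifet(toy_ref$snps[seq_len(60), ], cfg, seed = 71)
  expect_identical(nrow(ac), 60L)
  expect_true(all(ac$ref_count + ac$alt_count == ac$depth))
  expect_lt(abs(mean(ac$depth) - 5000), 3 * sqrt(5000 / 60))

  # informative sites show the paternal allele at ~ff/2
  inf <- ac[ac$informative & ac$depth > 0, ]
  minor <- pmin(inf$alt_count, inf$ref_count) / inf$depth
  expect_lt(abs(mean(minor) - 0.06), 0.01)

  # ff = 0: homozygous-mother sites carry no minor-allele reads
  cfg0 <- cfg; cfg0$fetal_fraction <- 0
  ac0 <- simulate_amplifet(toy_ref$snps[seq_len(60), ], cfg0, seed = 72)
  hom <- ac0[ac0$maternal_gt %in% c(0L, 2L), ]
  expect_true(all(pmin(hom$alt_count, hom$ref_count) == 0))

  # dropout zeroes depth for the configured share of amplicons
  cfg_d <- cfg; cfg_d$snp_dropout <- 0.2
  ac_d <- simulate_amplifet(toy_ref$snps[seq_len(60), ], cfg_d, seed = 73)
  expect_gt(sum(ac_d$depth == 0), 0)
})
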