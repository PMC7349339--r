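#' Bin matrices and variation-reduction corrections
#'
#' Shallow-WGS style aneuploidy calling works on a samples x genomic-bins
#' count matrix. The matrix carries its correction state; corrections are
#' applied in the fixed order peak -> GC -> chi-squared, after which
#' chromosomal fractions and Z-scores are computed.
#'
#' @name bin-matrix
NULL

.new_binmatrix <- function(bins, counts, state, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, nrow(bins))
  structure(list(bins = bins, counts = counts, state = state, mask = mask),
            class = "nipt_binmatrix")
}

#' @export
print.nipt_binmatrix <- function(x, ...) {
  cat(sprintf("nipt_binmatrix: %d sample(s) x %d bins [%s], %d masked\n",
              nrow(x$counts), ncol(x$counts), x$state, sum(x$mask)))
  invisible(x)
}

#' Suggested bin size for a reference
#'
#' 50 kb is the human-scale convention; toy genomes are split into ~1000
#' bins so that per-bin statistics behave comparably.
#'
#' @param reference A `nipt_reference`.
#' @param n_bins Target number of bins (default 1000).
#' @return Bin size in bp.
#' @export
default_bin_size <- function(reference, n_bins = 1000) {
  max(1000L, round(sum(reference$chrom_lengths) / n_bins))
}

#' Count fragments into fixed-width genomic bins
#'
#' Each fragment is assigned to the bin containing its start position.
#' Per-bin GC content is taken from the reference sequence.
#'
#' @param fragments A data.frame of fragments (`chrom`, `start`, `end`) for
#'   one sample, or a named list of such data.frames (one per sample).
#' @param bin_size Bin width in bp.
#' @param reference A `nipt_reference`.
#' @return A `nipt_binmatrix` with state `"raw"`.
#' @export
bin_counts <- function(fragments, bin_size, reference) {
  stopifnot(bin_size > 0, inherits(reference, "nipt_reference"))
  if (is.data.frame(fragments)) fragments <- list(sample1 = fragments)
  lens <- reference$chrom_lengths
  bins <- do.call(rbind, lapply(names(lens), function(chrom) {
    starts <- seq(0L, lens[[chrom]] - 1L, by = bin_size)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + bin_size, lens[[chrom]]))
  }))
  bins$gc <- gc_of_bins(reference, bins)
  # global bin index: offset per chromosome + local bin
  nbin_per_chrom <- table(factor(bins$chrom, levels = names(lens)))
  offset <- c(0, cumsum(as.integer(nbin_per_chrom)))
  names(offset) <- c(names(lens), "..end")

  counts <- t(vapply(fragments, function(fr) {
    if (any(!fr$chrom %in% names(lens)))
      stop("fragment on unknown chromosome")
    if (any(fr$start < 0) || any(fr$start >= lens[fr$chrom]))
      stop("fragment beyond chromosome end")
    gi <- offset[fr$chrom] + fr$start %/% bin_size + 1L
    tabulate(gi, nbins = nrow(bins))
  }, integer(nrow(bins))))
  rownames(counts) <- names(fragments)
  .new_binmatrix(bins, counts, "raw")
}

#' Peak correction
#'
#' Per sample, bins whose count exceeds the mean + 3 SD of that sample's
#' non-zero bins are replaced by the sample mean (single pass). Removes
#' isolated pile-up artefacts before GC correction.
#'
#' @param m A `nipt_binmatrix` with state `"raw"`.
#' @return A `nipt_binmatrix` with state `"peak_corrected"`.
#' @export
peak_correction <- function(m) {
  stopifnot(inherits(m, "nipt_binmatrix"))
  if (m$state != "raw") stop("peak_correction expects a raw matrix")
  counts <- m$counts
  for (s in seq_len(nrow(counts))) {
    x <- counts[s, ]
    nz <- x[x > 0]
    if (length(nz) == 0L) {
      warning("sample ", rownames(counts)[s], " has no counts; unchanged")
      next
    }
    thr <- mean(nz) + 3 * stats::sd(nz)
    if (!is.na(thr)) x[x > thr] <- mean(nz)
    counts[s, ] <- x
  }
  .new_binmatrix(m$bins, counts, "peak_corrected", m$mask)
}

#' GC-stratified count correction
#'
#' Bins are stratified by GC content rounded to 0.01. Per sample, counts in
#' a stratum are rescaled by (global mean bin count / stratum mean bin
#' count), so every well-populated stratum is brought to the common mean.
#' Strata with fewer than `min_stratum_bins` bins are left uncorrected.
#'
#' @param m A `nipt_binmatrix` (state `"peak_corrected"` or `"raw"`).
#' @param min_stratum_bins Minimum bins per GC stratum (default 10).
#' @return A `nipt_binmatrix` with state `"gc_corrected"`.
#' @export
gc_correct <- function(m, min_stratum_bins = 10L) {
  stopifnot(inherits(m, "nipt_binmatrix"))
  strat <- round(m$bins$gc, 2)
  counts <- m$counts
  tab <- table(strat)
  for (s in seq_len(nrow(counts))) {
    x <- counts[s, ]
    gmean <- mean(x)
    for (g in names(tab)) {
      if (tab[[g]] < min_stratum_bins) next
      i <- which(strat == as.numeric(g))
      smean <- mean(x[i])
      if (smean > 0) x[i] <- x[i] * (gmean / smean)
    }
    counts[s, ] <- x
  }
  .new_binmatrix(m$bins, counts, "gc_corrected", m$mask)
}

#' Chi-squared variation reduction
#'
#' Identifies bins whose between-control variability exceeds Poisson
#' expectation. Controls are scaled to a common total; for each bin the
#' chi-squared statistic over controls (expected value = control mean) is
#' reduced by its degrees of freedom, and bins whose reduced chi-squared
#' exceeds `cutoff` have their counts - in every sample - divided by that
#' reduced chi-squared. Bins with zero control mean are masked from all
#' downstream fractions.
#'
#' @param control_matrix `nipt_binmatrix` of the control samples (>= 2).
#' @param all_matrix `nipt_binmatrix` of all samples on identical bins.
#' @param reduced_chi2_cutoff Correction threshold (default 3.5).
#' @return `all_matrix` with corrected counts, state `"chi2_corrected"`,
#'   updated `mask`, and an attribute `reduced_chi2` (per-bin statistic).
#' @export
chi2_variation_reduction <- function(control_matrix, all_matrix,
                                     reduced_chi2_cutoff = 3.5) {
  stopifnot(inherits(control_matrix, "nipt_binmatrix"),
            inherits(all_matrix, "nipt_binmatrix"),
            ncol(control_matrix$counts) == ncol(all_matrix$counts))
  cc <- control_matrix$counts
  if (nrow(cc) < 2) stop("need >= 2 control samples")
  tot <- rowSums(cc)
  cc <- cc * (mean(tot) / tot)  # scale controls to common total
  cbar <- colMeans(cc)
  nctrl <- nrow(cc)
  chi2 <- colSums((cc - rep(cbar, each = nctrl))^2 /
                    rep(pmax(cbar, .Machine$double.eps), each = nctrl))
  red <- chi2 / (nctrl - 1)
  mask <- all_matrix$mask | cbar == 0
  correct <- !mask & red > reduced_chi2_cutoff
  counts <- all_matrix$counts
  if (any(correct))
    counts[, correct] <- sweep(counts[, correct, drop = FALSE], 2,
                               red[correct], "/")
  out <- .new_binmatrix(all_matrix$bins, counts, "chi2_corrected", mask)
  attr(out, "reduced_chi2") <- red
  out
}

#' Genome-wide profile match QC
#'
#' Compares a sample's fraction-normalised bin profile to the control mean
#' profile; the score is the sum of squared deviations. The sample passes
#' if its score does not exceed the mean + 3 SD of the leave-one-out scores
#' of the controls themselves.
#'
#' @param sample_row Numeric vector of the sample's bin counts.
#' @param control_matrix `nipt_binmatrix` of controls (>= 3 for the
#'   pass/fail decision).
#' @return list with `score` and `pass` (`NA` with a warning when fewer
#'   than 3 controls are available).
#' @export
match_qc <- function(sample_row, control_matrix) {
  stopifnot(inherits(control_matrix, "nipt_binmatrix"))
  keep <- !control_matrix$mask
  cc <- control_matrix$counts[, keep, drop = FALSE]
  f_ctrl <- cc / rowSums(cc)
  f_s <- sample_row[keep] / sum(sample_row[keep])
  score <- sum((f_s - colMeans(f_ctrl))^2)
  if (nrow(cc) < 3) {
    warning("fewer than 3 controls; match QC skipped")
    return(list(score = score, pass = NA))
  }
  loo <- vapply(seq_len(nrow(f_ctrl)), function(i)
    sum((f_ctrl[i, ] - colMeans(f_ctrl[-i, , drop = FALSE]))^2), numeric(1))
  list(score = score, pass = score <= mean(loo) + 3 * stats::sd(loo))
}
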