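#' Read a VCF of candidate SNPs into a site table
#'
#' Parses a (small) VCF and extracts the fields the panel-selection filters
#' need: identifier, position, alleles, allele frequency (`AF` INFO tag)
#' and, when genotypes are present, genotype counts.
#'
#' @param vcf_path Path to an uncompressed or gzipped VCF.
#' @return data.frame with `snp_id`, `chrom`, `pos`, `ref`, `alt`, `af`,
#'   `maf`, and `n_hom_ref`, `n_het`, `n_hom_alt` (NA without genotypes).
#' @export
read_panel_vcf <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  out <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, af = af)
  out$maf <- pmin(out$af, 1 - out$af)
  gt <- tryCatch(vcfR::extract.gt(v), error = function(e) NULL)
  if (!is.null(gt)) {
    norm <- gsub("\\|", "/", gt)
    out$n_hom_ref <- rowSums(norm == "0/0", na.rm = TRUE)
    out$n_het <- rowSums(norm == "0/1" | norm == "1/0", na.rm = TRUE)
    out$n_hom_alt <- rowSums(norm == "1/1", na.rm = TRUE)
  } else {
    out$n_hom_ref <- out$n_het <- out$n_hom_alt <- NA_integer_
  }
  out
}

#' Panel selection criteria
#'
#' Defaults mirror the published panel-design rules: biallelic rs-named
#' SNPs only; no indels; no sex chromosomes, mitochondrion or chr6 p-arm
#' (HLA); minor allele frequency at least 0.4; Hardy-Weinberg exact-test
#' p at least 1e-5; LD pruning at r-squared 0.5 in 50-SNP windows stepping
#' by 5.
#'
#' @param min_maf,hwe_p_min,ld_r2_max,ld_window,ld_step Thresholds.
#' @param excluded_chroms Chromosomes excluded outright.
#' @param chr6_parm_end End of the excluded chr6 p-arm interval (bp).
#' @param amplicon_max_len Maximum amplicon length (bp).
#' @return list of class `nipt_panel_criteria`.
#' @export
panel_criteria <- function(min_maf = 0.4, hwe_p_min = 1e-5,
                           ld_r2_max = 0.5, ld_window = 50L, ld_step = 5L,
                           excluded_chroms = c("chrX", "chrY", "X", "Y",
                                               "MT", "chrM"),
                           chr6_parm_end = 59800000,
                           amplicon_max_len = 140L) {
  stopifnot(ld_window > ld_step)
  structure(list(min_maf = min_maf, hwe_p_min = hwe_p_min,
                 ld_r2_max = ld_r2_max, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step),
                 excluded_chroms = excluded_chroms,
                 chr6_parm_end = chr6_parm_end,
                 amplicon_max_len = as.integer(amplicon_max_len)),
            class = "nipt_panel_criteria")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of every heterozygote count that is no
#' more likely than the observed one under the hypergeometric-type HWE
#' distribution. Monomorphic sites return p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes")
  na <- 2 * n_hom_ref + n_het        # count of the reference allele
  nb <- 2 * n_hom_alt + n_het
  if (na == 0 || nb == 0) return(1)
  n_minor <- min(na, nb)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # P(het = h | na, nb) up to a constant:
  # n! / (hom_a! h! hom_b!) * 2^h  with hom_a=(na-h)/2, hom_b=(nb-h)/2
  logp <- lfactorial(n) - lfactorial((na - hets) / 2) - lfactorial(hets) -
    lfactorial((nb - hets) / 2) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(p[p <= obs + 1e-12]))
}

#' LD pruning by sliding-window r-squared
#'
#' Within each window of `window` SNPs, the later SNP of any pair whose
#' genotype-dosage squared correlation reaches `r2_max` is greedily
#' removed; the window then advances by `step`. Constant-genotype SNPs
#' have undefined correlation, treated as unlinked.
#'
#' @param genotype_matrix SNPs x samples matrix of 0/1/2 dosages, SNPs
#'   ordered by position.
#' @param r2_max Removal threshold (default 0.5; removal at r2 >= r2_max).
#' @param window,step Window size and step in SNPs (defaults 50/5).
#' @return Integer indices of the kept SNPs.
#' @export
ld_prune <- function(genotype_matrix, r2_max = 0.5, window = 50L,
                     step = 5L) {
  n <- nrow(genotype_matrix)
  keep <- rep(TRUE, n)
  if (n < 2) return(which(keep))
  starts <- unique(c(seq(1L, max(1L, n - 1L), by = step)))
  for (w0 in starts) {
    w1 <- min(w0 + window - 1L, n)
    idx <- (w0:w1)[keep[w0:w1]]
    if (length(idx) < 2) next
    for (i in seq_along(idx)[-length(idx)]) {
      if (!keep[idx[i]]) next
      gi <- genotype_matrix[idx[i], ]
      if (stats::sd(gi) == 0) next
      for (j in (i + 1):length(idx)) {
        if (!keep[idx[j]]) next
        gj <- genotype_matrix[idx[j], ]
        if (stats::sd(gj) == 0) next
        r2 <- stats::cor(gi, gj)^2
        if (!is.na(r2) && r2 >= r2_max) keep[idx[j]] <- FALSE
      }
    }
  }
  which(keep)
}

#' Apply the panel-selection filters to candidate SNPs
#'
#' Rules are applied in their published order, with per-rule first-failing
#' removal counts: indels; excluded chromosomes (sex, mitochondrial,
#' chr6 p-arm); non-biallelic sites; missing rs identifiers; MAF below the
#' floor; Hardy-Weinberg exact-test p below the floor; LD pruning.
#' Records without an allele frequency are skipped with a warning count.
#'
#' @param records data.frame from [read_panel_vcf()].
#' @param criteria A [panel_criteria()].
#' @param genotype_matrix Optional SNPs x samples dosage matrix (same row
#'   order as `records`) for LD pruning; without it the LD rule is skipped.
#' @return list with `kept` (surviving records), `removed` (data.frame of
#'   rule -> count, in rule order) and `n_skipped` (no allele frequency).
#' @export
filter_snps <- function(records, criteria = panel_criteria(),
                        genotype_matrix = NULL) {
  skip <- is.na(records$af)
  if (any(skip)) warning(sum(skip), " record(s) without AF skipped")
  n_skipped <- sum(skip)
  rec <- records[!skip, , drop = FALSE]
  if (!is.null(genotype_matrix))
    genotype_matrix <- genotype_matrix[!skip, , drop = FALSE]

  reason <- rep("kept", nrow(rec))
  mark <- function(cond, tag) reason[reason == "kept" & cond] <<- tag

  alt_alleles <- strsplit(rec$alt, ",", fixed = TRUE)
  is_indel <- nchar(rec$ref) != 1 |
    vapply(alt_alleles, function(a) any(nchar(a) != 1), logical(1))
  mark(is_indel, "indel")
  excl <- rec$chrom %in% criteria$excluded_chroms |
    (rec$chrom %in% c("chr6", "6") & rec$pos <= criteria$chr6_parm_end)
  mark(excl, "excluded_region")
  multi <- grepl(",", rec$alt)
  mark(multi, "not_biallelic")
  mark(!grepl("^rs", rec$snp_id), "no_rs_id")
  mark(rec$maf < criteria$min_maf, "low_maf")

  has_gt <- !is.na(rec$n_het)
  hwe_p <- rep(NA_real_, nrow(rec))
  todo <- which(reason == "kept" & has_gt)
  for (i in todo)
    hwe_p[i] <- hwe_exact_test(rec$n_hom_ref[i], rec$n_het[i],
                               rec$n_hom_alt[i])
  mark(has_gt & !is.na(hwe_p) & hwe_p < criteria$hwe_p_min, "hwe")

  if (!is.null(genotype_matrix)) {
    cand <- which(reason == "kept")
    if (length(cand) > 1) {
      kept_idx <- ld_prune(genotype_matrix[cand, , drop = FALSE],
                           r2_max = criteria$ld_r2_max,
                           window = criteria$ld_window,
                           step = criteria$ld_step)
      pruned <- cand[-kept_idx]
      if (length(kept_idx) < length(cand)) reason[pruned] <- "ld"
    }
  }

  lev <- c("indel", "excluded_region", "not_biallelic", "no_rs_id",
           "low_maf", "hwe", "ld")
  removed <- data.frame(rule = lev,
                        count = as.integer(table(factor(reason, lev))))
  list(kept = rec[reason == "kept", , drop = FALSE], removed = removed,
       n_skipped = n_skipped)
}

#' Primer candidate check
#'
#' A primer fails on: a homopolymer of four or more identical bases; four
#' or more consecutive dinucleotide repeat units (e.g. ATATATAT); more
#' than three G/C among the last five 3'-end bases; GC fraction outside
#' [0.4, 0.6].
#'
#' @param sequence Primer sequence over A/C/G/T, length >= 15.
#' @return list with `pass` and `reason` (`""` when passing).
#' @export
primer_ok <- function(sequence) {
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s)) stop("non-ACGT character in primer")
  if (nchar(s) < 15) stop("primer shorter than 15 nt")
  if (grepl("([ACGT])\\1{3}", s))
    return(list(pass = FALSE, reason = "homopolymer"))
  if (grepl("([ACGT]{2})\\1{3}", s))
    return(list(pass = FALSE, reason = "dinucleotide_repeat"))
  tail5 <- substr(s, nchar(s) - 4, nchar(s))
  if (lengths(regmatches(tail5, gregexpr("[GC]", tail5))) > 3)
    return(list(pass = FALSE, reason = "gc_3prime"))
  gc <- lengths(regmatches(s, gregexpr("[GC]", s))) / nchar(s)
  if (gc < 0.4 || gc > 0.6)
    return(list(pass = FALSE, reason = "gc_fraction"))
  list(pass = TRUE, reason = "")
}
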