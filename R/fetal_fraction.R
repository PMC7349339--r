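#' Panel coverage QC
#'
#' A sample's SNP amplicon data is usable only if the mean read depth
#' across panel SNPs reaches `min_mean_depth` (inclusive); samples below
#' 50x provide no reliable fetal-fraction assessment.
#'
#' @param counts data.frame with `ref_count` and `alt_count` (or `depth`).
#' @param min_mean_depth Minimum mean depth (default 50).
#' @return list with `mean_depth` and `pass`.
#' @export
coverage_qc <- function(counts, min_mean_depth = 50) {
  if (nrow(counts) == 0L) stop("empty SNP panel")
  depth <- if ("depth" %in% names(counts)) counts$depth
           else counts$ref_count + counts$alt_count
  m <- mean(depth)
  list(mean_depth = m, pass = m >= min_mean_depth)
}

#' Classify informative panel SNPs
#'
#' An informative site has a homozygous mother and a heterozygous fetus,
#' so the fetal paternal allele appears at read fraction ff/2. Without
#' parental genotypes the classification is made from the minor-allele
#' read fraction m: informative iff `floor <= m <= ceiling`; sites with
#' `m > ceiling` look maternal-heterozygous and are excluded, sites below
#' the floor show no paternal signal. When truth genotypes are present
#' (simulated data, columns `maternal_gt`/`fetal_gt`), the genotype rule
#' is applied directly.
#'
#' @param counts data.frame with `ref_count`, `alt_count` and optionally
#'   `maternal_gt`, `fetal_gt`.
#' @param minor_fraction_floor Lower read-fraction bound (default 0.005).
#' @param maternal_hom_ceiling Upper read-fraction bound (default 0.20).
#' @param use_truth Use truth genotypes when available (default TRUE).
#' @return The informative subset of `counts`, with a `minor_fraction`
#'   column added.
#' @export
classify_informative <- function(counts, minor_fraction_floor = 0.005,
                                 maternal_hom_ceiling = 0.20,
                                 use_truth = TRUE) {
  depth <- counts$ref_count + counts$alt_count
  keep_depth <- depth > 0
  m <- ifelse(keep_depth,
              pmin(counts$alt_count, counts$ref_count) / pmax(depth, 1), NA)
  counts$minor_fraction <- m
  if (use_truth && all(c("maternal_gt", "fetal_gt") %in% names(counts))) {
    inf <- counts$maternal_gt %in% c(0L, 2L) & counts$fetal_gt == 1L &
      keep_depth
  } else {
    inf <- keep_depth & m >= minor_fraction_floor & m <= maternal_hom_ceiling
  }
  counts[inf, , drop = FALSE]
}

#' Fetal fraction from informative SNP allele counts
#'
#' At an informative SNP the paternal allele is carried by half the fetal
#' genomes only, so its read fraction is ff/2; the per-SNP estimate is
#' twice the minor-allele fraction and the sample estimate is the median
#' over informative SNPs (robust to occasional misclassified sites).
#'
#' @param informative data.frame from [classify_informative()].
#' @param min_informative Minimum informative SNPs required (default 5).
#' @return list of class `nipt_ff`: `method = "amplifet"`, `ff`,
#'   `n_informative`, `qc_pass`, `note`.
#' @export
estimate_ff <- function(informative, min_informative = 5L) {
  n <- nrow(informative)
  if (n < min_informative) {
    return(structure(list(method = "amplifet", ff = NA_real_,
                          n_informative = n, qc_pass = FALSE,
                          note = sprintf("only %d informative SNPs (< %d)",
                                         n, min_informative)),
                     class = "nipt_ff"))
  }
  depth <- informative$ref_count + informative$alt_count
  ff_i <- 2 * pmin(informative$alt_count, informative$ref_count) / depth
  structure(list(method = "amplifet", ff = stats::median(ff_i),
                 n_informative = n, qc_pass = TRUE, note = ""),
            class = "nipt_ff")
}

#' @export
print.nipt_ff <- function(x, ...) {
  cat(sprintf("fetal fraction (%s): %s (n = %d, QC %s)%s\n", x$method,
              ifelse(is.na(x$ff), "NA", sprintf("%.4f", x$ff)),
              x$n_informative, ifelse(x$qc_pass, "pass", "FAIL"),
              ifelse(nzchar(x$note), paste0(" - ", x$note), "")))
  invisible(x)
}

#' Fraction of filtered fragments on chromosome Y
#'
#' @param fragments data.frame of kept fragments with a `chrom` column.
#' @param y_chrom Name of the Y chromosome (default `"chrY"`).
#' @return Fraction in [0,1].
#' @export
y_fraction <- function(fragments, y_chrom = "chrY") {
  if (nrow(fragments) == 0L) stop("no fragments")
  mean(fragments$chrom == y_chrom)
}

#' Fetal fraction from chromosome-Y coverage
#'
#' Anchored linear estimator for male fetuses: the observed Y-fragment
#' share is interpolated between the female background (mismapping floor)
#' and the share expected if all cfDNA were male, and clamped to [0,1].
#'
#' @param y_frac Observed chromosome-Y fragment fraction.
#' @param y_frac_female_bg Background Y fraction for a female fetus.
#' @param y_frac_full_male Y fraction of a fully male cfDNA pool.
#' @return list of class `nipt_ff` with `method = "chrY"`.
#' @export
ff_from_y <- function(y_frac, y_frac_female_bg, y_frac_full_male) {
  if (!is.finite(y_frac_female_bg) || !is.finite(y_frac_full_male) ||
      y_frac_full_male <= y_frac_female_bg)
    stop("invalid calibration: need y_frac_full_male > y_frac_female_bg")
  ff <- (y_frac - y_frac_female_bg) / (y_frac_full_male - y_frac_female_bg)
  structure(list(method = "chrY", ff = min(max(ff, 0), 1),
                 n_informative = NA_integer_, qc_pass = TRUE, note = ""),
            class = "nipt_ff")
}

#' Expected chromosome-Y fragment share of a fully male cfDNA pool
#'
#' Calibration anchor for [ff_from_y()]: with diploid autosomes and
#' hemizygous X and Y, the Y share of purely male cfDNA is
#' (L_Y/2) / (L_autosomes + L_X/2 + L_Y/2).
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Expected Y fragment fraction.
#' @export
y_anchor_male <- function(chrom_lengths) {
  w <- chrom_lengths
  sex <- intersect(c("chrX", "X", "chrY", "Y"), names(w))
  w[sex] <- w[sex] / 2
  yn <- intersect(c("chrY", "Y"), names(w))
  if (length(yn) == 0) stop("no Y chromosome in chrom_lengths")
  sum(w[yn]) / sum(w)
}

#' Call fetal sex from the two fetal-fraction estimates
#'
#' Female iff the SNP-based fetal fraction exceeds 4% (enough fetal signal
#' to trust the absence of Y) while the Y-derived estimate stays at or
#' below 1%; male iff the Y-derived estimate exceeds `male_floor`;
#' indeterminate otherwise (including any sample whose fetal fraction is
#' at or below 4%).
#'
#' @param ff_amplifet SNP-based fetal fraction.
#' @param ff_y Y-coverage-based fetal fraction.
#' @param female_ceiling Maximum Y-derived ff compatible with a female
#'   fetus (default 0.01).
#' @param male_floor Minimum Y-derived ff to call male (default 0.02).
#' @return `"female"`, `"male"` or `"indeterminate"`.
#' @export
call_sex <- function(ff_amplifet, ff_y, female_ceiling = 0.01,
                     male_floor = 0.02) {
  if (is.na(ff_amplifet) || ff_amplifet <= 0.04) return("indeterminate")
  if (ff_y <= female_ceiling) return("female")
  if (ff_y > male_floor) return("male")
  "indeterminate"
}
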