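#' GRCh38 chromosome lengths (bp)
#'
#' Internal table of human chromosome lengths used to shape the toy genome:
#' toy chromosomes keep the human length proportions, scaled down.
#' @noRd
.human_chrom_lengths <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415
)

#' Toy chromosome lengths proportional to the human genome
#'
#' @param scale Scaling factor applied to GRCh38 chromosome lengths
#'   (default 1/1000, giving a ~3.1 Mb genome).
#' @return Named integer vector of chromosome lengths in bp.
#' @export
toy_chrom_lengths <- function(scale = 1 / 1000) {
  stopifnot(is.numeric(scale), scale > 0)
  round(.human_chrom_lengths * scale)
}

#' Simulation configuration for chimeric cfDNA libraries
#'
#' Bundles every tunable of the in-silico library generator: the toy genome
#' shape, the maternal/fetal cfDNA fragment-length mixture (166 bp and 143 bp
#' modes), fragmentase and double-size-selection parameters (40-50 bp window),
#' self-ligation into >300 bp chimeras, PE250 sequencing, and the SNP amplicon
#' panel used for fetal-fraction estimation.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param chrom_lengths Named vector of chromosome lengths in bp; default a
#'   24-chromosome toy genome with human proportions at 1/1000 scale.
#' @param gc_baseline Per-genome baseline GC content in (0,1).
#' @param gc_amplitude Amplitude of the smooth spatial GC variation.
#' @param fetal_fraction Fetal proportion of cfDNA, in [0,1].
#' @param fetal_sex `"male"` or `"female"`; drives X/Y copy weighting of
#'   fetal fragments (maternal fragments never come from chrY).
#' @param trisomy_chrom Chromosome name carrying a fetal trisomy, or `NULL`.
#' @param n_cfdna_fragments Number of cfDNA molecules to draw.
#' @param maternal_len_mean,maternal_len_sd Maternal fragment length (bp).
#' @param fetal_len_mean,fetal_len_sd Fetal fragment length (bp).
#' @param fragmentase_target_mean Target mean piece length for the enzymatic
#'   fragmentation model (bp).
#' @param size_select_window Length-2 numeric, inclusive retention window (bp).
#' @param chimera_min_len Molecules are closed once they exceed this (bp).
#' @param read_len Sequencing read length (bp), PE.
#' @param seq_error_rate Per-base substitution error probability.
#' @param amplifet_coverage_mean Mean reads per panel SNP.
#' @param n_snps SNP panel size.
#' @param repeat_fraction Fraction of the genome covered by the simulated
#'   repeat track (default 0.5, roughly half the genome as for RepeatMasker).
#' @param snp_dropout Probability that a panel amplicon yields no reads.
#' @return An object of class `nipt_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = toy_chrom_lengths(),
                       gc_baseline = 0.41,
                       gc_amplitude = 0.08,
                       fetal_fraction = 0.10,
                       fetal_sex = c("male", "female"),
                       trisomy_chrom = NULL,
                       n_cfdna_fragments = 1e5,
                       maternal_len_mean = 166, maternal_len_sd = 10,
                       fetal_len_mean = 143, fetal_len_sd = 10,
                       fragmentase_target_mean = 43.8,
                       size_select_window = c(40, 50),
                       chimera_min_len = 300,
                       read_len = 250,
                       seq_error_rate = 0,
                       amplifet_coverage_mean = 5000,
                       n_snps = 102,
                       repeat_fraction = 0.5,
                       snp_dropout = 0) {
  if (length(chrom_lengths) == 0L)
    stop("chrom_lengths must be non-empty")
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be named by chromosome")
  if (any(chrom_lengths <= 0))
    stop("zero-length chromosome in chrom_lengths: ",
         paste(names(chrom_lengths)[chrom_lengths <= 0], collapse = ", "))
  if (fetal_fraction < 0 || fetal_fraction > 1)
    stop("fetal_fraction must be in [0,1]")
  if (!is.null(trisomy_chrom) && !trisomy_chrom %in% names(chrom_lengths))
    stop("trisomy_chrom '", trisomy_chrom, "' not in chrom_lengths")
  stopifnot(length(size_select_window) == 2,
            size_select_window[1] < size_select_window[2],
            read_len > 0, chimera_min_len > 0,
            maternal_len_mean > 0, fetal_len_mean > 0,
            fragmentase_target_mean > 0,
            seq_error_rate >= 0, seq_error_rate < 1,
            repeat_fraction >= 0, repeat_fraction <= 1,
            snp_dropout >= 0, snp_dropout < 1)
  fetal_sex <- match.arg(fetal_sex)
  structure(list(
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    gc_baseline = gc_baseline, gc_amplitude = gc_amplitude,
    fetal_fraction = fetal_fraction, fetal_sex = fetal_sex,
    trisomy_chrom = trisomy_chrom,
    n_cfdna_fragments = n_cfdna_fragments,
    maternal_len_mean = maternal_len_mean, maternal_len_sd = maternal_len_sd,
    fetal_len_mean = fetal_len_mean, fetal_len_sd = fetal_len_sd,
    fragmentase_target_mean = fragmentase_target_mean,
    size_select_window = size_select_window,
    chimera_min_len = chimera_min_len,
    read_len = read_len, seq_error_rate = seq_error_rate,
    amplifet_coverage_mean = amplifet_coverage_mean,
    n_snps = as.integer(n_snps),
    repeat_fraction = repeat_fraction,
    snp_dropout = snp_dropout
  ), class = "nipt_sim_config")
}

#' @export
print.nipt_sim_config <- function(x, ...) {
  cat("chimeraNIPT simulation config\n")
  cat(sprintf("  genome: %d chromosomes, %.2f Mb total\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6))
  cat(sprintf("  fetal fraction: %.3f; trisomy: %s\n", x$fetal_fraction,
              if (is.null(x$trisomy_chrom)) "none" else x$trisomy_chrom))
  cat(sprintf("  cfDNA: %g fragments (maternal %g+/-%g bp, fetal %g+/-%g bp)\n",
              x$n_cfdna_fragments, x$maternal_len_mean, x$maternal_len_sd,
              x$fetal_len_mean, x$fetal_len_sd))
  cat(sprintf("  size selection: [%g, %g] bp; chimera min %g bp; PE%g\n",
              x$size_select_window[1], x$size_select_window[2],
              x$chimera_min_len, x$read_len))
  invisible(x)
}
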