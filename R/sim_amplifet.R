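#' Simulate SNP amplicon allele counts ("amplifet" library)
#'
#' Draws, for each panel SNP, a maternal genotype from Hardy-Weinberg
#' proportions at the site's population allele frequency, a fetal genotype
#' as one maternal allele plus one paternal allele drawn from the population
#' frequency, a Poisson read depth, and a binomial alternate-allele read
#' count at the expected plasma allele fraction. At an informative site
#' (mother homozygous, fetus heterozygous) the fetal paternal allele is seen
#' at read fraction `fetal_fraction / 2`, which is what the downstream
#' doubled-allele estimator inverts.
#'
#' @param panel_sites data.frame of panel SNPs (`snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `af`), e.g. `reference$snps`.
#' @param config A [sim_config()]; uses `fetal_fraction`,
#'   `amplifet_coverage_mean`, `snp_dropout`.
#' @param seed Optional integer seed.
#' @return data.frame with one row per panel SNP: `snp_id`, `chrom`, `pos`,
#'   `maternal_gt`, `fetal_gt` (0/1/2 alt-allele dosage), `informative`
#'   (truth flag), `depth`, `ref_count`, `alt_count`.
#' @export
simulate_amplifet <- function(panel_sites, config, seed = NULL) {
  stopifnot(inherits(config, "nipt_sim_config"), nrow(panel_sites) > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel_sites)
  p <- panel_sites$af  # population alt-allele frequency
  ff <- config$fetal_fraction

  mat_a1 <- stats::rbinom(n, 1, p)
  mat_a2 <- stats::rbinom(n, 1, p)
  maternal_gt <- mat_a1 + mat_a2
  transmitted <- ifelse(stats::runif(n) < 0.5, mat_a1, mat_a2)
  paternal <- stats::rbinom(n, 1, p)
  fetal_gt <- transmitted + paternal
  informative <- (maternal_gt %in% c(0L, 2L)) & fetal_gt == 1L

  # plasma alt-allele fraction: maternal dosage/2 weighted (1-ff),
  # fetal dosage/2 weighted ff
  alt_frac <- (1 - ff) * maternal_gt / 2 + ff * fetal_gt / 2

  depth <- stats::rpois(n, config$amplifet_coverage_mean)
  if (config$snp_dropout > 0)
    depth[stats::runif(n) < config$snp_dropout] <- 0L
  alt_count <- stats::rbinom(n, depth, alt_frac)

  data.frame(snp_id = panel_sites$snp_id, chrom = panel_sites$chrom,
             pos = panel_sites$pos,
             maternal_gt = maternal_gt, fetal_gt = fetal_gt,
             informative = informative,
             depth = depth, ref_count = depth - alt_count,
             alt_count = alt_count)
}
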