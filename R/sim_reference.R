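#' Generate a toy reference bundle
#'
#' Builds a deterministic in-silico stand-in for the aligned-genome resources
#' the pipeline consumes: chromosome sequences with smooth spatial GC
#' variation, a repeat track covering a configurable fraction of the genome
#' (default one half, as for the human RepeatMasker track), amplicon intervals
#' for the SNP panel, and panel SNP sites with population allele frequencies.
#' SNP sites always fall outside repeat intervals.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `nipt_reference`: a list with elements
#'   `seqs` (\link[Biostrings]{DNAStringSet}), `chrom_lengths`,
#'   `repeats` and `amplicons` (\link[GenomicRanges]{GRanges}, 0-based
#'   half-open when exported to BED), and `snps` (data.frame with
#'   `snp_id, chrom, pos, ref, alt, af`; `pos` 1-based).
#' @examples
#' ref <- make_reference(sim_config(seed = 7, chrom_lengths = c(chrA = 5e4)))
#' width(ref$seqs)
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "nipt_sim_config"))
  if (any(config$chrom_lengths <= 0)) stop("zero-length chromosome")
  set.seed(config$seed)
  lens <- config$chrom_lengths
  chroms <- names(lens)

  seqs <- Biostrings::DNAStringSet(vapply(seq_along(lens), function(i) {
    .simulate_chrom_seq(lens[[i]], config$gc_baseline, config$gc_amplitude)
  }, character(1)))
  names(seqs) <- chroms

  repeats <- .simulate_repeat_track(lens, config$repeat_fraction)

  snps <- .simulate_panel_snps(lens, repeats, config$n_snps)
  if (nrow(snps) > 0) {
    ref_base <- as.character(Biostrings::subseq(
      seqs[snps$chrom], start = snps$pos, width = 1))
    alts <- c(A = "G", C = "T", G = "A", T = "C")  # transitions
    snps$ref <- unname(ref_base)
    snps$alt <- unname(alts[ref_base])
  }

  amplicons <- .amplicons_around(snps, lens, amplicon_len = 120L)

  structure(list(seqs = seqs, chrom_lengths = lens,
                 repeats = repeats, amplicons = amplicons, snps = snps),
            class = "nipt_reference")
}

# Base composition with sinusoidal GC variation along the chromosome.
.simulate_chrom_seq <- function(len, gc_baseline, gc_amplitude) {
  pos <- seq_len(len)
  period <- max(10000, round(len / 10))
  phase <- stats::runif(1, 0, 2 * pi)
  gc <- gc_baseline + gc_amplitude * sin(2 * pi * pos / period + phase)
  gc <- pmin(pmax(gc, 0.05), 0.95)
  is_gc <- stats::runif(len) < gc
  pick <- stats::runif(len) < 0.5
  base <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
  paste(base, collapse = "")
}

# Alternating segments marked repeat with probability = target fraction.
.simulate_repeat_track <- function(lens, repeat_fraction) {
  if (repeat_fraction <= 0) {
    return(GenomicRanges::GRanges(seqlengths = lens))
  }
  grl <- lapply(names(lens), function(chrom) {
    L <- lens[[chrom]]
    # segment mean 800 bp keeps the realised coverage within ~1% of target
    n_seg <- max(2L, ceiling(L / 800 * 1.5))
    seg <- ceiling(stats::rexp(n_seg, 1 / 800))
    ends <- cumsum(seg)
    seg <- seg[ends - seg < L]
    ends <- pmin(cumsum(seg), L)
    starts <- c(1, utils::head(ends, -1) + 1)
    is_rep <- stats::runif(length(seg)) < repeat_fraction
    if (!any(is_rep)) return(NULL)
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(starts[is_rep], ends[is_rep]))
  })
  gr <- suppressWarnings(do.call(c, c(grl[!vapply(grl, is.null, logical(1))],
                                      list(GenomicRanges::GRanges()))))
  gr <- GenomicRanges::reduce(gr)
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- unname(lens)
  gr
}

# Panel SNP sites: uniform over non-repeat space, spaced apart (500 bp, or
# less on tiny genomes), alt-allele frequencies uniform on [0.4, 0.5]
# (high-MAF panel).
.simulate_panel_snps <- function(lens, repeats, n_snps) {
  if (n_snps == 0L) {
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      af = numeric()))
  }
  autos <- names(lens)[!names(lens) %in% c("chrX", "chrY", "X", "Y", "MT", "chrM")]
  if (length(autos) == 0) autos <- names(lens)
  gap <- min(500L, max(50L, floor(sum(lens[autos]) / (4L * n_snps))))
  got <- 0L; tries <- 0L
  chrom <- character(n_snps); pos <- integer(n_snps)
  while (got < n_snps && tries < 200L) {
    tries <- tries + 1L
    need <- n_snps - got
    c_i <- sample(autos, need * 4L, replace = TRUE,
                  prob = lens[autos] / sum(lens[autos]))
    p_i <- floor(stats::runif(length(c_i)) * (lens[c_i] - 60)) + 31L
    cand <- GenomicRanges::GRanges(c_i, IRanges::IRanges(p_i, width = 1))
    in_rep <- IRanges::overlapsAny(cand, repeats)
    c_i <- c_i[!in_rep]; p_i <- p_i[!in_rep]
    for (j in seq_along(c_i)) {
      if (got >= n_snps) break
      same <- chrom[seq_len(got)] == c_i[j]
      if (!any(same) || all(abs(pos[seq_len(got)][same] - p_i[j]) >= gap)) {
        got <- got + 1L
        chrom[got] <- c_i[j]; pos[got] <- p_i[j]
      }
    }
  }
  if (got < n_snps)
    stop("could not place ", n_snps, " panel SNPs outside repeats; ",
         "reduce n_snps or repeat_fraction")
  o <- order(match(chrom, names(lens)), pos)
  data.frame(snp_id = sprintf("rs_sim%04d", seq_len(n_snps)),
             chrom = chrom[o], pos = as.integer(pos[o]),
             ref = NA_character_, alt = NA_character_,
             af = stats::runif(n_snps, 0.4, 0.5))
}

.amplicons_around <- function(snps, lens, amplicon_len = 120L) {
  if (nrow(snps) == 0) return(GenomicRanges::GRanges(seqlengths = lens))
  half <- amplicon_len %/% 2L
  st <- pmax(1L, snps$pos - half)
  en <- pmin(unname(lens[snps$chrom]), snps$pos + half - 1L)
  gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(st, en),
                               snp_id = snps$snp_id)
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- unname(lens)
  gr
}

#' Per-bin GC content of a reference
#'
#' @param reference A `nipt_reference`.
#' @param bins Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return Numeric vector of GC fractions in [0,1], one per bin.
#' @export
gc_of_bins <- function(reference, bins) {
  stopifnot(inherits(reference, "nipt_reference"))
  out <- numeric(nrow(bins))
  for (chrom in unique(bins$chrom)) {
    i <- which(bins$chrom == chrom)
    vs <- Biostrings::Views(reference$seqs[[chrom]],
                            start = bins$start[i] + 1L, end = bins$end[i])
    freq <- Biostrings::letterFrequency(vs, letters = c("GC"))
    out[i] <- freq[, 1] / (bins$end[i] - bins$start[i])
  }
  out
}

#' Write a reference bundle to disk in standard formats
#'
#' Writes FASTA (sequences), BED (repeat and amplicon tracks, 0-based
#' half-open) and a minimal VCFv4.2 of the panel sites with `AF` INFO tags.
#'
#' @param reference A `nipt_reference`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "nipt_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                repeats = file.path(dir, "repeats.bed"),
                amplicons = file.path(dir, "amplicons.bed"),
                panel = file.path(dir, "panel.vcf"))
  Biostrings::writeXStringSet(reference$seqs, paths$fasta)
  rtracklayer::export(reference$repeats, paths$repeats, format = "BED")
  rtracklayer::export(reference$amplicons, paths$amplicons, format = "BED")
  write_panel_vcf(reference$snps, paths$panel)
  invisible(paths)
}

#' Write panel SNP sites as a minimal VCFv4.2 file
#'
#' @param snps Data frame with `snp_id, chrom, pos, ref, alt, af`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO"), collapse = "\t")))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%.4f",
                  snps$chrom, snps$pos, snps$snp_id, snps$ref, snps$alt,
                  snps$af)
  writeLines(c(hdr, body), path)
  invisible(path)
}
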