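#' Read a BED track into a merged interval index
#'
#' Loads a BED (3+ columns, 0-based half-open) file, sorts and merges
#' overlapping intervals per chromosome. Overlap queries run in logarithmic
#' time through the interval-tree machinery of \pkg{IRanges}.
#'
#' @param bed_path Path to a BED file.
#' @return A \link[GenomicRanges]{GRanges} of disjoint, sorted intervals.
#' @export
read_intervals <- function(bed_path) {
  gr <- tryCatch(rtracklayer::import(bed_path, format = "BED"),
                 error = function(e)
                   stop("malformed BED '", bed_path, "': ",
                        conditionMessage(e)))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Total bases covered by an interval set
#' @param gr A GRanges.
#' @return Total covered bp after merging overlaps.
#' @export
interval_bp <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr))))
}

# fragments data.frame (chrom,start,end 0-based half-open) -> GRanges
.fragments_granges <- function(fragments) {
  GenomicRanges::GRanges(fragments$chrom,
                         IRanges::IRanges(fragments$start + 1L,
                                          fragments$end))
}

#' Stream grouped alignment records from a SAM or BAM file
#'
#' Reads all mapped records (primary and supplementary; secondary
#' alignments are dropped) and returns them grouped by query name, the unit
#' that [extract_subreads()] consumes. SAM input is converted through
#' samtools-compatible machinery (\pkg{Rsamtools}).
#'
#' @param path Path to a SAM or BAM file.
#' @return data.frame with columns `qname`, `flag`, `chrom`, `pos` (1-based
#'   leftmost), `mapq`, `cigar`, `strand`, `secondary`, `supplementary`,
#'   `unmapped`, ordered by `qname`.
#' @export
stream_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("cannot parse SAM/BAM '", path, "': ",
                               conditionMessage(e)))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  df <- data.frame(qname = res$qname, flag = flag,
                   chrom = as.character(res$rname), pos = res$pos,
                   mapq = res$mapq, cigar = res$cigar,
                   strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                   secondary = bitwAnd(flag, 256L) > 0L,
                   supplementary = bitwAnd(flag, 2048L) > 0L,
                   unmapped = bitwAnd(flag, 4L) > 0L)
  df <- df[!df$secondary, , drop = FALSE]
  df[order(df$qname), , drop = FALSE]
}
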