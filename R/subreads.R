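#' Deconstruct chimeric-read alignments into genomic fragment tags
#'
#' Every mapped record of a read group (the primary alignment plus each
#' supplementary alignment) contributes one sub-read fragment spanning the
#' record's reference footprint, taken from its CIGAR. Secondary alignments
#' and unmapped records yield nothing. Fragments are reported on the
#' reference plus strand (`start < end` always) with the record strand and
#' MAPQ retained. Records with malformed CIGARs are skipped with a warning.
#'
#' @param records data.frame from [stream_alignments()].
#' @param pass Mapping pass the records come from (1 or 2). Pass-2 records
#'   that are supplementary or on the minus strand are expected to be
#'   removed downstream (the first pass already orients sub-reads to the
#'   plus strand), and [filter_fragments()] flags them when `pass2 = TRUE`.
#' @return data.frame of fragments: `read_id`, `mate`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `mapq`, `supplementary`.
#' @export
extract_subreads <- function(records, pass = 1L) {
  rec <- records[!records$unmapped & !records$secondary, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(read_id = character(), mate = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mapq = integer(), supplementary = logical()))
  }
  ok <- grepl("^([0-9]+[MIDNSHP=X])+$", rec$cigar)
  if (!all(ok)) {
    warning(sum(!ok), " record(s) with malformed CIGAR skipped")
    rec <- rec[ok, , drop = FALSE]
  }
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  mate <- ifelse(bitwAnd(rec$flag, 128L) > 0L, 2L, 1L)
  data.frame(read_id = rec$qname, mate = mate, chrom = rec$chrom,
             start = rec$pos - 1L, end = rec$pos - 1L + rw,
             strand = rec$strand, mapq = rec$mapq,
             supplementary = rec$supplementary)
}

#' Filter sub-read fragments by mapping quality and interval tracks
#'
#' Removes fragments that are imperfectly mapped (MAPQ below `min_mapq`),
#' overlap a repeat interval by at least 1 bp, overlap an amplicon interval
#' by at least 1 bp, or - for second-mapping-pass records - are
#' supplementary or minus-strand. Reasons are not mutually exclusive; the
#' per-reason statistics report the first failing rule in the fixed order
#' low_mapq, repeat, amplicon, pass-2 flags.
#'
#' @param fragments data.frame from [extract_subreads()].
#' @param repeats,amplicons \link[GenomicRanges]{GRanges} interval tracks
#'   (may be empty).
#' @param min_mapq Minimum MAPQ kept (inclusive; default 60).
#' @param pass2 If `TRUE`, apply the second-pass supplementary/minus-strand
#'   removal rules.
#' @return list with `kept` (fragments passing every rule), `flagged` (all
#'   fragments with a `filter_reason` column, `"pass"` for kept ones) and
#'   `stats` (data.frame of first-failing reason counts).
#' @export
filter_fragments <- function(fragments, repeats, amplicons,
                             min_mapq = 60L, pass2 = FALSE) {
  stopifnot(min_mapq >= 0, min_mapq <= 60)
  n <- nrow(fragments)
  if (n == 0L) {
    stats <- data.frame(reason = c("low_mapq", "repeat", "amplicon",
                                   "pass2", "pass"), count = 0L)
    return(list(kept = fragments,
                flagged = cbind(fragments, filter_reason = character()),
                stats = stats))
  }
  .check_chroms(fragments, repeats, "repeat")
  .check_chroms(fragments, amplicons, "amplicon")
  gr <- .fragments_granges(fragments)
  in_repeat <- if (length(repeats)) IRanges::overlapsAny(gr, repeats)
               else rep(FALSE, n)
  in_amplicon <- if (length(amplicons)) IRanges::overlapsAny(gr, amplicons)
                 else rep(FALSE, n)
  low_mapq <- fragments$mapq < min_mapq
  p2 <- if (pass2) fragments$supplementary | fragments$strand == "-"
        else rep(FALSE, n)

  reason <- rep("pass", n)
  reason[p2] <- "pass2"
  reason[in_amplicon] <- "amplicon"
  reason[in_repeat] <- "repeat"
  reason[low_mapq] <- "low_mapq"

  lev <- c("low_mapq", "repeat", "amplicon", "pass2", "pass")
  stats <- data.frame(reason = lev,
                      count = as.integer(table(factor(reason, levels = lev))))
  flagged <- cbind(fragments, filter_reason = reason)
  list(kept = fragments[reason == "pass", , drop = FALSE],
       flagged = flagged, stats = stats)
}

.check_chroms <- function(fragments, track, what) {
  if (length(track) == 0L) return(invisible())
  known <- GenomeInfoDb::seqlevels(track)
  bad <- setdiff(unique(fragments$chrom), known)
  if (length(bad))
    stop("fragment chromosome(s) absent from ", what, " track: ",
         paste(bad, collapse = ", "))
  invisible()
}

#' Merge a read pair by overlap (FLASH-style)
#'
#' Scans candidate overlaps from `max_overlap` down to `min_overlap`, in the
#' standard innie geometry (3' end of R1 over the reverse-complemented R2)
#' and, when `allow_outies`, in the outie (dovetail) geometry where the
#' reads read through each other. The overlap with the lowest mismatch
#' density wins, ties going to the larger overlap; the merge is accepted if
#' that density does not exceed `max_mismatch_density`. Ambiguous bases (N)
#' count as mismatches. The merged length (insert size) is
#' `len(r1) + len(r2) - overlap` for innies and `overlap` for outies.
#'
#' @param r1,r2 Read sequences as character strings (R2 as sequenced, i.e.
#'   reverse-complement orientation).
#' @param min_overlap,max_overlap Overlap scan range (defaults 20/250).
#' @param allow_outies Also consider the dovetail geometry (default TRUE).
#' @param max_mismatch_density Maximum mismatches per overlap base
#'   (default 0.20).
#' @return list with `merged` (logical) and, when merged, `length`,
#'   `overlap`, `density`, `geometry` (`"innie"`/`"outie"`).
#' @export
merge_read_pair <- function(r1, r2, min_overlap = 20L, max_overlap = 250L,
                            allow_outies = TRUE,
                            max_mismatch_density = 0.20) {
  stopifnot(nchar(r1) > 0, nchar(r2) > 0,
            min_overlap > 0, min_overlap <= max_overlap,
            max_mismatch_density >= 0, max_mismatch_density <= 1)
  s1 <- strsplit(toupper(r1), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(r2)))), "")[[1]]
  n1 <- length(s1); n2 <- length(s2)
  hi <- min(max_overlap, n1, n2)
  if (hi < min_overlap) return(list(merged = FALSE))

  mism <- function(a, b) sum(a != b | a == "N" | b == "N")
  best <- list(density = Inf, overlap = 0L, geometry = "")
  for (o in seq(hi, min_overlap)) {
    d <- mism(s1[(n1 - o + 1):n1], s2[1:o]) / o
    if (d < best$density) best <- list(density = d, overlap = o,
                                       geometry = "innie")
    if (allow_outies) {
      d2 <- mism(s1[1:o], s2[(n2 - o + 1):n2]) / o
      if (d2 < best$density) best <- list(density = d2, overlap = o,
                                          geometry = "outie")
    }
  }
  if (best$density > max_mismatch_density) return(list(merged = FALSE))
  len <- if (best$geometry == "innie") n1 + n2 - best$overlap else
    best$overlap
  list(merged = TRUE, length = len, overlap = best$overlap,
       density = best$density, geometry = best$geometry)
}

#' Fragment and information-content statistics
#'
#' Summarises filtered sub-read fragments: mean fragment length, the number
#' of filtered fragments recovered per read pair, and the information
#' content of a single read relative to a classic single-tag read - a
#' 250 bp read over ~44 bp tags carries several genomic tags instead of
#' one, the ratio being `read_len / mean_fragment_len`.
#'
#' @param fragments data.frame of (filtered) fragments.
#' @param read_len Read length in bp.
#' @param n_pairs Number of read pairs the fragments came from (optional).
#' @return list with `mean_fragment_len`, `info_content_ratio` (reported to
#'   one decimal) and `fragments_per_pair` (`NA` if `n_pairs` missing).
#' @export
fragment_stats <- function(fragments, read_len, n_pairs = NULL) {
  if (nrow(fragments) == 0L) stop("no fragments")
  m <- mean(fragments$end - fragments$start)
  list(mean_fragment_len = m,
       info_content_ratio = round(read_len / m, 1),
       fragments_per_pair = if (is.null(n_pairs)) NA_real_
                            else nrow(fragments) / n_pairs)
}

#' Per-sample quality control
#'
#' A sample is analysable only if it carries at least `min_fragments`
#' filtered fragments and its estimated fetal fraction is at least
#' `min_ff`. Both thresholds are inclusive: the exclusion rules are strict
#' "less than" conditions.
#'
#' @param n_filtered Number of filtered fragments.
#' @param fetal_fraction Estimated fetal fraction (`NA` allowed).
#' @param min_fragments Fragment floor (default 2,500,000).
#' @param min_ff Fetal-fraction floor (default 0.04).
#' @return list with `n_filtered`, `fetal_fraction`, `pass`, `reasons`.
#' @export
sample_qc <- function(n_filtered, fetal_fraction,
                      min_fragments = 2.5e6, min_ff = 0.04) {
  stopifnot(n_filtered >= 0)
  reasons <- character()
  if (n_filtered < min_fragments)
    reasons <- c(reasons, sprintf("fragments: %d < %d", as.integer(n_filtered),
                                  as.integer(min_fragments)))
  if (is.na(fetal_fraction) || fetal_fraction < min_ff)
    reasons <- c(reasons, sprintf("fetal fraction: %s < %g",
                                  format(fetal_fraction), min_ff))
  list(n_filtered = n_filtered, fetal_fraction = fetal_fraction,
       pass = length(reasons) == 0L, reasons = reasons)
}
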