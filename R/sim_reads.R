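# Read geometry -----------------------------------------------------------
#
# A chimeric molecule is the ordered concatenation of its parts; a part with
# orientation "-" contributes the reverse complement of its genomic
# sequence. R1 is the first read_len bases of the molecule top strand, R2 the
# reverse complement of the last read_len bases. All internal coordinates are
# 0-based half-open; the SAM writer converts to 1-based.

#' Per-read ground truth of a chimeric library
#'
#' Computes, for every read of every molecule, the molecule parts the read
#' covers, with the genomic interval clipped to the read extent, the
#' within-read offsets of the aligned block, and the strand the aligned
#' record carries (the part orientation, flipped for mate 2). This is the
#' oracle against which alignment deconstruction is checked: a 250 bp read
#' typically covers ~6 parts of ~44 bp, the last one partially.
#'
#' @param chimeras A `nipt_chimeras` from [ligate_chimeras()].
#' @param config A [sim_config()]; uses `read_len`.
#' @return data.frame with columns `molecule_id`, `mate` (1/2),
#'   `part_index`, `chrom`, `start`, `end` (clipped genomic, 0-based
#'   half-open), `strand` (record strand), `read_start`, `read_end`
#'   (0-based offsets of the aligned block within the sequenced read),
#'   `read_len` (length of that read).
#' @export
read_truth <- function(chimeras, config) {
  stopifnot(inherits(chimeras, "nipt_chimeras"))
  rlen <- config$read_len
  parts <- chimeras$parts
  L <- chimeras$molecules$total_len[match(parts$molecule_id,
                                          chimeras$molecules$molecule_id)]
  q <- parts$mol_offset
  l <- parts$end - parts$start

  one_mate <- function(mate) {
    this_rlen <- pmin(L, rlen)
    if (mate == 1L) {
      a <- q; b <- pmin(q + l, this_rlen)
    } else {
      w0 <- L - this_rlen
      a <- pmax(q, w0); b <- q + l
    }
    keep <- b > a
    ra <- if (mate == 1L) a else L - b
    rb <- if (mate == 1L) b else L - a
    plus <- parts$orientation == "+"
    gs <- ifelse(plus, parts$start + (a - q), parts$start + (q + l - b))
    ge <- ifelse(plus, parts$start + (b - q), parts$start + (q + l - a))
    strand <- if (mate == 1L) parts$orientation else
      ifelse(plus, "-", "+")
    data.frame(molecule_id = parts$molecule_id, mate = mate,
               part_index = parts$part_index, chrom = parts$chrom,
               start = as.integer(gs), end = as.integer(ge),
               strand = strand,
               read_start = as.integer(ra), read_end = as.integer(rb),
               read_len = as.integer(this_rlen))[keep, , drop = FALSE]
  }
  out <- rbind(one_mate(1L), one_mate(2L))
  out <- out[order(out$molecule_id, out$mate, out$read_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# molecule_id -> full molecule sequence (character vector)
.molecule_seqs <- function(chimeras, reference) {
  parts <- chimeras$parts
  seqs <- character(nrow(parts))
  for (chrom in unique(parts$chrom)) {
    i <- which(parts$chrom == chrom)
    v <- Biostrings::Views(reference$seqs[[chrom]],
                           start = parts$start[i] + 1L, end = parts$end[i])
    s <- Biostrings::DNAStringSet(v)
    rev <- parts$orientation[i] == "-"
    if (any(rev)) s[rev] <- Biostrings::reverseComplement(s[rev])
    seqs[i] <- as.character(s)
  }
  # parts arrive ordered by molecule and part_index
  o <- order(parts$molecule_id, parts$part_index)
  vapply(split(seqs[o], parts$molecule_id[o]), paste, character(1),
         collapse = "")
}

.inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(stats::runif(total) < rate)
  if (length(hit) == 0) return(seqs)
  ends <- cumsum(lens)
  ri <- findInterval(hit - 1L, ends) + 1L
  pos <- hit - c(0, ends)[ri]
  for (k in seq_along(hit)) {
    old <- substr(seqs[ri[k]], pos[k], pos[k])
    new <- sample(setdiff(bases, old), 1)
    substr(seqs[ri[k]], pos[k], pos[k]) <- new
  }
  seqs
}

#' Generate paired-end reads from chimeric molecules
#'
#' R1 is the first `read_len` bases of each molecule, R2 the reverse
#' complement of the last `read_len` bases; molecules shorter than the read
#' length yield full-length reads of the whole molecule. Substitution errors
#' are injected at `seq_error_rate`; read names carry the molecule id.
#'
#' @param chimeras A `nipt_chimeras`.
#' @param reference A `nipt_reference`.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (affects only error injection).
#' @return list with `r1` and `r2` (\link[Biostrings]{DNAStringSet}, named
#'   by molecule id).
#' @export
generate_reads <- function(chimeras, reference, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mseq <- .molecule_seqs(chimeras, reference)
  L <- nchar(mseq)
  rlen <- pmin(L, config$read_len)
  r1 <- substr(mseq, 1, rlen)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(mseq, L - rlen + 1, L))))
  r1 <- .inject_errors(r1, config$seq_error_rate)
  r2 <- .inject_errors(r2, config$seq_error_rate)
  r1 <- Biostrings::DNAStringSet(r1); names(r1) <- names(mseq)
  r2 <- Biostrings::DNAStringSet(r2); names(r2) <- names(mseq)
  list(r1 = r1, r2 = r2)
}

#' Write paired FASTQ files
#'
#' @param reads list with `r1`, `r2` as returned by [generate_reads()].
#' @param r1_path,r2_path Output paths (plain or `.gz`).
#' @return Invisibly, c(r1_path, r2_path).
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  for (p in list(list(reads$r1, r1_path), list(reads$r2, r2_path))) {
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(p[[1]])))
    Biostrings::writeXStringSet(p[[1]], p[[2]], format = "fastq",
                                qualities = q)
  }
  invisible(c(r1_path, r2_path))
}

#' Write truth split alignments as SAM
#'
#' Stands in for the first mapping pass of an aligner: each read gets one
#' primary record plus one supplementary record per additional covered part.
#' Soft-clip CIGARs delimit each part within the read; records whose part
#' lies on the reference minus strand carry the reverse flag and store the
#' reverse-complemented read sequence, per the SAM specification. SA tags
#' link the records of a read. MAPQ is 60 for uniquely placed parts; a
#' fraction of records can be planted with a low MAPQ to exercise the
#' downstream mapping-quality filter.
#'
#' @param chimeras A `nipt_chimeras`.
#' @param reference A `nipt_reference`.
#' @param config A [sim_config()].
#' @param path Output SAM path.
#' @param low_mapq_prob Probability that a record is planted with
#'   `low_mapq_value` instead of 60.
#' @param low_mapq_value MAPQ given to planted ambiguous records.
#' @param seed Optional integer seed (MAPQ planting).
#' @return Invisibly, the [read_truth()] table with an added `mapq` column
#'   reflecting planted values.
#' @export
emit_truth_sam <- function(chimeras, reference, config, path,
                           low_mapq_prob = 0, low_mapq_value = 30L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- read_truth(chimeras, config)
  lens <- reference$chrom_lengths
  if (any(truth$end > lens[truth$chrom]))
    stop("internal consistency error: part mapped outside reference")

  truth$mapq <- ifelse(stats::runif(nrow(truth)) < low_mapq_prob,
                       as.integer(low_mapq_value), 60L)

  mseq <- .molecule_seqs(chimeras, reference)
  L <- nchar(mseq)
  rlen <- pmin(L, config$read_len)
  r1 <- substr(mseq, 1, rlen)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(mseq, L - rlen + 1, L))))
  names(r1) <- names(r2) <- names(mseq)

  # stored (record-orientation) offsets and CIGAR
  minus <- truth$strand == "-"
  sa <- ifelse(minus, truth$read_len - truth$read_end, truth$read_start)
  sb <- ifelse(minus, truth$read_len - truth$read_start, truth$read_end)
  cig <- paste0(ifelse(sa > 0, paste0(sa, "S"), ""),
                sb - sa, "M",
                ifelse(truth$read_len - sb > 0,
                       paste0(truth$read_len - sb, "S"), ""))

  # primary record per (molecule, mate): the block starting the read
  grp <- paste(truth$molecule_id, truth$mate)
  is_primary <- !duplicated(grp)  # truth is sorted by read_start within read

  flag <- 1L +
    ifelse(truth$mate == 1L, 64L, 128L) +
    ifelse(minus, 16L, 0L) +
    ifelse(is_primary, 0L, 2048L)

  read_seq <- ifelse(truth$mate == 1L, r1[truth$molecule_id],
                     r2[truth$molecule_id])
  stored_seq <- read_seq
  if (any(minus))
    stored_seq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(read_seq[minus])))

  # SA tag: the other records of the same read, in read order
  sa_entry <- sprintf("%s,%d,%s,%s,%d,0;", truth$chrom, truth$start + 1L,
                      truth$strand, cig, truth$mapq)
  sa_tag <- character(nrow(truth))
  for (i in split(seq_len(nrow(truth)), grp)) {
    if (length(i) == 1L) next
    ent <- sa_entry[i]
    for (j in seq_along(i)) sa_tag[i[j]] <- paste(ent[-j], collapse = "")
  }

  qual <- strrep("I", nchar(stored_seq))
  rec <- paste(truth$molecule_id, flag, truth$chrom, truth$start + 1L,
               truth$mapq, cig, "*", 0L, 0L, stored_seq, qual,
               ifelse(sa_tag == "", "", paste0("SA:Z:", sa_tag)),
               sep = "\t")
  rec <- sub("\t$", "", rec)

  hdr <- c("@HD\tVN:1.6\tSO:queryname",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), unname(lens)))
  writeLines(c(hdr, rec), path)
  invisible(truth)
}
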