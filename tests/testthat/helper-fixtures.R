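# Shared small fixtures, built once per test run.

# two-chromosome 100 kb genome: fast unit-test scale
tiny_cfg <- sim_config(seed = 101,
                       chrom_lengths = c(chrA = 60000, chrB = 40000),
                       n_cfdna_fragments = 3000, n_snps = 40)
tiny_ref <- make_reference(tiny_cfg)

# human-proportioned toy genome at 1/5000 scale (~620 kb)
toy_cfg <- sim_config(seed = 202, chrom_lengths = toy_chrom_lengths(1 / 5000),
                      n_cfdna_fragments = 20000, n_snps = 60)
toy_ref <- make_reference(toy_cfg)

# fragments data.frame constructor for hand-built cases
make_frags <- function(chrom, start, end, mapq = 60L, strand = "+",
                       read_id = NULL, mate = 1L, supplementary = FALSE) {
  n <- length(start)
  data.frame(read_id = if (is.null(read_id)) sprintf("r%03d", seq_len(n))
                       else read_id,
             mate = rep_len(mate, n), chrom = rep_len(chrom, n),
             start = start, end = end, strand = rep_len(strand, n),
             mapq = rep_len(mapq, n),
             supplementary = rep_len(supplementary, n))
}

granges_track <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

# brute-force all-offsets read-pair merge scorer (oracle for merge_read_pair)
merge_oracle <- function(r1, r2, min_overlap = 20L, max_overlap = 250L,
                         allow_outies = TRUE, max_density = 0.20) {
  s1 <- strsplit(r1, "")[[1]]
  s2 <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r2))), "")[[1]]
  n1 <- length(s1); n2 <- length(s2)
  mism <- function(a, b) sum(a != b | a == "N" | b == "N")
  best <- NULL
  for (o in min_overlap:min(max_overlap, n1, n2)) {
    cands <- list(list(d = mism(s1[(n1 - o + 1):n1], s2[1:o]) / o,
                       o = o, geom = "innie"))
    if (allow_outies)
      cands <- c(cands, list(list(d = mism(s1[1:o], s2[(n2 - o + 1):n2]) / o,
                                  o = o, geom = "outie")))
    for (cand in cands) {
      if (is.null(best) || cand$d < best$d ||
          (cand$d == best$d && cand$o > best$o)) best <- cand
    }
  }
  if (is.null(best) || best$d > max_density) return(list(merged = FALSE))
  list(merged = TRUE,
       length = if (best$geom == "innie") n1 + n2 - best$o else best$o,
       overlap = best$o, density = best$d, geometry = best$geom)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
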