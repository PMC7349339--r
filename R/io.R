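#' Write and read the fragment interchange TSV
#'
#' Tab-delimited with a header row; coordinates stay 0-based half-open.
#' `write_fragments_tsv()` and `read_fragments_tsv()` round-trip the
#' fragment tables produced by [extract_subreads()] / [filter_fragments()].
#'
#' @param fragments data.frame of fragments.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Write allele-count table
#' @param counts data.frame from [simulate_amplifet()] or external source.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
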