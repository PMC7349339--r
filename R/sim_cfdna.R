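#' Simulate a maternal/fetal cfDNA fragment mixture
#'
#' Draws cfDNA molecules from the toy genome. Each fragment is fetal with
#' probability `fetal_fraction` and its length comes from the origin-specific
#' normal mixture (maternal mode 166 bp, fetal mode 143 bp), truncated at
#' 20 bp. Fragment placement is uniform within a chromosome; chromosomes are
#' chosen proportionally to length times copy number (the mother is XX, a
#' male fetus hemizygous X/Y), and a fetal trisomy multiplies the fetal
#' sampling rate on the affected chromosome by 1.5 (three copies instead of
#' two), so the expected overall share of that chromosome is inflated by
#' the dosage factor (1 - ff) + 1.5 ff = 1 + ff/2.
#'
#' @param reference A `nipt_reference` from [make_reference()].
#' @param config A [sim_config()]; uses `fetal_fraction`, `trisomy_chrom`,
#'   `n_cfdna_fragments` and the length-mixture parameters.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `origin` (`"maternal"`/`"fetal"`).
#' @export
simulate_cfdna <- function(reference, config, seed = NULL) {
  stopifnot(inherits(reference, "nipt_reference"),
            inherits(config, "nipt_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_cfdna_fragments
  stopifnot(n >= 1)
  lens <- reference$chrom_lengths
  if (!is.null(config$trisomy_chrom) &&
      !config$trisomy_chrom %in% names(lens))
    stop("trisomy_chrom '", config$trisomy_chrom, "' not in reference")

  fetal <- stats::runif(n) < config$fetal_fraction

  # copy-number weights: diploid autosomes; the mother is XX (no Y);
  # a male fetus is hemizygous for both sex chromosomes; a fetal trisomy
  # carries 3 copies instead of 2 (factor 1.5)
  y_names <- intersect(c("chrY", "Y"), names(lens))
  x_names <- intersect(c("chrX", "X"), names(lens))
  p_mat <- lens
  p_mat[y_names] <- 0
  p_mat <- p_mat / sum(p_mat)
  p_fet <- lens
  if (identical(config$fetal_sex, "male")) {
    p_fet[c(x_names, y_names)] <- p_fet[c(x_names, y_names)] / 2
  } else {
    p_fet[y_names] <- 0
  }
  if (!is.null(config$trisomy_chrom))
    p_fet[config$trisomy_chrom] <- 1.5 * p_fet[config$trisomy_chrom]
  p_fet <- p_fet / sum(p_fet)

  ci <- integer(n)
  n_fet <- sum(fetal)
  if (n_fet > 0)
    ci[fetal] <- sample.int(length(lens), n_fet, replace = TRUE, prob = p_fet)
  if (n_fet < n)
    ci[!fetal] <- sample.int(length(lens), n - n_fet, replace = TRUE,
                             prob = p_mat)
  chrom <- names(lens)[ci]

  len <- ifelse(fetal,
                stats::rnorm(n, config$fetal_len_mean, config$fetal_len_sd),
                stats::rnorm(n, config$maternal_len_mean,
                             config$maternal_len_sd))
  len <- pmax(20, round(len))
  clen <- unname(lens[ci])
  len <- pmin(len, clen)
  start <- floor(stats::runif(n) * (clen - len + 1))

  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len),
             origin = ifelse(fetal, "fetal", "maternal"))
}

#' Enzymatic fragmentation and double size selection
#'
#' Emulates fragmentase digestion followed by two-sided bead size selection.
#' Each parent fragment receives a Poisson number of cuts with mean
#' `length / fragmentase_target_mean - 1` at uniform internal breakpoints;
#' only pieces whose length falls inside the inclusive retention window
#' (default 40-50 bp) survive. A parent whose pieces all miss the window
#' simply contributes nothing. Note that with a hard retention window the
#' conditional mean of kept pieces sits near 44.8 bp, slightly above the
#' 43.8 bp target (see the methods vignette).
#'
#' @param fragments data.frame from [simulate_cfdna()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return data.frame of retained sub-fragments with columns `chrom`,
#'   `start`, `end`, `origin`, `parent` (row index of the parent fragment).
#' @export
fragmentase_and_select <- function(fragments, config, seed = NULL) {
  stopifnot(inherits(config, "nipt_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  win <- config$size_select_window
  n <- nrow(fragments)
  if (n == 0L) return(cbind(fragments[0, ], parent = integer()))
  plen <- fragments$end - fragments$start

  ncuts <- stats::rpois(n, pmax(plen / config$fragmentase_target_mean - 1, 0))
  idx <- rep.int(seq_len(n), ncuts)
  u <- stats::runif(length(idx)) * plen[idx]
  o <- order(idx, u)
  idx <- idx[o]; u <- u[o]

  # piece boundaries per parent: (0, cut_1, ..., cut_k, parent_len)
  first <- !duplicated(idx)
  last <- !duplicated(idx, fromLast = TRUE)
  prev <- c(0, u[-length(u)]); prev[first] <- 0
  piece_parent <- c(idx, idx[last], which(ncuts == 0L))
  piece_start <- c(prev, u[last], rep(0, sum(ncuts == 0L)))
  piece_end <- c(u, plen[idx[last]], plen[ncuts == 0L])

  piece_start <- floor(piece_start)
  piece_end <- floor(piece_end)
  L <- piece_end - piece_start
  keep <- L >= win[1] & L <= win[2]
  piece_parent <- piece_parent[keep]
  out <- data.frame(
    chrom = fragments$chrom[piece_parent],
    start = as.integer(fragments$start[piece_parent] + piece_start[keep]),
    end = as.integer(fragments$start[piece_parent] + piece_end[keep]),
    origin = fragments$origin[piece_parent],
    parent = piece_parent)
  out[order(out$parent), , drop = FALSE]
}

#' Random self-ligation into long chimeric molecules
#'
#' Consumes sub-fragments in random order without replacement, assigning
#' each an independent random orientation, and closes a molecule as soon as
#' its total length exceeds `chimera_min_len` (default 300 bp). A leftover
#' short tail that never reaches the threshold is discarded. The parts table
#' is the simulator's ground truth: every junction offset within each
#' molecule is recorded.
#'
#' @param sub_fragments data.frame from [fragmentase_and_select()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `nipt_chimeras` with elements
#'   \describe{
#'     \item{parts}{data.frame: `molecule_id`, `part_index`, `chrom`,
#'       `start`, `end` (0-based half-open genomic), `orientation`
#'       (`"+"`/`"-"` within the molecule), `mol_offset` (0-based offset of
#'       the part within the molecule), `origin`.}
#'     \item{molecules}{data.frame: `molecule_id`, `n_parts`, `total_len`.}
#'   }
#' @export
ligate_chimeras <- function(sub_fragments, config, seed = NULL) {
  stopifnot(inherits(config, "nipt_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sub_fragments)
  if (n == 0L) stop("no sub-fragments to ligate")
  ord <- sample.int(n)
  sf <- sub_fragments[ord, , drop = FALSE]
  len <- sf$end - sf$start

  # molecule boundaries: close as soon as cumulative length > min_len
  min_len <- config$chimera_min_len
  mol <- integer(n); m <- 1L
  total <- 0
  for (i in seq_len(n)) {
    mol[i] <- m
    total <- total + len[i]
    if (total > min_len) { m <- m + 1L; total <- 0 }
  }
  if (total > 0 && total <= min_len) {
    # unfinished tail molecule discarded
    keep <- mol < m
    sf <- sf[keep, , drop = FALSE]; len <- len[keep]; mol <- mol[keep]
  }
  if (nrow(sf) == 0L) stop("no molecule reached chimera_min_len")

  orientation <- ifelse(stats::runif(nrow(sf)) < 0.5, "+", "-")
  part_index <- stats::ave(seq_along(mol), mol, FUN = seq_along)
  mol_offset <- stats::ave(len, mol, FUN = function(x) cumsum(x) - x)

  parts <- data.frame(
    molecule_id = sprintf("mol%06d", mol),
    part_index = as.integer(part_index),
    chrom = sf$chrom, start = sf$start, end = sf$end,
    orientation = orientation,
    mol_offset = as.integer(mol_offset),
    origin = sf$origin)
  molecules <- data.frame(
    molecule_id = sprintf("mol%06d", sort(unique(mol))),
    n_parts = as.integer(tapply(mol, mol, length)),
    total_len = as.integer(tapply(len, mol, sum)))
  rownames(molecules) <- NULL
  structure(list(parts = parts, molecules = molecules),
            class = "nipt_chimeras")
}
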