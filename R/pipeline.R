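#' Run the full simulated NIPT workflow
#'
#' Simulates a cohort on a toy genome and pushes it through the complete
#' analysis: per-sample cfDNA simulation (cases carry the fetal trisomy),
#' SNP-amplicon fetal-fraction estimation, sample QC, binning, the
#' peak/GC/chi-squared variation-reduction chain, chromosomal-fraction
#' Z-scores against the control set, aneuploidy calls, and cross-validated
#' performance metrics with prevalence-indexed predictive values.
#'
#' Two modes are available. `"fragments"` (default) samples cfDNA fragment
#' tags directly - the fast path used for cohort-scale evaluation.
#' `"reads"` additionally runs each sample through enzymatic fragmentation,
#' random self-ligation, truth-SAM emission and alignment deconstruction
#' with repeat/amplicon filtering, exercising the whole chimeric-read
#' machinery (slower; intended for small cohorts).
#'
#' @param config A [sim_config()]; `fetal_fraction` applies to every
#'   sample and `n_cfdna_fragments` is the per-sample fragment count.
#' @param n_controls,n_cases Cohort composition.
#' @param trisomy_chrom Chromosome trisomic in the case samples.
#' @param mode `"fragments"` or `"reads"` (see Details).
#' @param bin_size Bin width; default [default_bin_size()].
#' @param min_fragments,min_ff Sample QC thresholds. The defaults are the
#'   clinical values (2.5e6 fragments, 4 percent); pass scaled values for
#'   toy cohorts below clinical depth.
#' @param z_threshold Aneuploidy call threshold (default 3).
#' @param n_runs Cross-validation runs (default 200).
#' @param out_dir Optional directory for TSV/JSON artifacts.
#' @return list of class `nipt_report`: `samples` (per-sample QC, fetal
#'   fraction, sex call, genome-wide match QC), `z` (per-sample Z-score
#'   table), `cv` (cross-validation result), `predictive` (PPV/NPV
#'   table), `bin_state`.
#' @export
run_pipeline <- function(config = sim_config(),
                         n_controls = 20, n_cases = 5,
                         trisomy_chrom = "chr21",
                         mode = c("fragments", "reads"),
                         bin_size = NULL,
                         min_fragments = 2.5e6, min_ff = 0.04,
                         z_threshold = 3, n_runs = 200,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_controls > n_cases, n_cases >= 1)
  set.seed(config$seed)
  ref <- make_reference(config)
  if (is.null(bin_size)) bin_size <- default_bin_size(ref)

  ids <- c(sprintf("ctrl%02d", seq_len(n_controls)),
           sprintf("case%02d", seq_len(n_cases)))
  is_case <- c(rep(FALSE, n_controls), rep(TRUE, n_cases))

  frag_list <- vector("list", length(ids)); names(frag_list) <- ids
  samples <- data.frame(sample_id = ids, is_case = is_case,
                        n_filtered = NA_real_, ff = NA_real_,
                        ff_y = NA_real_, sex = NA_character_,
                        qc_pass = NA)
  male_anchor <- y_anchor_male(ref$chrom_lengths)

  for (i in seq_along(ids)) {
    cfg_i <- config
    cfg_i$trisomy_chrom <- if (is_case[i]) trisomy_chrom else NULL
    seed_i <- (config$seed + 1009L * i) %% .Machine$integer.max
    fr <- simulate_cfdna(ref, cfg_i, seed = seed_i)
    if (mode == "reads") {
      sub <- fragmentase_and_select(fr, cfg_i)
      chim <- ligate_chimeras(sub, cfg_i)
      sam <- tempfile(fileext = ".sam")
      emit_truth_sam(chim, ref, cfg_i, sam)
      frags <- extract_subreads(stream_alignments(sam))
      unlink(sam)
      kept <- filter_fragments(frags, ref$repeats, ref$amplicons)$kept
    } else {
      kept <- fr
    }
    frag_list[[i]] <- kept
    samples$n_filtered[i] <- nrow(kept)

    counts <- simulate_amplifet(ref$snps, cfg_i, seed = seed_i + 1L)
    ffest <- if (coverage_qc(counts)$pass)
      estimate_ff(classify_informative(counts)) else
        structure(list(method = "amplifet", ff = NA_real_,
                       n_informative = 0L, qc_pass = FALSE,
                       note = "coverage below 50x"), class = "nipt_ff")
    samples$ff[i] <- ffest$ff
    yfr <- y_fraction(kept)
    ffy <- ff_from_y(yfr, y_frac_female_bg = 0,
                     y_frac_full_male = male_anchor)
    samples$ff_y[i] <- ffy$ff
    samples$sex[i] <- call_sex(ffest$ff, ffy$ff)
    qc <- sample_qc(nrow(kept), ffest$ff, min_fragments, min_ff)
    samples$qc_pass[i] <- qc$pass
  }

  usable <- samples$qc_pass
  if (sum(usable & !is_case) < 3)
    stop("fewer than 3 usable control samples after QC")

  bm <- bin_counts(frag_list[usable], bin_size, ref)
  bm <- peak_correction(bm)
  bm <- gc_correct(bm)
  ctrl_rows <- which(!is_case[usable])
  ctrl_bm <- .new_binmatrix(bm$bins, bm$counts[ctrl_rows, , drop = FALSE],
                            bm$state, bm$mask)
  bm <- chi2_variation_reduction(ctrl_bm, bm)

  # genome-wide profile match QC of every usable sample against the
  # control cohort (controls checked leave-one-out)
  samples$match_qc_pass <- NA
  usable_idx <- which(usable)
  for (j in seq_along(usable_idx)) {
    ref_rows <- setdiff(ctrl_rows, j)
    ref_bm <- .new_binmatrix(bm$bins, bm$counts[ref_rows, , drop = FALSE],
                             bm$state, bm$mask)
    samples$match_qc_pass[usable_idx[j]] <-
      match_qc(bm$counts[j, ], ref_bm)$pass
  }

  frac <- chromosomal_fraction(bm, trisomy_chrom)
  ctrl_frac <- frac[ctrl_rows]
  zt <- z_score(frac, ctrl_frac, threshold = z_threshold)
  zt$is_case <- is_case[usable]

  cv <- cross_validate(frac, is_case[usable], n_runs = n_runs,
                       z_threshold = z_threshold)
  perf <- stats::setNames(list(list(sensitivity = cv$sensitivity,
                                    specificity = cv$specificity)),
                          trisomy_chrom)
  predictive <- performance_table(perf)

  report <- structure(list(samples = samples, z = zt, cv = cv,
                           predictive = predictive, bin_state = bm$state,
                           bin_size = bin_size),
                      class = "nipt_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(samples, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(zt, file.path(out_dir, "zscores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(cv = cv[c("sensitivity", "sensitivity_sd", "specificity",
                     "specificity_sd", "auc", "auc_sd", "n_runs")],
           seed = config$seed, bin_size = bin_size),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.nipt_report <- function(x, ...) {
  cat("chimeraNIPT pipeline report\n")
  cat(sprintf("  samples: %d (%d QC-pass), bin state %s\n",
              nrow(x$samples), sum(x$samples$qc_pass), x$bin_state))
  called <- sum(x$z$call == "aneuploid")
  cat(sprintf("  aneuploid calls: %d of %d tested\n", called, nrow(x$z)))
  print(x$cv)
  invisible(x)
}
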