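#' Chromosomal fraction of a target chromosome
#'
#' The statistic standardised into the aneuploidy Z-score: counts on the
#' target chromosome divided by counts on a fixed denominator set. By
#' default the denominator contains all autosomes except chromosomes 13,
#' 18 and 21 (and no sex chromosomes), so a trisomy never deflates its own
#' normaliser; the same denominator is used for every sample. Masked bins
#' are excluded everywhere.
#'
#' @param m A corrected `nipt_binmatrix`.
#' @param target_chrom Chromosome whose dosage is tested.
#' @param denominator_chroms Optional character vector overriding the
#'   default denominator set.
#' @return Named numeric vector of per-sample fractions.
#' @export
chromosomal_fraction <- function(m, target_chrom,
                                 denominator_chroms = NULL) {
  stopifnot(inherits(m, "nipt_binmatrix"))
  chroms <- unique(m$bins$chrom)
  if (!target_chrom %in% chroms) stop("unknown target chromosome")
  if (is.null(denominator_chroms)) {
    excl <- c("chr13", "chr18", "chr21", "chrX", "chrY",
              "13", "18", "21", "X", "Y", "chrM", "MT")
    denominator_chroms <- setdiff(chroms, excl)
  }
  keep <- !m$mask
  ti <- keep & m$bins$chrom == target_chrom
  di <- keep & m$bins$chrom %in% denominator_chroms
  num <- rowSums(m$counts[, ti, drop = FALSE])
  den <- rowSums(m$counts[, di, drop = FALSE])
  if (any(den == 0)) stop("zero denominator counts for sample(s): ",
                          paste(rownames(m$counts)[den == 0], collapse = ", "))
  num / den
}

#' Aneuploidy Z-score against a control set
#'
#' Standardises a sample's chromosomal fraction against the control mean
#' and SD; the call is aneuploid if and only if z strictly exceeds the
#' threshold (one-sided: the test targets trisomies).
#'
#' @param sample_fraction Numeric vector of sample fractions (named).
#' @param control_fractions Numeric vector of control fractions (>= 2).
#' @param threshold Z-score call threshold (default 3).
#' @return data.frame with `fraction`, `control_mean`, `control_sd`, `z`,
#'   `call` (`"aneuploid"`/`"euploid"`).
#' @export
z_score <- function(sample_fraction, control_fractions, threshold = 3) {
  if (length(control_fractions) < 2) stop("need >= 2 controls")
  mu <- mean(control_fractions)
  sd_ <- stats::sd(control_fractions)
  if (sd_ == 0) stop("degenerate control set: sd = 0")
  z <- (sample_fraction - mu) / sd_
  data.frame(sample_id = if (is.null(names(sample_fraction)))
               as.character(seq_along(sample_fraction))
             else names(sample_fraction),
             fraction = unname(sample_fraction),
             control_mean = mu, control_sd = sd_, z = unname(z),
             call = ifelse(z > threshold, "aneuploid", "euploid"))
}

# rank-statistic AUC, ties counted 0.5 (average ranks)
.auc_rank <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated case-control cross-validation of the Z-score classifier
#'
#' Each run builds a test set from all case samples plus an equal number of
#' randomly chosen controls; the remaining controls form the training set
#' that defines the control mean and SD. Sensitivity (cases with z above
#' the threshold), specificity (held-out controls at or below it) and the
#' rank-statistic AUC are averaged over `n_runs` runs, with SDs; per-sample
#' minimum and maximum z across runs are tracked.
#'
#' @param fractions Named numeric vector of chromosomal fractions, one per
#'   sample.
#' @param is_case Logical vector: which samples carry the trisomy.
#' @param n_runs Number of runs (default 200).
#' @param z_threshold Call threshold (default 3).
#' @param seed Optional integer seed for the control sampling.
#' @return list of class `nipt_cv`: `sensitivity`, `sensitivity_sd`,
#'   `specificity`, `specificity_sd`, `auc`, `auc_sd`, `n_runs`,
#'   `n_test`, `n_train`, and `per_sample` (data.frame with `sample_id`,
#'   `is_case`, `min_z`, `max_z`, `n_tested`).
#' @export
cross_validate <- function(fractions, is_case, n_runs = 200,
                           z_threshold = 3, seed = NULL) {
  stopifnot(length(fractions) == length(is_case))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(fractions)
  if (is.null(ids)) ids <- as.character(seq_along(fractions))
  cases <- which(is_case); ctrls <- which(!is_case)
  n_case <- length(cases)
  if (n_case < 1) stop("need >= 1 case")
  if (length(ctrls) <= n_case)
    stop("need more controls than cases (", length(ctrls), " <= ",
         n_case, ")")

  sens <- spec <- auc <- numeric(n_runs)
  min_z <- rep(Inf, length(fractions)); max_z <- rep(-Inf, length(fractions))
  n_tested <- integer(length(fractions))
  for (r in seq_len(n_runs)) {
    test_ctrl <- sample(ctrls, n_case)
    train <- setdiff(ctrls, test_ctrl)
    mu <- mean(fractions[train]); sd_ <- stats::sd(fractions[train])
    test <- c(cases, test_ctrl)
    z <- (fractions[test] - mu) / sd_
    zc <- z[seq_len(n_case)]; z0 <- z[-seq_len(n_case)]
    sens[r] <- mean(zc > z_threshold)
    spec[r] <- mean(z0 <= z_threshold)
    auc[r] <- .auc_rank(zc, z0)
    min_z[test] <- pmin(min_z[test], z)
    max_z[test] <- pmax(max_z[test], z)
    n_tested[test] <- n_tested[test] + 1L
  }
  per_sample <- data.frame(sample_id = ids, is_case = is_case,
                           min_z = ifelse(n_tested > 0, min_z, NA),
                           max_z = ifelse(n_tested > 0, max_z, NA),
                           n_tested = n_tested)
  structure(list(sensitivity = mean(sens), sensitivity_sd = stats::sd(sens),
                 specificity = mean(spec), specificity_sd = stats::sd(spec),
                 auc = mean(auc), auc_sd = stats::sd(auc),
                 n_runs = n_runs, n_test = 2L * n_case,
                 n_train = length(ctrls) - n_case,
                 per_sample = per_sample),
            class = "nipt_cv")
}

#' @export
print.nipt_cv <- function(x, ...) {
  cat(sprintf(paste0("cross-validation over %d runs ",
                     "(test %d, train %d):\n"),
              x$n_runs, x$n_test, x$n_train))
  cat(sprintf("  sensitivity %.4f (SD %.4f)\n", x$sensitivity,
              x$sensitivity_sd))
  cat(sprintf("  specificity %.4f (SD %.4f)\n", x$specificity,
              x$specificity_sd))
  cat(sprintf("  AUC         %.4f (SD %.4f)\n", x$auc, x$auc_sd))
  invisible(x)
}

#' Sensitivity/specificity sweep over minimum-fragment thresholds
#'
#' Re-runs the cross-validated evaluation per chromosome after excluding
#' samples whose filtered-fragment count falls below each threshold
#' (defaults: 1.0, 1.5, 2.0, 2.5 and 3.0 million). Cells with no
#' qualifying case are reported as `NA`, not zero.
#'
#' @param fractions Named list: chromosome -> named numeric vector of
#'   per-sample fractions.
#' @param trisomy Character vector per sample: the trisomic chromosome or
#'   `"none"`.
#' @param n_filtered Numeric vector of per-sample filtered-fragment counts.
#' @param thresholds Fragment thresholds to sweep.
#' @param n_runs,z_threshold,seed Passed to [cross_validate()].
#' @return data.frame with one row per chromosome x threshold:
#'   `chrom`, `threshold`, `n_cases`, `n_controls`, `sensitivity`,
#'   `sensitivity_sd`, `specificity`, `specificity_sd`, `auc`.
#' @export
min_fragment_sweep <- function(fractions, trisomy, n_filtered,
                               thresholds = c(1.0e6, 1.5e6, 2.0e6,
                                              2.5e6, 3.0e6),
                               n_runs = 200, z_threshold = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (chrom in names(fractions)) {
    fr <- fractions[[chrom]]
    stopifnot(length(fr) == length(trisomy),
              length(fr) == length(n_filtered))
    for (thr in thresholds) {
      qual <- n_filtered >= thr
      is_case <- trisomy == chrom
      nc <- sum(qual & is_case); n0 <- sum(qual & trisomy == "none")
      row <- data.frame(chrom = chrom, threshold = thr, n_cases = nc,
                        n_controls = n0, sensitivity = NA_real_,
                        sensitivity_sd = NA_real_, specificity = NA_real_,
                        specificity_sd = NA_real_, auc = NA_real_)
      if (nc >= 1 && n0 > nc) {
        sub <- qual & (is_case | trisomy == "none")
        cv <- cross_validate(fr[sub], is_case[sub], n_runs = n_runs,
                             z_threshold = z_threshold)
        row$sensitivity <- cv$sensitivity
        row$sensitivity_sd <- cv$sensitivity_sd
        row$specificity <- cv$specificity
        row$specificity_sd <- cv$specificity_sd
        row$auc <- cv$auc
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
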