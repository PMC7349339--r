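#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the normal-approximation score test. For k = n the lower bound
#' reduces to n / (n + z^2), which is what makes small perfect-sensitivity
#' cohorts (4/4, 6/6) give informative lower limits. The z quantile is used
#' at full precision.
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(k >= 0, k <= n)
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes' rule for a binary test: PPV = se.pi / (se.pi + (1-sp)(1-pi)),
#' NPV = sp(1-pi) / (sp(1-pi) + (1-se)pi). Degenerate prevalences resolve
#' to the limits PPV = 0, NPV = 1 at pi = 0 and PPV = 1, NPV = 0 at
#' pi = 1; a test with perfect sensitivity has NPV = 1 at any prevalence.
#'
#' @param se,sp Sensitivity and specificity in [0,1].
#' @param prevalence Disease prevalence in [0,1] (vectorised).
#' @return data.frame with `prevalence`, `ppv`, `npv`.
#' @export
ppv_npv <- function(se, sp, prevalence) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            all(prevalence >= 0), all(prevalence <= 1))
  pi <- prevalence
  tp <- se * pi; fp <- (1 - sp) * (1 - pi)
  tn <- sp * (1 - pi); fn <- (1 - se) * pi
  ppv <- ifelse(pi == 0, 0, ifelse(pi == 1, 1,
                                   ifelse(tp + fp == 0, 0, tp / (tp + fp))))
  npv <- ifelse(pi == 0, 1, ifelse(pi == 1, 0,
                                   ifelse(tn + fn == 0, 0, tn / (tn + fn))))
  data.frame(prevalence = pi, ppv = ppv, npv = npv)
}

#' Default prevalence grids per trisomy
#'
#' Population prevalences of the three viable autosomal trisomies differ by
#' an order of magnitude (about 22, 5 and 2 per 10,000 births for T21, T18
#' and T13), so predictive values are tabulated over trisomy-specific
#' prevalence grids.
#'
#' @return Named list chromosome -> numeric vector of prevalences.
#' @export
default_prevalence_grids <- function() {
  list(chr21 = c(0.05, 0.10, 0.20, 0.50, 1.00, 1.50, 2.00) / 100,
       chr18 = c(0.03, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50) / 100,
       chr13 = c(0.01, 0.02, 0.05, 0.10, 0.20) / 100)
}

#' Prevalence-indexed predictive-value report
#'
#' Evaluates PPV/NPV on a prevalence grid per chromosome from
#' cross-validated (or directly estimated) sensitivity and specificity.
#'
#' @param performance Named list chromosome -> list with `sensitivity` and
#'   `specificity` (e.g. [cross_validate()] results).
#' @param prevalence_grids Named list chromosome -> prevalences; defaults
#'   to [default_prevalence_grids()] where names match.
#' @return data.frame with `chrom`, `prevalence`, `ppv`, `npv`.
#' @export
performance_table <- function(performance, prevalence_grids = NULL) {
  if (is.null(prevalence_grids)) prevalence_grids <- default_prevalence_grids()
  rows <- lapply(names(performance), function(chrom) {
    grid <- prevalence_grids[[chrom]]
    if (is.null(grid)) grid <- c(0.001, 0.005, 0.01)
    pv <- ppv_npv(performance[[chrom]]$sensitivity,
                  performance[[chrom]]$specificity, grid)
    cbind(chrom = chrom, pv)
  })
  do.call(rbind, rows)
}
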