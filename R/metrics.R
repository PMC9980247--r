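# AUC and the study's summary statistics: train/test tradeoff geometry,
# boxplot summaries, and learning-curve convergence.

#' Mann–Whitney AUC
#'
#' The probability that a random positive case scores above a random
#' negative case, counting ties as 1/2 — computed from midranks, which is
#' algebraically identical to the pairwise count and to the trapezoidal
#' area under the ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_mann_whitney(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)) # 0.75
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined: both classes must be present.",
          class = "splitbias_domain_error")
  }
  if (anyNA(scores)) {
    abort("AUC is undefined for missing scores.",
          class = "splitbias_domain_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Train-vs-test tradeoff statistics
#'
#' Summarizes a cloud of (train AUC, test AUC) points from repeated
#' shuffle-splits. Points are projected onto the diagonal direction
#' `(1,1)/sqrt(2)` (joint level) and the anti-diagonal `(1,-1)/sqrt(2)`
#' (train-test disparity); `anisotropy = sd_antidiagonal / sd_diagonal`
#' greater than 1, together with a negative Pearson correlation, is the
#' signature of the train/test tradeoff in which better training splits
#' test worse and vice versa. Isotropic scatter around the diagonal
#' (anisotropy near 1) indicates no such tradeoff.
#'
#' @param points A data frame with numeric columns `train_auc` and
#'   `test_auc` (at least 2 rows).
#' @return A one-row tibble of class `tradeoff_stats`: `n_points`,
#'   `pearson_r`, `spearman_rho`, `sd_diagonal`, `sd_antidiagonal`,
#'   `anisotropy`, `degenerate`.
#' @export
tradeoff_statistics <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("train_auc", "test_auc") %in% names(points)))
  tr <- points$train_auc
  te <- points$test_auc
  if (length(tr) < 2) {
    abort("tradeoff_statistics needs at least 2 points.",
          class = "splitbias_domain_error")
  }
  diag_proj <- (tr + te) / sqrt(2)
  anti_proj <- (tr - te) / sqrt(2)
  sd_d <- sd(diag_proj)
  sd_a <- sd(anti_proj)
  degenerate <- sd(tr) == 0 || sd(te) == 0
  out <- tibble::tibble(
    n_points = length(tr),
    pearson_r = if (degenerate) NA_real_ else cor(tr, te),
    spearman_rho = if (degenerate) NA_real_ else cor(tr, te, method = "spearman"),
    sd_diagonal = sd_d,
    sd_antidiagonal = sd_a,
    anisotropy = if (sd_d == 0) Inf else sd_a / sd_d,
    degenerate = degenerate)
  class(out) <- c("tradeoff_stats", class(out))
  out
}

#' Five-number boxplot summary of CV AUCs
#'
#' Median and quartiles by linear interpolation between order statistics
#' (the type-7 convention), matching what a standard boxplot displays.
#'
#' @param values Numeric vector (at least 1 value).
#' @param size Optional cohort size the values belong to.
#' @return A one-row tibble: `size, n, median, q1, q3, iqr`.
#' @export
boxplot_summary <- function(values, size = NA_integer_) {
  if (length(values) < 1 || anyNA(values)) {
    abort("boxplot_summary needs at least one non-missing value.",
          class = "splitbias_domain_error")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(size = as.integer(size), n = length(values),
                 median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Smallest cohort size at which the learning-curve median has converged
#'
#' Operationalizes "medians stop changing" as: the smallest size `s` such
#' that for every consecutive pair of sizes from `s` onward, the absolute
#' change in median is at most `tol_multiplier` times the IQR at the
#' larger size. Returns `NA` if no size qualifies.
#'
#' @param summaries A data frame of per-size [boxplot_summary()] rows with
#'   columns `size, median, iqr`, ordered by increasing size.
#' @param tol_multiplier Multiplier on the IQR tolerance (default 1).
#' @return The convergence size as an integer, or `NA_integer_`.
#' @export
convergence_size <- function(summaries, tol_multiplier = 1) {
  stopifnot(is.data.frame(summaries),
            all(c("size", "median", "iqr") %in% names(summaries)))
  if (nrow(summaries) < 2) {
    abort("convergence_size needs at least 2 per-size summaries.",
          class = "splitbias_domain_error")
  }
  if (is.unsorted(summaries$size, strictly = TRUE)) {
    abort("summaries must be ordered by strictly increasing size.",
          class = "splitbias_ordering_error")
  }
  m <- nrow(summaries)
  ok <- abs(diff(summaries$median)) <= tol_multiplier * summaries$iqr[-1]
  # ok[i] refers to the pair ending at size index i + 1
  holds_from <- rev(cumprod(rev(ok))) == 1 # all pairs from index i+1 onward
  idx <- which(holds_from)
  if (length(idx) == 0) return(NA_integer_)
  as.integer(summaries$size[min(idx) + 1L])
}
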