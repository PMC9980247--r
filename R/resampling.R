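# Prevalence-preserving stratified shuffle-splits, nested incremental
# cohorts for the learning curve, and per-split covariate balance testing.

#' Stratified train/test counts
#'
#' Allocates positives to the training set by half-up rounding of the exact
#' proportion, so a 700-case pool with 114 positives split 400/300 yields
#' 65/335 training and 49/251 test cases — the canonical design this
#' package studies.
#'
#' @param n_pos,n_neg Pool class counts.
#' @param train_size Number of training cases, `0 < train_size < n_pos + n_neg`.
#' @return A one-row tibble: `train_pos, train_neg, test_pos, test_neg`.
#' @examples
#' stratified_counts(114, 586, 400)
#' @export
stratified_counts <- function(n_pos, n_neg, train_size) {
  n_pos <- check_count(n_pos, "n_pos")
  n_neg <- check_count(n_neg, "n_neg")
  train_size <- check_count(train_size, "train_size")
  n <- n_pos + n_neg
  if (train_size <= 0 || train_size >= n) {
    abort("`train_size` must satisfy 0 < train_size < n_pos + n_neg.",
          class = "splitbias_stratification_error")
  }
  train_pos <- as.integer(round_half_up(train_size * n_pos / n))
  train_neg <- as.integer(train_size - train_pos)
  test_pos <- n_pos - train_pos
  test_neg <- n_neg - train_neg
  if (min(train_pos, train_neg, test_pos, test_neg) <= 0) {
    abort(sprintf("degenerate stratification: counts (%d, %d, %d, %d) include an empty stratum.",
                  train_pos, train_neg, test_pos, test_neg),
          class = "splitbias_stratification_error")
  }
  tibble::tibble(train_pos = train_pos, train_neg = train_neg,
                 test_pos = test_pos, test_neg = test_neg)
}

#' One stratified shuffle-split
#'
#' Uniformly random assignment within each label stratum, preserving the
#' pool prevalence per [stratified_counts()]. Deterministic given `seed`.
#'
#' @param cohort A `cohort` tibble.
#' @param train_size Number of training cases.
#' @param seed Integer seed for this split.
#' @return A list of class `cohort_split`: `seed`, `train_ids`, `test_ids`,
#'   and the `counts` tibble.
#' @export
shuffle_split <- function(cohort, train_size, seed) {
  counts <- stratified_counts(sum(cohort$label == 1), sum(cohort$label == 0),
                              train_size)
  pos_ids <- cohort$case_id[cohort$label == 1]
  neg_ids <- cohort$case_id[cohort$label == 0]
  with_seed(seed, {
    train_ids <- c(sample(pos_ids, counts$train_pos),
                   sample(neg_ids, counts$train_neg))
  })
  split <- list(seed = as.integer(seed),
                train_ids = sort(train_ids),
                test_ids = sort(setdiff(cohort$case_id, train_ids)),
                counts = counts)
  class(split) <- "cohort_split"
  split
}

#' @exportS3Method base::print
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split seed=%d> train %d (%d+/%d-), test %d (%d+/%d-)\n",
              x$seed, length(x$train_ids), x$counts$train_pos,
              x$counts$train_neg, length(x$test_ids), x$counts$test_pos,
              x$counts$test_neg))
  invisible(x)
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t statistic with Welch–Satterthwaite degrees of freedom,
#' computed directly from the textbook formula. If both groups have zero
#' variance and equal means, `t = 0, p = 1` by convention; zero variance
#' with unequal means is an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `statistic, df, p_value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_t_test needs at least 2 observations per group.",
          class = "splitbias_domain_error")
  }
  vx <- var(x); vy <- var(y)
  nx <- length(x); ny <- length(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = nx + ny - 2, p_value = 1))
    }
    abort("both groups have zero variance but unequal means.",
          class = "splitbias_domain_error")
  }
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  tibble::tibble(statistic = t_stat, df = df,
                 p_value = 2 * pt(-abs(t_stat), df))
}

#' Covariate balance report for a split
#'
#' Tests each monitored covariate (by default patient age and lesion size,
#' the established upstaging predictors the study monitors) for a
#' train-vs-test mean difference and flags covariates with `p < alpha`.
#' `"lesion_size"` resolves to the designated radiomic column `f001`.
#'
#' @param cohort A `cohort` tibble.
#' @param split A [shuffle_split()] result.
#' @param covariates Covariate names to monitor.
#' @param alpha Significance level for flagging.
#' @param test `"welch"` (default) or `"mannwhitney"`.
#' @return A tibble of class `balance_report`: one row per covariate with
#'   `statistic, df, p_value, flag`; `attr(, "alpha")` records the level.
#' @export
covariate_balance <- function(cohort, split,
                              covariates = c("age", "lesion_size"),
                              alpha = 0.05,
                              test = c("welch", "mannwhitney")) {
  test <- rlang::arg_match(test)
  tr <- match(split$train_ids, cohort$case_id)
  te <- match(split$test_ids, cohort$case_id)
  rows <- purrr::map_dfr(covariates, function(cv) {
    col <- resolve_covariate(cohort, cv)
    x <- cohort[[col]][tr]
    y <- cohort[[col]][te]
    if (test == "welch") {
      res <- welch_t_test(x, y)
    } else {
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      res <- tibble::tibble(statistic = unname(wt$statistic), df = NA_real_,
                            p_value = wt$p.value)
    }
    dplyr::mutate(res, covariate = cv, .before = 1)
  })
  rows$flag <- rows$p_value < alpha
  attr(rows, "alpha") <- alpha
  class(rows) <- c("balance_report", class(rows))
  rows
}

#' Nested incremental cohorts for the learning curve
#'
#' Builds `n_chains` independent chains of strictly nested stratified
#' subsets: each chain starts from a random stratified subset at the
#' smallest size and grows by stratified random increments (sampling
#' without replacement from the remaining pool) until the full cohort is
#' reached. Per-size positive counts are `round_half_up(size * prevalence)`,
#' so at the full size every chain is the whole cohort.
#'
#' @param cohort A `cohort` tibble.
#' @param sizes Strictly increasing subset sizes; defaults to steps of 100
#'   up to the cohort size.
#' @param n_chains Number of independent chains.
#' @param seed Master seed; chain `i` uses `derive_seed(seed, i)`.
#' @return A list of `cohort_chain` objects, each with `chain_id`, `sizes`
#'   and `member_ids` (a list of id vectors, nested across sizes).
#' @export
nested_cohorts <- function(cohort, sizes = NULL, n_chains = 20, seed = 1) {
  n <- nrow(cohort)
  if (is.null(sizes)) sizes <- unique(c(seq(100, n, by = 100), n))
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) {
    abort("`sizes` must be strictly increasing.",
          class = "splitbias_stratification_error")
  }
  if (max(sizes) > n) {
    abort("max(sizes) exceeds the cohort size.",
          class = "splitbias_stratification_error")
  }
  n_pos <- sum(cohort$label == 1)
  prev <- n_pos / n
  pos_target <- as.integer(round_half_up(sizes * prev))
  neg_target <- sizes - pos_target
  if (any(diff(c(0L, pos_target)) < 0) || any(diff(c(0L, neg_target)) < 0)) {
    abort("an increment is too small to preserve stratification.",
          class = "splitbias_stratification_error")
  }
  if (any(pos_target < 1) || any(neg_target < 1)) {
    abort("a size yields an empty stratum.",
          class = "splitbias_stratification_error")
  }
  pos_ids <- cohort$case_id[cohort$label == 1]
  neg_ids <- cohort$case_id[cohort$label == 0]
  purrr::map(seq_len(n_chains), function(ch) {
    with_seed(derive_seed(seed, ch), {
      pos_order <- sample(pos_ids)
      neg_order <- sample(neg_ids)
      member_ids <- purrr::map2(pos_target, neg_target, function(np, nn) {
        sort(c(pos_order[seq_len(np)], neg_order[seq_len(nn)]))
      })
      structure(list(chain_id = ch, sizes = sizes, member_ids = member_ids,
                     pos_counts = pos_target),
                class = "cohort_chain")
    })
  })
}

#' @exportS3Method base::print
print.cohort_chain <- function(x, ...) {
  cat(sprintf("<cohort_chain %d> sizes: %s\n", x$chain_id,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @rdname nested_cohorts
#' @param x A `cohort_chain`.
#' @param ... Unused.
#' @export
tidy.cohort_chain <- function(x, ...) {
  purrr::map2_dfr(x$sizes, x$member_ids, function(s, ids) {
    tibble::tibble(chain_id = x$chain_id, size = s, case_id = ids)
  })
}

#' @rdname shuffle_split
#' @param x A `cohort_split`.
#' @param ... Unused.
#' @export
tidy.cohort_split <- function(x, ...) {
  tibble::tibble(seed = x$seed,
                 case_id = c(x$train_ids, x$test_ids),
                 role = rep(c("train", "test"),
                            c(length(x$train_ids), length(x$test_ids))))
}
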