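test_that("stratified counts reproduce the canonical 400/300 split of a 700-case pool", {
  counts <- stratified_counts(114, 586, 400)
  expect_equal(counts$train_pos, 65)
  expect_equal(counts$train_neg, 335)
  expect_equal(counts$test_pos, 49)
  expect_equal(counts$test_neg, 251)
})

test_that("stratified counts follow half-up rounding and reject degenerate splits", {
  expect_equal(stratified_counts(5, 5, 4)$train_pos, 2)
  # 50 * 7 / 100 = 3.5 rounds up to 4
  expect_equal(stratified_counts(7, 93, 50)$train_pos, 4)
  expect_error(stratified_counts(2, 98, 99),
               class = "splitbias_stratification_error")
  expect_error(stratified_counts(114, 586, 0),
               class = "splitbias_config_error")
  expect_error(stratified_counts(114, 586, 700),
               class = "splitbias_stratification_error")
})

test_that("shuffle splits are exact partitions with fixed stratum counts and deterministic seeds", {
  cohort <- generate_cohort(generator_config(seed = 8))
  for (seed in c(1, 999)) {
    sp <- shuffle_split(cohort, 400, seed)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), cohort$case_id)
    expect_equal(sum(cohort$label[match(sp$train_ids, cohort$case_id)]), 65)
  }
  expect_identical(shuffle_split(cohort, 400, 7), shuffle_split(cohort, 400, 7))
  expect_false(identical(shuffle_split(cohort, 400, 7)$train_ids,
                         shuffle_split(cohort, 400, 8)$train_ids))
})

test_that("positive cases enter training exchangeably across seeds", {
  cohort <- small_cohort()
  n_seeds <- 400
  pos_ids <- cohort$case_id[cohort$label == 1]
  counts <- stratified_counts(40, 120, 100)
  freq <- rowSums(vapply(seq_len(n_seeds), function(s) {
    pos_ids %in% shuffle_split(cohort, 100, s)$train_ids
  }, logical(length(pos_ids))))
  p <- counts$train_pos / 40
  bounds <- qbinom(c(0.0005, 0.9995), n_seeds, p) # Bonferroni-ish 99.9% band
  expect_true(all(freq >= bounds[1] & freq <= bounds[2]))
})

test_that("welch_t_test matches stats::t.test and honors its conventions", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 3, 4, 5, 6)
  mine <- welch_t_test(x, y)
  ref <- t.test(x, y) # independent oracle
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # identical samples
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # overwhelming effect
  set.seed(2)
  expect_lt(welch_t_test(rnorm(30, 0), rnorm(30, 10))$p_value, 1e-10)
  # degenerate variance conventions
  expect_equal(welch_t_test(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), class = "splitbias_domain_error")
  expect_error(welch_t_test(1, c(1, 2)), class = "splitbias_domain_error")
})

test_that("covariate balance flags constructed imbalance and none when train equals test", {
  cohort <- small_cohort()
  # adversarial: train = the youngest cases
  by_age <- cohort$case_id[order(cohort$age)]
  sp <- list(seed = 0L, train_ids = by_age[1:100], test_ids = by_age[101:160],
             counts = NULL)
  class(sp) <- "cohort_split"
  rep1 <- covariate_balance(cohort, sp)
  expect_true(rep1$flag[rep1$covariate == "age"])
  # toy duplication: identical train and test populations
  dup <- dplyr::bind_rows(cohort, dplyr::mutate(cohort, case_id = paste0(case_id, "_b")))
  sp2 <- list(seed = 0L, train_ids = cohort$case_id,
              test_ids = paste0(cohort$case_id, "_b"), counts = NULL)
  class(sp2) <- "cohort_split"
  rep2 <- covariate_balance(dup, sp2)
  expect_true(all(rep2$p_value == 1))
  # lesion_size resolves to the first radiomic column
  expect_setequal(rep2$covariate, c("age", "lesion_size"))
})

test_that("balance flag rate under the null matches alpha (binomial calibration)", {
  cohort <- small_cohort(n_cases = 200, n_positive = 50)
  n_splits <- 500
  flags <- vapply(seq_len(n_splits), function(s) {
    covariate_balance(cohort, shuffle_split(cohort, 120, s),
                      covariates = "age")$flag
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), n_splits, 0.05)
  expect_gte(sum(flags), bounds[1])
  expect_lte(sum(flags), bounds[2])
})

test_that("nested cohorts are stratified, nested, and end at the full cohort", {
  cohort <- generate_cohort(generator_config(seed = 12))
  chains <- nested_cohorts(cohort, n_chains = 4, seed = 3)
  expect_length(chains, 4)
  for (chain in chains) {
    expect_equal(chain$sizes, seq(100L, 700L, 100L))
    labels <- cohort$label[match(chain$member_ids[[1]], cohort$case_id)]
    expect_equal(sum(labels), 16) # round(100 * 114/700)
    for (i in 2:7) {
      expect_true(all(chain$member_ids[[i - 1]] %in% chain$member_ids[[i]]))
    }
    expect_setequal(chain$member_ids[[7]], cohort$case_id)
  }
  # distinct chains draw different subsets
  expect_false(setequal(chains[[1]]$member_ids[[1]], chains[[2]]$member_ids[[1]]))
  expect_error(nested_cohorts(cohort, sizes = c(100, 100)),
               class = "splitbias_stratification_error")
  expect_error(nested_cohorts(cohort, sizes = c(100, 800)),
               class = "splitbias_stratification_error")
})
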