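fake_record <- function(winners, regs = rev(seq_along(unique(winners)))) {
  ids <- sort(unique(winners))
  grid <- tibble::tibble(grid_id = ids, .reg = regs[seq_along(ids)])
  structure(list(
    folds = tibble::tibble(repeat_id = seq_along(winners),
                           fold = 1L, grid_id = winners, val_auc = 0.6),
    winners = tibble::tibble(repeat_id = seq_along(winners),
                             grid_id = winners),
    grid = grid), class = "cv_record")
}

test_that("stratified k-fold splits each class evenly and deterministically", {
  labels <- rep(c(1, 0), c(65, 335))
  folds <- stratified_kfold_indices(labels, 5, 11)
  for (f in 1:5) {
    expect_equal(sum(labels == 1 & folds == f), 13)
    expect_equal(sum(labels == 0 & folds == f), 67)
  }
  expect_identical(folds, stratified_kfold_indices(labels, 5, 11))
  expect_false(identical(folds, stratified_kfold_indices(labels, 5, 12)))
  # leave-one-out on 6 balanced cases gives singleton folds
  loo <- stratified_kfold_indices(rep(0:1, 3), 3, 1)
  expect_equal(as.integer(table(loo)), rep(2L, 3))
  expect_error(stratified_kfold_indices(c(1, rep(0, 20)), 5, 1),
               class = "splitbias_fold_error")
})

test_that("repeated_cv reaches AUC 1 on separable data and records every fold", {
  set.seed(3)
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- rep(0:1, each = 20)
  x[y == 1, 1] <- x[y == 1, 1] + 8
  rec <- repeated_cv(x, y, lr_spec_small(), cv_protocol(5, 3, 1))
  expect_equal(training_auc_summary(rec), 1.0)
  expect_equal(nrow(rec$folds), 3 * 5 * 2) # repeats x folds x grid
  expect_true(all(rec$folds$val_auc >= 0 & rec$folds$val_auc <= 1))
})

test_that("a single-grid-point spec wins every repeat", {
  set.seed(4)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep_len(0:1, 60)
  spec <- classifier_spec("logistic_regression",
                          grid = tibble::tibble(lambda = 1))
  rec <- repeated_cv(x, y, spec, cv_protocol(3, 4, 9))
  expect_true(all(rec$winners$grid_id == 1L))
})

test_that("repeated_cv on no-signal data stays near chance", {
  cohort <- generate_cohort(small_config(
    n_cases = 200, n_positive = 60, target = 0.5,
    clinical_effects = list(), lesion_size_effect = 0))
  feats <- assemble_features(cohort, "radiomics")
  rec <- repeated_cv(feats, cohort$label, lr_spec_small(),
                     cv_protocol(5, 20, 2), vendor = cohort$vendor)
  expect_gt(training_auc_summary(rec), 0.40)
  expect_lt(training_auc_summary(rec), 0.60)
})

test_that("modal hyperparameter selection matches an independent tally and tie-breaks", {
  # majority
  rec <- fake_record(c(1L, 1L, 2L))
  expect_equal(select_hyperparameters(rec)$grid_id, 1L)
  # tie goes to the more regularized grid point
  rec2 <- fake_record(c(1L, 2L), regs = c(0.1, 10))
  expect_equal(select_hyperparameters(rec2)$grid_id, 2L)
  # 200-repeat record equals the mode from a brute-force count
  set.seed(21)
  winners <- sample(1:4, 200, replace = TRUE, prob = c(0.1, 0.4, 0.3, 0.2))
  rec3 <- fake_record(winners, regs = c(4, 3, 2, 1))
  tally <- table(winners)
  expect_equal(select_hyperparameters(rec3)$grid_id,
               as.integer(names(tally)[which.max(tally)]))
})

test_that("training_auc_summary averages fold AUCs at per-repeat winners", {
  rec <- fake_record(1L)
  rec$folds <- tibble::tibble(repeat_id = 1L, fold = 1:5, grid_id = 1L,
                              val_auc = c(0.6, 0.7, 0.65, 0.7, 0.6))
  expect_equal(training_auc_summary(rec), 0.65)
  # losing grid points do not contribute
  rec$folds <- dplyr::bind_rows(
    rec$folds, tibble::tibble(repeat_id = 1L, fold = 1:5, grid_id = 2L,
                              val_auc = 0.99))
  expect_equal(training_auc_summary(rec), 0.65)
})

test_that("univariate feature selection finds separating columns and recovers planted signal", {
  set.seed(6)
  x <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(NULL, paste0("c", 1:8)))
  y <- rep_len(0:1, 100)
  x[y == 1, 5] <- x[y == 1, 5] + 50 # perfectly separating column
  expect_equal(univariate_feature_selection(x, y, 1), "c5")
  expect_equal(univariate_feature_selection(x, y, 8), paste0("c", 1:8))
  # recovery of the informative radiomic block (f002..f005 by construction)
  hits <- vapply(1:5, function(s) {
    cohort <- generate_cohort(small_config(n_cases = 2000, n_positive = 500,
                                           target = 0.85, seed = s))
    sel <- univariate_feature_selection(
      as.matrix(assemble_features(cohort, "radiomics")[, -1]),
      cohort$label, 4)
    sum(sel %in% sprintf("f%03d", 2:5))
  }, numeric(1))
  expect_gte(median(hits), 3)
})

test_that("fit_final is deterministic and its linear scores match the extracted coefficients", {
  cohort <- small_cohort()
  feats <- assemble_features(cohort, "radiomics")
  spec <- lr_spec_small()
  gp <- spec$grid[1, ]
  fm1 <- fit_final(feats, cohort$label, spec, gp, vendor = cohort$vendor)
  fm2 <- fit_final(feats, cohort$label, spec, gp, vendor = cohort$vendor)
  s1 <- predict(fm1, feats, vendor = cohort$vendor)
  expect_identical(s1, predict(fm2, feats, vendor = cohort$vendor))
  # decision function recomputed from coefficients
  co <- tidy(fm1)
  beta <- co$estimate[match(fm1$selected, co$term)]
  icpt <- co$estimate[co$term == "(Intercept)"]
  xs <- std_mat <- as.matrix(feats[, -1])
  xs <- splitbias:::std_apply_m(std_mat, cohort$vendor, fm1$std_stats)
  expect_equal(unname(s1), unname(drop(xs %*% beta) + icpt), tolerance = 1e-8)
  # refit on separable toy reaches training AUC 1
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0:1, each = 15)
  x[y == 1, 2] <- x[y == 1, 2] + 10
  fm3 <- fit_final(x, y, spec, gp)
  expect_equal(auc_mann_whitney(predict(fm3, x), y), 1.0)
  expect_error(fit_final(x, y, spec, tibble::tibble(lambda = 5, grid_id = 99L)),
               class = "splitbias_config_error")
})

test_that("fold models are functions of fold-training rows only (leak-free replication)", {
  # independent replication: rebuild every fold's model from the fold-train
  # rows alone (validation rows are touched only to be scored) and demand
  # bit-identical validation AUCs from repeated_cv
  cohort <- small_cohort()
  feats <- assemble_features(cohort, "radiomics")
  x <- as.matrix(feats[, -1])
  y <- cohort$label
  proto <- cv_protocol(5, 1, 31)
  spec <- classifier_spec("logistic_regression", fs_k = 5,
                          grid = tibble::tibble(lambda = c(0.01, 1)))
  rec <- repeated_cv(feats, y, spec, proto, vendor = cohort$vendor)
  folds <- stratified_kfold_indices(y, 5, derive_seed(proto$seed, 1))
  for (f in 1:5) {
    tr <- folds != f
    st <- splitbias:::std_fit_m(x[tr, ], cohort$vendor[tr])
    xtr <- splitbias:::std_apply_m(x[tr, ], cohort$vendor[tr], st)
    keep <- univariate_feature_selection(xtr, y[tr], 5)
    for (g in 1:2) {
      fit <- glmnet::glmnet(xtr[, keep], y[tr], family = "binomial",
                            alpha = 0, lambda = sort(spec$grid$lambda,
                                                     decreasing = TRUE),
                            standardize = FALSE)
      xva <- splitbias:::std_apply_m(x[!tr, ], cohort$vendor[!tr], st)
      manual_auc <- auc_mann_whitney(
        drop(predict(fit, xva[, keep], s = spec$grid$lambda[g])), y[!tr])
      got <- rec$folds$val_auc[rec$folds$fold == f & rec$folds$grid_id == g]
      expect_identical(got, manual_auc)
    }
  }
})

test_that("perturbing held-out test rows leaves training results bit-identical", {
  cohort <- small_cohort()
  res1 <- run_split_experiment(cohort, n_splits = 1, train_size = 100,
                               protocol = cv_protocol(5, 2, 3),
                               grids = list(logistic_regression =
                                              tibble::tibble(lambda = c(0.01, 1))),
                               seed = 5)
  test_ids <- shuffle_split(cohort, 100, derive_seed(5, 1))$test_ids
  perturbed <- cohort
  idx <- perturbed$case_id %in% test_ids
  rc <- grep("^f[0-9]{3}$", names(perturbed), value = TRUE)
  perturbed[idx, rc] <- perturbed[idx, rc] * 2 + 5
  res2 <- run_split_experiment(perturbed, n_splits = 1, train_size = 100,
                               protocol = cv_protocol(5, 2, 3),
                               grids = list(logistic_regression =
                                              tibble::tibble(lambda = c(0.01, 1))),
                               seed = 5)
  expect_identical(res1$splits$train_auc, res2$splits$train_auc)
  expect_identical(res1$splits$hyperparameters, res2$splits$hyperparameters)
  expect_false(identical(res1$splits$test_auc, res2$splits$test_auc))
})

test_that("SMO SVM satisfies the dual constraints and separates what it should", {
  set.seed(13)
  x <- matrix(rnorm(50 * 2), 50, 2)
  y <- rep(0:1, each = 25)
  x[y == 1, ] <- x[y == 1, ] + 4
  fit <- svm_smo_fit(x, y, C = 1, kernel = "linear")
  expect_true(fit$converged)
  # dual feasibility: sum_i alpha_i y_i = 0, |alpha_i y_i| <= C
  expect_equal(sum(fit$sv_coef), 0, tolerance = 1e-6)
  expect_true(all(abs(fit$sv_coef) <= 1 + 1e-8))
  scores <- predict(fit, x)
  expect_equal(auc_mann_whitney(scores, y), 1.0)
  # KKT: support vectors sit on or inside the margin, non-SVs outside it
  yy <- ifelse(y > 0, 1, -1)
  margins <- yy * scores
  is_sv <- apply(x, 1, function(r) {
    any(colSums(abs(t(fit$sv_x) - r)) < 1e-12)
  })
  expect_true(all(margins[!is_sv] >= 1 - 1e-3))
  expect_true(all(margins[is_sv] <= 1 + 1e-3))
  # XOR: linear fails, rbf succeeds
  xor_x <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  xor_x <- xor_x[rep(1:4, each = 10), ] + matrix(rnorm(80, sd = 0.1), 40, 2)
  xor_y <- as.integer(sign(xor_x[, 1]) * sign(xor_x[, 2]) > 0)
  lin <- svm_smo_fit(xor_x, xor_y, C = 10, kernel = "linear")
  rbf <- svm_smo_fit(xor_x, xor_y, C = 10, kernel = "rbf", gamma = 1)
  expect_lt(auc_mann_whitney(predict(lin, xor_x), xor_y), 0.8)
  expect_equal(auc_mann_whitney(predict(rbf, xor_x), xor_y), 1.0)
})

test_that("the SVM family runs through repeated_cv and the tie-break prefers smaller C", {
  set.seed(17)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(0:1, each = 30)
  x[y == 1, 1] <- x[y == 1, 1] + 12
  spec <- classifier_spec("svm", grid = tibble::tibble(
    kernel = "linear", C = c(0.1, 10), gamma = NA_real_))
  rec <- repeated_cv(x, y, spec, cv_protocol(3, 2, 5))
  expect_equal(training_auc_summary(rec), 1.0)
  # both C values separate perfectly -> tie -> smaller C (more regularized)
  expect_equal(select_hyperparameters(rec)$C, 0.1)
})
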