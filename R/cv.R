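# Repeated stratified k-fold cross-validation over a hyperparameter grid,
# modal hyperparameter selection, fold-internal feature selection, and the
# final refit on the full training set.

#' Classifier specification
#'
#' A classifier family plus its hyperparameter grid. The defaults are the
#' package's declared choices (the study names the families and, for the
#' SVM, the tuned hyperparameter kinds, but not the grid values):
#' L2-penalized logistic regression with penalty strength `lambda` on a
#' log grid `10^(-3..3)`, and a C-SVM over kernel `{linear, rbf}`, `C` in
#' `10^(-2..2)` and RBF coefficient `gamma` in `{scale heuristic, 1e-3,
#' 1e-2, 1e-1, 1}` (`NA` = scale heuristic; ignored by the linear kernel).
#'
#' The internal column `.reg` orders grid points from least to most
#' regularized and drives the "prefer the simpler model" tie-break.
#'
#' @param family `"logistic_regression"` or `"svm"`.
#' @param grid Optional tibble overriding the default grid
#'   (`lambda` for logistic regression; `kernel`, `C`, `gamma` for SVM).
#' @param fs_k Optional number of radiomic features to select inside each
#'   training fold (the `radiomics_fs` model); `NULL` disables selection.
#' @return A list of class `classifier_spec` with a `grid_id`-indexed grid.
#' @export
classifier_spec <- function(family = c("logistic_regression", "svm"),
                            grid = NULL, fs_k = NULL) {
  family <- rlang::arg_match(family)
  if (is.null(grid)) {
    grid <- if (family == "logistic_regression") {
      tibble::tibble(lambda = 10^seq(-3, 3))
    } else {
      dplyr::bind_rows(
        tidyr::expand_grid(kernel = "linear", C = 10^seq(-2, 2),
                           gamma = NA_real_),
        tidyr::expand_grid(kernel = "rbf", C = 10^seq(-2, 2),
                           gamma = c(NA_real_, 1e-3, 1e-2, 1e-1, 1)))
    }
  }
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) {
    abort("classifier grid must be non-empty.",
          class = "splitbias_config_error")
  }
  if (family == "logistic_regression") {
    stopifnot("lambda" %in% names(grid))
    grid$.reg <- grid$lambda
  } else {
    stopifnot(all(c("kernel", "C") %in% names(grid)))
    if (!"gamma" %in% names(grid)) grid$gamma <- NA_real_
    grid$.reg <- 1 / grid$C
  }
  grid$grid_id <- seq_len(nrow(grid))
  structure(list(family = family, grid = grid, fs_k = fs_k),
            class = "classifier_spec")
}

#' Cross-validation protocol
#'
#' @param k Number of folds (default 5).
#' @param repeats Number of times the k-fold CV is repeated with
#'   re-shuffled fold assignments (study default 200; use ~10 for a fast
#'   profile).
#' @param seed Integer seed; repeat `r` shuffles folds with
#'   `derive_seed(seed, r)`.
#' @return A list of class `cv_protocol`.
#' @export
cv_protocol <- function(k = 5, repeats = 200, seed = 1) {
  k <- check_count(k, "k", lower = 2)
  repeats <- check_count(repeats, "repeats", lower = 1)
  structure(list(k = k, repeats = repeats, seed = as.integer(seed)),
            class = "cv_protocol")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals it round-robin into `k`
#' folds, so fold sizes differ by at most one within each class.
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment in `1..k`, aligned with `labels`.
#' @export
stratified_kfold_indices <- function(labels, k, seed) {
  labels <- as.integer(labels > 0)
  k <- check_count(k, "k", lower = 2)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      if (length(idx) < k) {
        abort(sprintf("class %d has %d members, fewer than k = %d folds.",
                      cls, length(idx), k),
              class = "splitbias_fold_error")
      }
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Univariate feature selection by two-sample t statistic
#'
#' Ranks columns by the absolute Welch t statistic between classes and
#' keeps the top `k`; ties broken by column order. Run inside each
#' training fold so held-out cases never inform the selection.
#'
#' @param x Numeric matrix or data frame of features.
#' @param labels Binary labels aligned with rows.
#' @param k Number of columns to keep.
#' @return Character vector of selected column names (or indices when
#'   unnamed), in original column order.
#' @export
univariate_feature_selection <- function(x, labels, k) {
  x <- as.matrix(x)
  labels <- as.integer(labels > 0)
  if (k > ncol(x)) {
    abort("k exceeds the number of columns.", class = "splitbias_config_error")
  }
  t_abs <- abs(col_welch_t(x, labels))
  keep <- sort(order(-t_abs)[seq_len(k)])
  if (!is.null(colnames(x))) colnames(x)[keep] else keep
}

# vectorized per-column Welch t; zero-SE columns map to 0 (equal means)
# or Inf (separated constants).
col_welch_t <- function(x, labels) {
  x1 <- x[labels == 1L, , drop = FALSE]
  x0 <- x[labels == 0L, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  se <- sqrt(v1 / n1 + v0 / n0)
  d <- m1 - m0
  t_stat <- ifelse(se == 0, ifelse(d == 0, 0, Inf * sign(d)), d / se)
  t_stat
}

# ---- matrix-level per-vendor standardization used inside folds ------------

std_fit_m <- function(x, vendor) {
  groups <- if (is.null(vendor)) list(all = seq_len(nrow(x))) else
    split(seq_len(nrow(x)), vendor)
  lapply(groups, function(idx) {
    mu <- colMeans(x[idx, , drop = FALSE])
    sdv <- sqrt(colMeans(sweep(x[idx, , drop = FALSE], 2, mu)^2))
    list(mean = mu, sd = ifelse(sdv < 1e-12, 1, sdv))
  })
}

std_apply_m <- function(x, vendor, stats) {
  if (is.null(vendor)) {
    st <- stats[["all"]]
    return(sweep(sweep(x, 2, st$mean), 2, st$sd, `/`))
  }
  missing_v <- setdiff(unique(vendor), names(stats))
  if (length(missing_v) > 0) {
    abort(sprintf("vendor '%s' present at apply time but absent at fit time; refusing to leak.",
                  missing_v[1]),
          class = "splitbias_leakage_error")
  }
  out <- x
  for (v in unique(vendor)) {
    idx <- which(vendor == v)
    st <- stats[[v]]
    out[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, st$mean), 2,
                        st$sd, `/`)
  }
  out
}

# ---- grid scoring ---------------------------------------------------------

# Score validation rows for every grid point. Returns an nrow(xva) x
# nrow(grid) matrix of decision values; failed fits give NA columns.
score_grid <- function(xtr, ytr, xva, spec) {
  grid <- spec$grid
  out <- matrix(NA_real_, nrow(xva), nrow(grid))
  if (spec$family == "logistic_regression") {
    xtr2 <- ensure_two_cols(xtr)
    xva2 <- ensure_two_cols(xva)
    lam <- sort(unique(grid$lambda), decreasing = TRUE)
    fit <- tryCatch(
      glmnet::glmnet(xtr2, ytr, family = "binomial", alpha = 0,
                     lambda = lam, standardize = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) {
      for (g in seq_len(nrow(grid))) {
        out[, g] <- tryCatch(
          drop(predict(fit, xva2, s = grid$lambda[g], type = "link")),
          error = function(e) NA_real_)
      }
    }
  } else {
    for (g in seq_len(nrow(grid))) {
      fit <- tryCatch(
        svm_smo_fit(xtr, ytr, C = grid$C[g], kernel = grid$kernel[g],
                    gamma = grid$gamma[g]),
        error = function(e) NULL)
      if (!is.null(fit)) out[, g] <- predict(fit, xva)
    }
  }
  out
}

# glmnet refuses single-column x; pad with an all-zero dummy column.
ensure_two_cols <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.dummy` = 0)
}

winner_of <- function(mean_auc, grid) {
  ok <- which(!is.na(mean_auc))
  if (length(ok) == 0) return(NA_integer_)
  ord <- ok[order(-mean_auc[ok], -grid$.reg[ok], grid$grid_id[ok])]
  grid$grid_id[ord[1]]
}

#' Repeated stratified k-fold cross-validation over a grid
#'
#' For each repeat: a fresh stratified fold shuffle; for each fold,
#' per-vendor standardization and (if `spec$fs_k` is set) univariate
#' feature selection are refit on the fold-training rows only, every grid
#' point is fit on the fold-training rows and scored on the validation
#' fold by Mann–Whitney AUC. Each repeat's winner is the grid point with
#' the highest mean validation AUC across the k folds (ties prefer the
#' more regularized point, then grid order). Non-convergent fits are
#' recorded as `NA` and excluded from the comparison.
#'
#' @param features Feature tibble/matrix (a `case_id` column, if present,
#'   is dropped), rows aligned with `labels`.
#' @param labels Binary outcome vector.
#' @param spec A [classifier_spec()].
#' @param protocol A [cv_protocol()].
#' @param vendor Optional vendor vector for per-vendor standardization.
#' @param standardize Refit standardization inside each fold (default
#'   `TRUE`; set `FALSE` when features were pre-standardized globally).
#' @return An object of class `cv_record` with `$folds` (tidy per
#'   repeat/fold/grid AUCs), `$winners` (one row per repeat), and the
#'   grid/spec/protocol used.
#' @export
repeated_cv <- function(features, labels, spec, protocol,
                        vendor = NULL, standardize = TRUE) {
  x <- features_matrix(features)
  labels <- as.integer(labels > 0)
  stopifnot(nrow(x) == length(labels))
  grid <- spec$grid
  n_grid <- nrow(grid)
  k <- protocol$k
  fold_rows <- vector("list", protocol$repeats)
  winner_ids <- integer(protocol$repeats)
  for (r in seq_len(protocol$repeats)) {
    folds <- stratified_kfold_indices(labels, k, derive_seed(protocol$seed, r))
    auc_mat <- matrix(NA_real_, k, n_grid)
    for (f in seq_len(k)) {
      tr <- folds != f
      xtr <- x[tr, , drop = FALSE]
      xva <- x[!tr, , drop = FALSE]
      ytr <- labels[tr]
      yva <- labels[!tr]
      if (standardize) {
        st <- std_fit_m(xtr, vendor[tr])
        xtr <- std_apply_m(xtr, vendor[tr], st)
        xva <- std_apply_m(xva, vendor[!tr], st)
      }
      if (!is.null(spec$fs_k)) {
        keep <- univariate_feature_selection(xtr, ytr, spec$fs_k)
        xtr <- xtr[, keep, drop = FALSE]
        xva <- xva[, keep, drop = FALSE]
      }
      scores <- score_grid(xtr, ytr, xva, spec)
      auc_mat[f, ] <- apply(scores, 2, function(s) {
        if (anyNA(s)) NA_real_ else auc_mann_whitney(s, yva)
      })
    }
    mean_auc <- colMeans(auc_mat)      # NA if any fold failed for that point
    all_na <- apply(auc_mat, 2, function(a) all(is.na(a)))
    mean_auc[!all_na & is.na(mean_auc)] <-
      colMeans(auc_mat, na.rm = TRUE)[!all_na & is.na(mean_auc)]
    winner_ids[r] <- winner_of(mean_auc, grid)
    fold_rows[[r]] <- tibble::tibble(
      repeat_id = r,
      fold = rep(seq_len(k), n_grid),
      grid_id = rep(grid$grid_id, each = k),
      val_auc = as.vector(auc_mat))
  }
  if (all(is.na(winner_ids))) {
    abort("every grid point failed in every repeat.",
          class = "splitbias_fit_error")
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  winners <- tibble::tibble(repeat_id = seq_len(protocol$repeats),
                            grid_id = winner_ids)
  structure(list(folds = folds_tbl, winners = winners, grid = grid,
                 spec = spec, protocol = protocol),
            class = "cv_record")
}

features_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  df <- as.data.frame(features)
  df$case_id <- NULL
  as.matrix(df)
}

#' @exportS3Method base::print
print.cv_record <- function(x, ...) {
  cat(sprintf("<cv_record> %d repeats x %d folds x %d grid points; training AUC %.4f\n",
              x$protocol$repeats, x$protocol$k, nrow(x$grid),
              training_auc_summary(x)))
  invisible(x)
}

#' @rdname repeated_cv
#' @param x A `cv_record`.
#' @param ... Unused.
#' @export
tidy.cv_record <- function(x, ...) x$folds

#' Modal hyperparameter selection
#'
#' Returns the grid point that won the most CV repeats — the study's rule
#' for turning 200 repeated cross-validations into the single
#' hyperparameter setting used for the final classifier. Ties prefer the
#' more regularized point, then grid order.
#'
#' @param cvrecord A [repeated_cv()] result.
#' @return The winning grid row (one-row tibble, including `grid_id`).
#' @export
select_hyperparameters <- function(cvrecord) {
  w <- cvrecord$winners$grid_id
  w <- w[!is.na(w)]
  if (length(w) == 0) {
    abort("cv record has no successful repeats.",
          class = "splitbias_fit_error")
  }
  counts <- table(w)
  top <- as.integer(names(counts)[counts == max(counts)])
  grid <- cvrecord$grid[cvrecord$grid$grid_id %in% top, ]
  grid <- grid[order(-grid$.reg, grid$grid_id), ]
  grid[1, ]
}

#' Mean validation AUC at per-repeat winners
#'
#' The "training result" of one cross-validated model: the arithmetic mean
#' of all retained per-fold validation AUCs, each repeat contributing the
#' folds of its own winning grid point.
#'
#' @param cvrecord A [repeated_cv()] result.
#' @return A single AUC value.
#' @export
training_auc_summary <- function(cvrecord) {
  at_winner <- dplyr::inner_join(cvrecord$folds,
                                 cvrecord$winners, by = c("repeat_id", "grid_id"))
  mean(at_winner$val_auc, na.rm = TRUE)
}

#' Final refit on the full training set
#'
#' Refits standardization, feature selection (if any) and the classifier at
#' the selected grid point on all supplied rows, producing a deterministic
#' scorer for held-out cases.
#'
#' @param features Training features (as in [repeated_cv()]).
#' @param labels Binary outcomes.
#' @param spec A [classifier_spec()].
#' @param grid_point A grid row, e.g. from [select_hyperparameters()].
#' @param vendor Optional vendor vector.
#' @param standardize Refit standardization on the training rows (default
#'   `TRUE`).
#' @return An object of class `fitted_model`; `predict()` returns a
#'   real-valued score per case.
#' @export
fit_final <- function(features, labels, spec, grid_point,
                      vendor = NULL, standardize = TRUE) {
  x <- features_matrix(features)
  labels <- as.integer(labels > 0)
  if (!grid_point$grid_id %in% spec$grid$grid_id) {
    abort("selected grid point is not in the spec's grid.",
          class = "splitbias_config_error")
  }
  st <- NULL
  if (standardize) {
    st <- std_fit_m(x, vendor)
    x <- std_apply_m(x, vendor, st)
  }
  keep <- colnames(x)
  if (!is.null(spec$fs_k)) {
    keep <- univariate_feature_selection(x, labels, spec$fs_k)
    x <- x[, keep, drop = FALSE]
  }
  model <- if (spec$family == "logistic_regression") {
    lam <- sort(unique(spec$grid$lambda), decreasing = TRUE)
    fit <- glmnet::glmnet(ensure_two_cols(x), labels, family = "binomial",
                          alpha = 0, lambda = lam, standardize = FALSE)
    list(glmnet = fit, lambda = grid_point$lambda)
  } else {
    svm_smo_fit(x, labels, C = grid_point$C, kernel = grid_point$kernel,
                gamma = grid_point$gamma)
  }
  structure(list(family = spec$family, grid_point = grid_point,
                 std_stats = st, selected = keep, model = model,
                 n_train = nrow(x)),
            class = "fitted_model")
}

#' @rdname fit_final
#' @param object A `fitted_model`.
#' @param newdata Features of the cases to score.
#' @param vendor Vendor vector aligned with `newdata` (required when the
#'   model was fit with per-vendor standardization).
#' @param ... Unused.
#' @export
predict.fitted_model <- function(object, newdata, vendor = NULL, ...) {
  x <- features_matrix(newdata)
  if (!is.null(object$std_stats)) {
    x <- std_apply_m(x, vendor, object$std_stats)
  }
  x <- x[, object$selected, drop = FALSE]
  if (object$family == "logistic_regression") {
    drop(predict(object$model$glmnet, ensure_two_cols(x),
                 s = object$model$lambda, type = "link"))
  } else {
    predict(object$model, x)
  }
}

#' @rdname fit_final
#' @param x A `fitted_model`.
#' @export
tidy.fitted_model <- function(x, ...) {
  if (x$family == "logistic_regression") {
    co <- as.matrix(stats::coef(x$model$glmnet, s = x$model$lambda))
    tb <- tibble::tibble(term = rownames(co), estimate = co[, 1])
    tb[tb$term != ".dummy", ]
  } else {
    tibble::tibble(term = c("n_support_vectors", "intercept"),
                   estimate = c(length(x$model$sv_coef), x$model$b))
  }
}

#' @rdname fit_final
#' @export
glance.fitted_model <- function(x, ...) {
  gp <- x$grid_point
  tibble::tibble(family = x$family,
                 hyperparameters = format_grid_point(x$family, gp),
                 n_features = length(x$selected),
                 n_train = x$n_train)
}

format_grid_point <- function(family, gp) {
  if (family == "logistic_regression") {
    sprintf("lambda=%g", gp$lambda)
  } else {
    sprintf("kernel=%s,C=%g,gamma=%s", gp$kernel, gp$C,
            if (is.na(gp$gamma)) "scale" else format(gp$gamma))
  }
}
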