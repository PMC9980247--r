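# The two headline experiments: the repeated shuffle-split study (train vs
# test AUC tradeoff) and the incremental-cohort learning curve.

#' Repeated shuffle-split experiment
#'
#' For each of `n_splits` stratified shuffle-splits of the cohort: run
#' [repeated_cv()] on the training rows for every requested model type and
#' classifier family, select the modal hyperparameters, refit once on the
#' whole training set, and score the held-out test set — yielding one
#' (train AUC, test AUC) pair per split, together with the split's
#' covariate balance report. Train AUC is the mean validation AUC at
#' per-repeat winners ([training_auc_summary()]); test AUC is the
#' Mann–Whitney AUC of the final model's scores on the test rows.
#'
#' Per-split seeds derive deterministically from `seed`, so any single
#' split can be re-run in isolation and match the full run.
#'
#' @param cohort A `cohort` tibble.
#' @param n_splits Number of shuffle-splits (study default 50).
#' @param train_size Training-set size per split (study default 400).
#' @param model_types Subset of `"clinical"`, `"radiomics"`,
#'   `"radiomics_fs"`, `"combined"`.
#' @param families Subset of `"logistic_regression"`, `"svm"`.
#' @param protocol A [cv_protocol()]; use low `repeats` for a fast profile.
#' @param fs_k Features kept inside folds for the `radiomics_fs` model.
#' @param balance_alpha Significance level for covariate balance flags.
#' @param balance_covariates Covariates monitored per split.
#' @param standardize_scope `"train"` (fit standardization on training
#'   rows/folds only; methodologically leak-free, the default) or `"all"`
#' (one global standardization of the whole cohort before splitting).
#' @param grids Optional named list of grid overrides per family.
#' @param seed Master seed.
#' @return An object of class `split_experiment` with `$splits` (one row
#'   per split x model x family) and `$tradeoff` (one [tradeoff_statistics()]
#'   row per model x family). `tidy()` returns `$splits`, `glance()`
#'   returns `$tradeoff`.
#' @export
run_split_experiment <- function(cohort,
                                 n_splits = 50,
                                 train_size = 400,
                                 model_types = "radiomics",
                                 families = "logistic_regression",
                                 protocol = cv_protocol(),
                                 fs_k = 20,
                                 balance_alpha = 0.05,
                                 balance_covariates = c("age", "lesion_size"),
                                 standardize_scope = c("train", "all"),
                                 grids = NULL,
                                 seed = 1) {
  validate_cohort(cohort)
  standardize_scope <- rlang::arg_match(standardize_scope)
  model_types <- match.arg(model_types, MODEL_TYPES, several.ok = TRUE)
  families <- match.arg(families, c("logistic_regression", "svm"),
                        several.ok = TRUE)
  work_cohort <- cohort
  per_fold_std <- standardize_scope == "train"
  if (!per_fold_std) {
    stats <- fit_standardization(cohort)
    work_cohort <- apply_standardization(cohort, stats)
  }
  specs <- purrr::map(rlang::set_names(families), function(fam) {
    classifier_spec(fam, grid = grids[[fam]])
  })
  rows <- list()
  for (s in seq_len(n_splits)) {
    split_seed <- derive_seed(seed, s)
    split <- shuffle_split(cohort, train_size, split_seed)
    balance <- covariate_balance(cohort, split,
                                 covariates = balance_covariates,
                                 alpha = balance_alpha)
    tr_idx <- match(split$train_ids, work_cohort$case_id)
    te_idx <- match(split$test_ids, work_cohort$case_id)
    y_tr <- work_cohort$label[tr_idx]
    y_te <- work_cohort$label[te_idx]
    combo <- 0L
    for (mt in model_types) {
      feats <- assemble_features(work_cohort, mt)
      for (fam in families) {
        combo <- combo + 1L
        spec <- specs[[fam]]
        if (mt == "radiomics_fs") spec$fs_k <- fs_k
        vend_tr <- if (per_fold_std) work_cohort$vendor[tr_idx] else NULL
        vend_te <- if (per_fold_std) work_cohort$vendor[te_idx] else NULL
        res <- tryCatch({
          proto <- cv_protocol(protocol$k, protocol$repeats,
                               derive_seed(split_seed, combo))
          rec <- repeated_cv(feats[tr_idx, ], y_tr, spec, proto,
                             vendor = vend_tr, standardize = per_fold_std)
          gp <- select_hyperparameters(rec)
          fm <- fit_final(feats[tr_idx, ], y_tr, spec, gp,
                          vendor = vend_tr, standardize = per_fold_std)
          test_scores <- predict(fm, feats[te_idx, ], vendor = vend_te)
          tibble::tibble(
            split = s, seed = split_seed, model_type = mt, family = fam,
            train_auc = training_auc_summary(rec),
            test_auc = auc_mann_whitney(test_scores, y_te),
            hyperparameters = format_grid_point(fam, gp),
            p_age = balance$p_value[balance$covariate == "age"][1],
            p_lesion_size = balance$p_value[balance$covariate == "lesion_size"][1],
            balance_flag = any(balance$flag))
        }, error = function(e) {
          warn(sprintf("split %d / %s / %s failed: %s", s, mt, fam,
                       conditionMessage(e)))
          NULL
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  splits <- dplyr::bind_rows(rows)
  tradeoff <- splits |>
    dplyr::group_by(.data$model_type, .data$family) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) >= 2) {
        tradeoff_statistics(d)
      } else {
        tibble::tibble(n_points = nrow(d), pearson_r = NA_real_,
                       spearman_rho = NA_real_, sd_diagonal = NA_real_,
                       sd_antidiagonal = NA_real_, anisotropy = NA_real_,
                       degenerate = TRUE)
      }
    }) |>
    dplyr::ungroup()
  structure(list(splits = splits, tradeoff = tradeoff,
                 config = list(n_splits = n_splits, train_size = train_size,
                               model_types = model_types, families = families,
                               protocol = protocol, fs_k = fs_k,
                               balance_alpha = balance_alpha,
                               standardize_scope = standardize_scope,
                               seed = seed)),
            class = "split_experiment")
}

#' @exportS3Method base::print
print.split_experiment <- function(x, ...) {
  cat(sprintf("<split_experiment> %d splits x %s x %s\n",
              x$config$n_splits,
              paste(x$config$model_types, collapse = "/"),
              paste(x$config$families, collapse = "/")))
  print(x$tradeoff)
  invisible(x)
}

#' @rdname run_split_experiment
#' @param x A `split_experiment`.
#' @param ... Unused.
#' @export
tidy.split_experiment <- function(x, ...) x$splits

#' @rdname run_split_experiment
#' @export
glance.split_experiment <- function(x, ...) x$tradeoff

#' Incremental-cohort learning curve
#'
#' Builds [nested_cohorts()] chains, then for every chain x size runs
#' [repeated_cv()] on that subset; the cross-validated AUC of the subset is
#' the mean validation AUC at per-repeat winners. Per-size boxplot
#' summaries and the [convergence_size()] diagnostic quantify how the CV
#' estimate tightens and stabilizes as cases accumulate.
#'
#' @param cohort A `cohort` tibble.
#' @param sizes Increasing cohort sizes (default: steps of 100 up to the
#'   full cohort).
#' @param n_chains Number of independent nested chains (study default 20).
#' @param model_type Feature set to use (study: `"radiomics"`).
#' @param family Classifier family (study: logistic regression).
#' @param protocol A [cv_protocol()]; the repeat count for this experiment
#'   defaults to 20.
#' @param fs_k As in [run_split_experiment()].
#' @param grid Optional grid override for the family.
#' @param standardize_scope As in [run_split_experiment()].
#' @param tol_multiplier IQR multiplier for [convergence_size()].
#' @param seed Master seed.
#' @return An object of class `learning_curve` with `$curve` (chain x size
#'   CV AUCs), `$summary` (per-size [boxplot_summary()] rows) and
#'   `$convergence_size`.
#' @export
run_learning_curve <- function(cohort,
                               sizes = NULL,
                               n_chains = 20,
                               model_type = "radiomics",
                               family = "logistic_regression",
                               protocol = cv_protocol(repeats = 20),
                               fs_k = 20,
                               grid = NULL,
                               standardize_scope = c("train", "all"),
                               tol_multiplier = 1,
                               seed = 1) {
  validate_cohort(cohort)
  standardize_scope <- rlang::arg_match(standardize_scope)
  model_type <- match.arg(model_type, MODEL_TYPES)
  per_fold_std <- standardize_scope == "train"
  work_cohort <- cohort
  if (!per_fold_std) {
    work_cohort <- apply_standardization(cohort, fit_standardization(cohort))
  }
  spec <- classifier_spec(family, grid = grid)
  if (model_type == "radiomics_fs") spec$fs_k <- fs_k
  chains <- nested_cohorts(cohort, sizes = sizes, n_chains = n_chains,
                           seed = derive_seed(seed, 0))
  feats <- assemble_features(work_cohort, model_type)
  rows <- purrr::map_dfr(chains, function(chain) {
    purrr::map2_dfr(chain$sizes, chain$member_ids, function(sz, ids) {
      idx <- match(ids, work_cohort$case_id)
      proto <- cv_protocol(protocol$k, protocol$repeats,
                           derive_seed(seed, chain$chain_id * 10000 + sz))
      rec <- repeated_cv(feats[idx, ], work_cohort$label[idx], spec, proto,
                         vendor = if (per_fold_std) work_cohort$vendor[idx],
                         standardize = per_fold_std)
      tibble::tibble(chain = chain$chain_id, size = sz,
                     cv_auc = training_auc_summary(rec))
    })
  })
  summary <- rows |>
    dplyr::group_by(.data$size) |>
    dplyr::group_modify(function(d, key) {
      bs <- boxplot_summary(d$cv_auc, size = key$size)
      bs$size <- NULL
      bs$sd <- sd(d$cv_auc)
      bs
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$size)
  conv <- convergence_size(summary, tol_multiplier = tol_multiplier)
  structure(list(curve = rows, summary = summary, convergence_size = conv,
                 config = list(sizes = unique(rows$size), n_chains = n_chains,
                               model_type = model_type, family = family,
                               protocol = protocol, fs_k = fs_k,
                               standardize_scope = standardize_scope,
                               tol_multiplier = tol_multiplier, seed = seed)),
            class = "learning_curve")
}

#' @exportS3Method base::print
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %d chains, sizes %s; convergence at %s cases\n",
              x$config$n_chains, paste(range(x$summary$size), collapse = "-"),
              ifelse(is.na(x$convergence_size), "NA", x$convergence_size)))
  print(x$summary)
  invisible(x)
}

#' @rdname run_learning_curve
#' @param x A `learning_curve`.
#' @param ... Unused.
#' @export
tidy.learning_curve <- function(x, ...) x$curve

#' @rdname run_learning_curve
#' @export
glance.learning_curve <- function(x, ...) {
  dplyr::mutate(x$summary, convergence_size = x$convergence_size)
}
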