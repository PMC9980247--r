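# Cohort CSV dialect, per-vendor standardization with leakage control, and
# feature-matrix assembly for the four model types.

COHORT_REQUIRED <- c("case_id", "vendor", "label", "age", "er", "pr", "grade")
CLINICAL_COLS <- c("age", "er", "pr", "grade")
VALID_VENDORS <- c("A", "B")
MODEL_TYPES <- c("clinical", "radiomics", "radiomics_fs", "combined")

radiomic_cols <- function(cohort) {
  grep("^f[0-9]{3,}$", names(cohort), value = TRUE)
}

feature_cols <- function(cohort) c(CLINICAL_COLS, radiomic_cols(cohort))

# Alias used by covariate monitoring: radiomic column 1 is lesion size.
resolve_covariate <- function(cohort, covariate) {
  if (covariate == "lesion_size" && !"lesion_size" %in% names(cohort)) {
    rc <- radiomic_cols(cohort)
    if (length(rc) == 0) {
      abort("cohort has no radiomic columns to stand in for lesion_size.",
            class = "splitbias_format_error")
    }
    return(rc[1])
  }
  if (!covariate %in% names(cohort)) {
    abort(sprintf("covariate `%s` not found in cohort.", covariate),
          class = "splitbias_format_error")
  }
  covariate
}

validate_cohort <- function(cohort, source = "cohort") {
  missing <- setdiff(COHORT_REQUIRED, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  source, paste(missing, collapse = ", ")),
          class = "splitbias_format_error")
  }
  bad <- which(!cohort$label %in% c(0, 1))
  if (length(bad) > 0) {
    abort(sprintf("%s column `label` has non-binary value %s on row %d.",
                  source, format(cohort$label[bad[1]]), bad[1]),
          class = "splitbias_format_error")
  }
  bad <- which(!cohort$vendor %in% VALID_VENDORS)
  if (length(bad) > 0) {
    abort(sprintf("%s column `vendor` has unknown value '%s' on row %d (expected %s).",
                  source, cohort$vendor[bad[1]], bad[1],
                  paste(VALID_VENDORS, collapse = "/")),
          class = "splitbias_format_error")
  }
  if (anyDuplicated(cohort$case_id)) {
    abort(sprintf("%s column `case_id` contains duplicated ids.", source),
          class = "splitbias_format_error")
  }
  rc <- radiomic_cols(cohort)
  num_cols <- c(CLINICAL_COLS, rc)
  for (cl in num_cols) {
    v <- cohort[[cl]]
    if (!is.numeric(v)) {
      abort(sprintf("%s column `%s` must be numeric.", source, cl),
            class = "splitbias_format_error")
    }
    if (anyNA(v)) {
      abort(sprintf("%s column `%s` has a missing value on row %d.",
                    source, cl, which(is.na(v))[1]),
            class = "splitbias_format_error")
    }
  }
  invisible(cohort)
}

#' Read a cohort from CSV
#'
#' Expects the package's cohort dialect: comma-separated, header row, columns
#' `case_id, vendor, label, age, er, pr, grade` followed by radiomic columns
#' `f001...fNNN`. Validation errors name the offending column and row.
#'
#' @param path Path to a cohort CSV.
#' @return A `cohort` tibble.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              case_id = readr::col_character(),
                              vendor = readr::col_character(),
                              .default = readr::col_double()))
  cohort$label <- as.integer(cohort$label)
  validate_cohort(cohort, source = sprintf("'%s'", path))
  class(cohort) <- c("cohort", class(cohort))
  cohort
}

#' Write a cohort to CSV
#'
#' Round-trips through [read_cohort()] with values preserved to at least
#' 12 significant digits.
#'
#' @param cohort A `cohort` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(tibble::as_tibble(as.data.frame(cohort)), path)
  invisible(path)
}

#' Fit per-vendor standardization statistics
#'
#' Computes, for each vendor present among `row_ids` and each feature
#' column, the mean and population (denominator n) standard deviation over
#' exactly those rows — the fit set, typically the training rows, so no
#' information leaks from held-out cases. Columns with SD below `1e-12` are
#' flagged and later only centered.
#'
#' @param cohort A `cohort` tibble.
#' @param row_ids Case ids to fit on; defaults to all.
#' @param columns Feature columns; defaults to all clinical + radiomic.
#' @return A tibble of class `standardization_stats` with columns
#'   `vendor, column, mean, sd, zero_sd`, and the fit ids in
#'   `attr(, "fit_row_ids")`.
#' @export
fit_standardization <- function(cohort, row_ids = cohort$case_id,
                                columns = feature_cols(cohort)) {
  rows <- cohort[match(row_ids, cohort$case_id), , drop = FALSE]
  if (anyNA(rows$case_id)) {
    abort("row_ids contains ids not present in the cohort.",
          class = "splitbias_format_error")
  }
  counts <- table(rows$vendor)
  if (any(counts < 2)) {
    abort("each vendor present in the fit rows needs at least 2 cases.",
          class = "splitbias_format_error")
  }
  stats <- purrr::map_dfr(split(rows, rows$vendor), function(vr) {
    x <- as.matrix(vr[, columns, drop = FALSE])
    mu <- colMeans(x)
    sdv <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population convention
    tibble::tibble(vendor = vr$vendor[1], column = columns,
                   mean = unname(mu), sd = unname(sdv),
                   zero_sd = sdv < 1e-12)
  })
  attr(stats, "fit_row_ids") <- row_ids
  class(stats) <- c("standardization_stats", class(stats))
  stats
}

#' Apply per-vendor standardization
#'
#' Transforms every row of `cohort` (including rows outside the fit set)
#' using its vendor's fitted statistics: `(x - mean) / sd`, or `x - mean`
#' for flagged zero-SD columns. A vendor present at apply time but absent at
#' fit time raises a leakage error rather than silently refitting.
#'
#' @param cohort A `cohort` tibble.
#' @param stats A [fit_standardization()] result.
#' @return The standardized cohort.
#' @export
apply_standardization <- function(cohort, stats) {
  vendors <- unique(cohort$vendor)
  missing_v <- setdiff(vendors, unique(stats$vendor))
  if (length(missing_v) > 0) {
    abort(sprintf("vendor '%s' present at apply time but absent at fit time; refusing to leak.",
                  missing_v[1]),
          class = "splitbias_leakage_error")
  }
  columns <- unique(stats$column)
  out <- cohort
  out[columns] <- lapply(out[columns], as.numeric)
  for (v in vendors) {
    idx <- which(cohort$vendor == v)
    st <- stats[stats$vendor == v, ]
    st <- st[match(columns, st$column), ]
    x <- as.matrix(cohort[idx, columns, drop = FALSE])
    x <- sweep(x, 2, st$mean)
    div <- ifelse(st$zero_sd, 1, st$sd)
    x <- sweep(x, 2, div, `/`)
    out[idx, columns] <- tibble::as_tibble(x)
  }
  out
}

#' Assemble the feature table for one model type
#'
#' The four model types mirror the study design: `clinical` (age, ER, PR,
#' grade), `radiomics` (all radiomic columns), `radiomics_fs` (all radiomic
#' columns — feature selection happens *inside* CV folds, see
#' [repeated_cv()]), and `combined` (clinical + radiomic).
#'
#' @param cohort A `cohort` tibble.
#' @param model_type One of `"clinical"`, `"radiomics"`, `"radiomics_fs"`,
#'   `"combined"`.
#' @return A tibble with `case_id` plus the selected feature columns;
#'   `attr(, "model_type")` records the choice.
#' @export
assemble_features <- function(cohort, model_type = MODEL_TYPES) {
  model_type <- rlang::arg_match(model_type, MODEL_TYPES)
  cols <- switch(model_type,
                 clinical = CLINICAL_COLS,
                 radiomics = radiomic_cols(cohort),
                 radiomics_fs = radiomic_cols(cohort),
                 combined = c(CLINICAL_COLS, radiomic_cols(cohort)))
  out <- cohort[, c("case_id", cols), drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(out))
  attr(out, "model_type") <- model_type
  out
}
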