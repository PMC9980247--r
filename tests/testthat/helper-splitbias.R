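# Shared fixtures: small cohorts built in code.

small_config <- function(n_cases = 160, n_positive = 40, n_radiomic = 12,
                         n_informative = 4, target = 0.80, seed = 42, ...) {
  generator_config(n_cases = n_cases, n_positive = n_positive,
                   n_radiomic = n_radiomic, n_informative = n_informative,
                   mahalanobis_delta = calibrate_separation(target),
                   seed = seed, ...)
}

small_cohort <- function(...) generate_cohort(small_config(...))

# a 3-row handcrafted cohort CSV (the io dialect)
handmade_cohort_csv <- function(path) {
  writeLines(c(
    "case_id,vendor,label,age,er,pr,grade,f001,f002",
    "c1,A,0,55.5,1,1,2,0.1,-0.4",
    "c2,B,1,62.0,0,1,3,1.2,0.9",
    "c3,A,0,48.2,1,0,1,-0.3,0.2"), path)
  path
}

# brute-force pairwise AUC oracle (ties count 1/2), independent of ranks
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

lr_spec_small <- function() {
  classifier_spec("logistic_regression",
                  grid = tibble::tibble(lambda = c(0.01, 1)))
}
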