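# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom stats pnorm qnorm plogis qlogis rnorm runif rbinom pt cor sd
#'   quantile median var predict
NULL

# Evaluate `expr` under a temporary RNG state; the caller's stream is restored
# afterwards so library code never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a unit index
#'
#' Deterministic Lehmer-style mixing so that any single split, repeat or chain
#' can be re-run in isolation and match the full run. Stays below 2^31.
#'
#' @param master integer master seed.
#' @param index nonnegative integer unit index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- ((as.numeric(master) %% m) * 48271 + as.numeric(index) * 8191 + 1) %% m
  s <- (s * 48271) %% m
  as.integer(if (s == 0) 1 else s)
}

# Half-up rounding used for all stratified counts (round(3.5) == 4).
round_half_up <- function(x) floor(x + 0.5)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "splitbias_config_error")
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %s violates the required range %s%s, %s%s.",
                  name, format(x),
                  if (allow_lower) "[" else "(", format(lower),
                  format(upper), if (allow_upper) "]" else ")"),
          class = "splitbias_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != round_half_up(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "splitbias_config_error")
  }
  invisible(as.integer(x))
}
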