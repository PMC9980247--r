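# Minimal C-SVM via sequential minimal optimization (SMO) with maximal
# violating pair working-set selection. Written in-package because no SVM
# library is available in the target environment; deliberately small:
# binary classification, linear and RBF kernels, dense inputs of at most a
# few hundred rows — the regime of the fold-level fits here.

svm_kernel_matrix <- function(x, z, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(x, z))
  # rbf: exp(-gamma * ||x - z||^2)
  d2 <- outer(rowSums(x^2), rowSums(z^2), `+`) - 2 * tcrossprod(x, z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# gamma = 1 / (p * mean feature variance), the usual "scale" heuristic.
svm_scale_gamma <- function(x) {
  v <- mean(apply(x, 2, var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

#' Fit a C-SVM by SMO
#'
#' Solves the soft-margin dual (minimize `1/2 a'Qa - e'a` subject to
#' `y'a = 0`, `0 <= a <= C`, with `Q = yy' * K`) by maximal-violating-pair
#' SMO to KKT tolerance `tol`. Deterministic: no randomness is involved.
#'
#' @param x Numeric matrix (rows = cases).
#' @param y Binary labels (0/1 or -1/+1).
#' @param C Regularization parameter (> 0).
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma RBF kernel coefficient; `NULL`/`NA` uses the scale
#'   heuristic `1 / (ncol(x) * mean(var))`.
#' @param tol KKT violation tolerance.
#' @param max_iter Iteration cap; hitting it marks the fit non-converged.
#' @return An object of class `svm_fit` with a [predict()] method returning
#'   decision values.
#' @keywords internal
#' @export
svm_smo_fit <- function(x, y, C = 1, kernel = c("linear", "rbf"),
                        gamma = NULL, tol = 1e-3, max_iter = 20000L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- ifelse(y > 0, 1, -1)
  n <- nrow(x)
  if (length(unique(y)) < 2) {
    abort("svm_smo_fit needs both classes present.",
          class = "splitbias_fit_error")
  }
  if (kernel == "rbf" && (is.null(gamma) || is.na(gamma))) {
    gamma <- svm_scale_gamma(x)
  }
  K <- svm_kernel_matrix(x, x, kernel, gamma)
  alpha <- numeric(n)
  grad <- rep(-1, n)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) break
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == 1 & alpha > 1e-12) | (y == -1 & alpha < C - 1e-12)
    yg <- -y * grad
    if (!any(up) || !any(lo)) { converged <- TRUE; break }
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < tol) { converged <- TRUE; break }
    ai <- alpha[i]; aj <- alpha[j]
    if (y[i] != y[j]) {
      quad <- K[i, i] + K[j, j] + 2 * K[i, j]
      if (quad <= 1e-12) quad <- 1e-12
      delta <- (-grad[i] - grad[j]) / quad
      diff <- ai - aj
      alpha[i] <- ai + delta
      alpha[j] <- aj + delta
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diff }
        if (alpha[i] > C) { alpha[i] <- C; alpha[j] <- C - diff }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diff }
        if (alpha[j] > C) { alpha[j] <- C; alpha[i] <- C + diff }
      }
    } else {
      quad <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (quad <= 1e-12) quad <- 1e-12
      delta <- (grad[i] - grad[j]) / quad
      s <- ai + aj
      alpha[i] <- ai - delta
      alpha[j] <- aj + delta
      if (s > C) {
        if (alpha[i] > C) { alpha[i] <- C; alpha[j] <- s - C }
        if (alpha[j] > C) { alpha[j] <- C; alpha[i] <- s - C }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- s }
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- s }
      }
    }
    dai <- alpha[i] - ai
    daj <- alpha[j] - aj
    grad <- grad + (y * K[, i]) * (y[i] * dai) + (y * K[, j]) * (y[j] * daj)
  }
  # decision values on training rows: f_t = sum_s alpha_s y_s K(s, t)
  f <- drop(K %*% (alpha * y))
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) {
    mean(y[free] - f[free])
  } else {
    yg <- y - f
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == 1 & alpha > 1e-12) | (y == -1 & alpha < C - 1e-12)
    vals <- c(if (any(up)) min(yg[up]) else NA, if (any(lo)) max(yg[lo]) else NA)
    mean(vals, na.rm = TRUE)
  }
  sv <- alpha > 1e-8
  structure(list(sv_x = x[sv, , drop = FALSE],
                 sv_coef = (alpha * y)[sv],
                 b = b, kernel = kernel, gamma = gamma, C = C,
                 converged = converged, iterations = min(it, max_iter)),
            class = "svm_fit")
}

#' @rdname svm_smo_fit
#' @param object An `svm_fit`.
#' @param newdata Numeric matrix of cases to score.
#' @param ... Unused.
#' @export
predict.svm_fit <- function(object, newdata, ...) {
  K <- svm_kernel_matrix(as.matrix(newdata), object$sv_x, object$kernel,
                         object$gamma)
  drop(K %*% object$sv_coef) + object$b
}
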