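## Static and kernel-based dynamic correlation, plus the vectorization of
## symmetric correlation matrices used throughout the package.
##
## A "corr_series" is a T x ((K^2-K)/2 + K) matrix: row t holds the
## upper triangle (including the diagonal, row-major order) of the
## symmetric K x K correlation matrix estimated at timepoint t.

VAR_FLOOR <- 1e-12

check_timeseries <- function(X, name = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(name, " must be a numeric matrix (timepoints x features)",
         call. = FALSE)
  if (!all(is.finite(X)))
    stop(name, " contains non-finite values", call. = FALSE)
  if (nrow(X) < 2L)
    stop(name, " must have at least 2 timepoints", call. = FALSE)
  invisible(X)
}

new_corr_series <- function(values, K, order = 1L, kernel = NULL,
                            mode = NULL) {
  structure(values, K = as.integer(K), order = as.integer(order),
            kernel = kernel, mode = mode,
            class = c("corr_series", class(values)))
}

#' @export
print.corr_series <- function(x, ...) {
  cat(sprintf("<corr_series: %d timepoints, K = %d (%d entries/timepoint)>\n",
              nrow(x), attr(x, "K"), ncol(x)))
  if (!is.null(attr(x, "kernel")))
    cat("  kernel:", format(attr(x, "kernel")), " mode:",
        attr(x, "mode"), "\n")
  invisible(x)
}

#' Static Pearson correlation of a multivariate timeseries
#'
#' Plain column-wise Pearson correlation; the limiting case of the
#' dynamic estimator under a uniform (infinitely wide) kernel.
#'
#' @param X Numeric `T x K` matrix (timepoints by features).
#' @return Symmetric `K x K` correlation matrix with unit diagonal.
#' @export
static_corr <- function(X) {
  check_timeseries(X)
  v <- apply(X, 2L, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)[1L]
    nm <- colnames(X)[bad]
    stop("column ", if (!is.null(nm)) paste0("'", nm, "' (", bad, ")") else bad,
         " has zero variance; correlation is undefined", call. = FALSE)
  }
  stats::cor(X)
}

#' Vectorize / devectorize a symmetric correlation matrix
#'
#' `vectorize_corr` extracts the upper triangle and diagonal of a
#' symmetric `K x K` matrix into a length-`(K^2-K)/2 + K` vector in
#' row-major order: (1,1), (1,2), ..., (1,K), (2,2), ..., (K,K).
#' `devectorize_corr` is its exact inverse.
#'
#' @param S Symmetric numeric matrix (within `tol`).
#' @param tol Symmetry tolerance.
#' @return For `vectorize_corr`, a numeric vector; for
#'   `devectorize_corr`, a symmetric matrix.
#' @examples
#' vectorize_corr(diag(2))  # c(1, 0, 1)
#' @export
vectorize_corr <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("S must be a square matrix", call. = FALSE)
  if (max(abs(S - t(S))) > tol)
    stop("S is not symmetric within tolerance ", tol, call. = FALSE)
  ## row-major upper triangle of a symmetric matrix == column-major lower
  S[lower.tri(S, diag = TRUE)]
}

#' @rdname vectorize_corr
#' @param v Numeric vector of length `(K^2-K)/2 + K` for some integer `K`.
#' @export
devectorize_corr <- function(v) {
  L <- length(v)
  K <- (sqrt(8 * L + 1) - 1) / 2
  if (abs(K - round(K)) > 1e-9)
    stop("length ", L, " is not (K^2-K)/2 + K for any integer K",
         call. = FALSE)
  K <- as.integer(round(K))
  S <- matrix(0, K, K)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

## index of the vectorized entries within the full K x K matrix
vec_index <- function(K) which(lower.tri(diag(K), diag = TRUE))

## logical mask over the vectorized entries marking off-diagonal pairs
vec_offdiag <- function(K) {
  ij <- which(lower.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  ij[, 1L] != ij[, 2L]
}

#' Kernel-based dynamic correlation
#'
#' Estimates the instantaneous `K x K` correlation matrix at every
#' timepoint of `X` and returns the vectorized stream (one row per
#' timepoint, see [vectorize_corr()] for the ordering).
#'
#' At timepoint `t` the estimator centres the data on the kernel-weighted
#' mean \eqn{\tilde X_t = \sum_\tau \kappa_t(\tau) X(\tau,\cdot)}. Two
#' variants of the remaining sums are provided:
#'
#' \describe{
#'   \item{`as_printed`}{The cross-product and squared-deviation sums run
#'     unweighted over all timepoints; only the centring is
#'     kernel-weighted. This form is well defined for the exact Dirac
#'     delta kernel and is the package default.}
#'   \item{`fully_weighted`}{The kernel weights also enter the
#'     cross-product and variance sums (conventional weighted Pearson).
#'     Undefined for the exact Dirac delta (zero weighted variance) and
#'     for the Mexican hat (weights of mixed sign can give negative
#'     variances); both raise errors.}
#' }
#'
#' Both variants reduce exactly to the static Pearson correlation under
#' the uniform kernel, and both are bounded in `[-1, 1]` whenever the
#' weights are non-negative (Cauchy-Schwarz).
#'
#' @param X Numeric `T x K` matrix.
#' @param kernel A [kernel_spec()].
#' @param mode `"as_printed"` (default) or `"fully_weighted"`.
#' @return A `corr_series` (`T x ((K^2-K)/2 + K)` matrix).
#' @export
dynamic_corr <- function(X, kernel, mode = c("as_printed", "fully_weighted")) {
  mode <- match.arg(mode)
  check_timeseries(X)
  stopifnot(inherits(kernel, "kernel_spec"))
  K <- ncol(X)
  T <- nrow(X)
  idx <- vec_index(K)
  out <- matrix(NA_real_, T, length(idx))
  ## centring the columns is a no-op mathematically (the estimator is
  ## shift invariant) but avoids cancellation in the expanded sums
  X <- sweep(X, 2L, colMeans(X))

  if (mode == "as_printed") {
    W <- kernel_matrix(kernel, T)
    M <- W %*% X                       # row t = kernel-weighted mean at t
    S <- crossprod(X)
    s <- colSums(X)
    dS <- diag(S)
    for (t in seq_len(T)) {
      m <- M[t, ]
      num <- S - outer(m, s) - outer(s, m) + T * outer(m, m)
      v <- dS - 2 * m * s + T * m^2
      if (any(v < VAR_FLOOR))
        stop("effective variance below floor at timepoint ", t,
             " (feature ", which(v < VAR_FLOOR)[1L],
             "); is a column constant?", call. = FALSE)
      r <- num / sqrt(outer(v, v))
      out[t, ] <- r[idx]
    }
  } else {
    if (kernel$family == "dirac_delta")
      stop("fully_weighted mode is undefined for the dirac_delta kernel ",
           "(zero weighted variance); use mode = \"as_printed\" or a ",
           "wider kernel", call. = FALSE)
    W <- kernel_matrix(kernel, T)
    for (t in seq_len(T)) {
      w <- W[t, ]
      m <- drop(w %*% X)
      Xc <- sweep(X, 2L, m)
      num <- crossprod(Xc, w * Xc)
      v <- diag(num)
      if (any(v < VAR_FLOOR))
        stop("effective weighted variance below floor at timepoint ", t,
             if (kernel$family == "mexican_hat")
               "; mexican_hat is intended for mode = \"as_printed\"" else
               "; use mode = \"as_printed\" or a wider kernel",
             call. = FALSE)
      r <- num / sqrt(outer(v, v))
      out[t, ] <- r[idx]
    }
  }
  new_corr_series(out, K = K, kernel = kernel, mode = mode)
}

#' Kernel-based dynamic cross-correlation between two timeseries
#'
#' Applies the dynamic correlation estimator to every pair (column of
#' `A`, column of `B`). The output at each timepoint is a generally
#' non-symmetric `K_A x K_B` matrix; entry `(i, j)` is the instantaneous
#' correlation between `A[, i]` and `B[, j]`.
#'
#' @param A,B Numeric matrices sharing the number of rows `T`.
#' @inheritParams dynamic_corr
#' @return A list of `T` matrices (`K_A x K_B`).
#' @export
dynamic_xcorr <- function(A, B, kernel,
                          mode = c("as_printed", "fully_weighted")) {
  mode <- match.arg(mode)
  check_timeseries(A, "A"); check_timeseries(B, "B")
  if (nrow(A) != nrow(B))
    stop("A and B must share the number of timepoints", call. = FALSE)
  stopifnot(inherits(kernel, "kernel_spec"))
  T <- nrow(A)
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))

  if (mode == "as_printed") {
    W <- kernel_matrix(kernel, T)
    MA <- W %*% A; MB <- W %*% B
    S <- crossprod(A, B)
    dA <- colSums(A^2); dB <- colSums(B^2)
    sA <- colSums(A); sB <- colSums(B)
    lapply(seq_len(T), function(t) {
      ma <- MA[t, ]; mb <- MB[t, ]
      num <- S - outer(ma, sB) - outer(sA, mb) + T * outer(ma, mb)
      vA <- dA - 2 * ma * sA + T * ma^2
      vB <- dB - 2 * mb * sB + T * mb^2
      if (any(vA < VAR_FLOOR) || any(vB < VAR_FLOOR))
        stop("effective variance below floor at timepoint ", t, call. = FALSE)
      num / sqrt(outer(vA, vB))
    })
  } else {
    if (kernel$family == "dirac_delta")
      stop("fully_weighted mode is undefined for the dirac_delta kernel",
           call. = FALSE)
    W <- kernel_matrix(kernel, T)
    lapply(seq_len(T), function(t) {
      w <- W[t, ]
      ma <- drop(w %*% A); mb <- drop(w %*% B)
      Ac <- sweep(A, 2L, ma); Bc <- sweep(B, 2L, mb)
      num <- crossprod(Ac, w * Bc)
      vA <- colSums(w * Ac^2); vB <- colSums(w * Bc^2)
      if (any(vA < VAR_FLOOR) || any(vB < VAR_FLOOR))
        stop("effective weighted variance below floor at timepoint ", t,
             call. = FALSE)
      num / sqrt(outer(vA, vB))
    })
  }
}
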