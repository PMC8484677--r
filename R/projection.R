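## Low-dimensional projection of a correlation stream: a T x
## ((K^2-K)/2+K) stream of vectorized correlation matrices is mapped to a
## T x K feature matrix, either by PCA (invertible up to rank) or by
## per-timepoint eigenvector centrality (a graph measure).

#' Fit a PCA projection for correlation streams
#'
#' Fits a single linear embedding on the row-stacked streams so that all
#' participants or groups in an analysis share one `K`-dimensional
#' space. Columns are centred (not scaled); the top-`K` principal
#' component loadings are retained with a deterministic sign convention
#' (the largest-magnitude loading of each component is made positive).
#'
#' @param streams A `corr_series`/matrix or list of them, all with the
#'   same number of columns.
#' @param K Target dimensionality (positive integer, at most the stream
#'   width and the stacked row count). Components beyond the rank of the
#'   centred data are completed with an orthonormal null-space basis, so
#'   rank-deficient streams project to (near-)constant scores.
#' @return An object of class `"corr_projection"` with elements
#'   `method`, `center` and `loadings` (columns orthonormal).
#' @export
pca_fit <- function(streams, K) {
  if (!is.list(streams)) streams <- list(streams)
  mats <- lapply(streams, function(s) unclass(as.matrix(s)))
  nc <- vapply(mats, ncol, integer(1L))
  if (length(unique(nc)) != 1L)
    stop("all streams must share the number of columns", call. = FALSE)
  Y <- do.call(rbind, mats)
  K <- as.integer(K)
  if (K < 1L) stop("K must be positive", call. = FALSE)
  if (nrow(Y) < K)
    stop("need at least K stacked rows to fit a rank-", K, " projection",
         call. = FALSE)
  if (K > ncol(Y))
    stop("K = ", K, " exceeds the stream width (", ncol(Y), ")",
         call. = FALSE)
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr)
  sv <- svd(Yc, nu = 0L, nv = min(dim(Yc)))
  if (K > ncol(sv$v))
    stop("K = ", K, " exceeds the available dimensionality (",
         ncol(sv$v), ")", call. = FALSE)
  ## components beyond the data rank are an (orthonormal, deterministic)
  ## null-space basis from the svd; their scores are ~0, so
  ## rank-deficient streams (e.g. constant correlations) project cleanly
  V <- sv$v[, seq_len(K), drop = FALSE]
  ## deterministic signs: largest-|loading| entry of each component > 0
  for (j in seq_len(K)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(method = "pca", center = ctr, loadings = V),
            class = "corr_projection")
}

#' @export
print.corr_projection <- function(x, ...) {
  cat(sprintf("<corr_projection: pca, %d -> %d>\n",
              length(x$center), ncol(x$loadings)))
  invisible(x)
}

#' Apply a fitted PCA projection
#'
#' Projects a correlation stream onto the fitted component space,
#' producing `T x K` scores.
#'
#' @param spec A fitted `"corr_projection"` from [pca_fit()].
#' @param Y A `corr_series` or matrix with matching columns.
#' @return A numeric `T x K` matrix of scores.
#' @export
pca_apply <- function(spec, Y) {
  stopifnot(inherits(spec, "corr_projection"))
  Y <- unclass(as.matrix(Y))
  if (ncol(Y) != length(spec$center))
    stop("stream has ", ncol(Y), " columns but the projection was fitted ",
         "on ", length(spec$center), call. = FALSE)
  sweep(Y, 2L, spec$center) %*% spec$loadings
}

#' Per-timepoint eigenvector centrality of a correlation stream
#'
#' Devectorizes each row to a symmetric `K x K` matrix, takes elementwise
#' absolute values (eigenvector centrality requires non-negative edge
#' weights; by Perron-Frobenius the principal eigenvector of the
#' absolute-value matrix is non-negative), and returns the principal
#' eigenvector (unit Euclidean norm, oriented so its largest-magnitude
#' entry is positive). Alternatively, `weights = "shifted"` maps
#' correlations to `(1 + r)/2` instead of `|r|`.
#'
#' @param Y A `corr_series` or `T x ((K^2-K)/2+K)` matrix.
#' @param weights How signed correlations become non-negative edge
#'   weights: `"absolute"` (default) or `"shifted"`.
#' @return A `T x K` matrix with non-negative rows of unit norm.
#' @export
centrality_project <- function(Y, weights = c("absolute", "shifted")) {
  weights <- match.arg(weights)
  Y <- unclass(as.matrix(Y))
  K <- (sqrt(8 * ncol(Y) + 1) - 1) / 2
  if (abs(K - round(K)) > 1e-9)
    stop("column count is not (K^2-K)/2 + K for any K", call. = FALSE)
  K <- as.integer(round(K))
  out <- matrix(NA_real_, nrow(Y), K)
  for (t in seq_len(nrow(Y))) {
    S <- devectorize_corr(Y[t, ])
    A <- if (weights == "absolute") abs(S) else (1 + S) / 2
    e <- eigen(A, symmetric = TRUE)
    tied <- which(e$values > e$values[1L] -
                    1e-10 * max(1, abs(e$values[1L])))
    if (length(tied) > 1L) {
      ## tied dominant eigenvalues: deterministic resolution by
      ## projecting the all-ones vector onto the tied eigenspace
      B <- e$vectors[, tied, drop = FALSE]
      v <- drop(B %*% crossprod(B, rep(1, K)))
      if (sqrt(sum(v^2)) < 1e-8) v <- e$vectors[, 1L]
    } else {
      v <- e$vectors[, 1L]
    }
    v <- v / sqrt(sum(v^2))
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    out[t, ] <- v
  }
  out
}

## Plug-in surface for other graph measures: any function
## (symmetric K x K matrix) -> length-K vector can stand in for
## eigenvector centrality.
apply_graph_measure <- function(Y, measure) {
  Y <- unclass(as.matrix(Y))
  t(apply(Y, 1L, function(v) measure(devectorize_corr(v))))
}

#' Project a correlation stream to `T x K` features
#'
#' Dispatcher used by the higher-order recursion: `"pca"` fits (or
#' reuses) a linear embedding; `"eigenvector_centrality"` computes the
#' per-timepoint principal eigenvector of the absolute correlation
#' matrix.
#'
#' @inheritParams centrality_project
#' @param method `"pca"`, `"eigenvector_centrality"`, or a fitted
#'   `"corr_projection"` to reuse.
#' @param K Target dimensionality (defaults to the source `K`).
#' @return A list with `values` (`T x K`) and `projection` (the fitted
#'   spec for `"pca"`, otherwise the method name).
#' @export
project_corrs <- function(Y, method = "pca", K = NULL) {
  srcK <- attr(Y, "K")
  if (is.null(srcK)) srcK <- as.integer(round((sqrt(8 * ncol(Y) + 1) - 1) / 2))
  if (is.null(K)) K <- srcK
  if (inherits(method, "corr_projection")) {
    list(values = pca_apply(method, Y), projection = method)
  } else if (identical(method, "pca")) {
    spec <- pca_fit(Y, K)
    list(values = pca_apply(spec, Y), projection = spec)
  } else if (identical(method, "eigenvector_centrality")) {
    if (K != srcK)
      stop("eigenvector centrality always returns K = ", srcK, " columns",
           call. = FALSE)
    list(values = centrality_project(Y), projection = "eigenvector_centrality")
  } else {
    stop("unknown projection method", call. = FALSE)
  }
}
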