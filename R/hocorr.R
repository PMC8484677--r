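#' Estimate dynamic higher-order correlations
#'
#' `hocorr()` is the central fitting function of the package. Starting
#' from a `T x K` multivariate timeseries \eqn{X_0}, it alternates two
#' operations up to `max_order` times: (i) estimate the stream of
#' instantaneous correlation matrices \eqn{Y_{n+1}} between the columns
#' of \eqn{X_n} with a weighting kernel ([dynamic_corr()]), and (ii)
#' project that `T x ((K^2-K)/2+K)` stream back to a `T x K` feature
#' matrix \eqn{X_{n+1}} ([project_corrs()]). Because every order is
#' summarized by a `T x K` matrix, storing orders `0..n` takes
#' `(n+1) * T * K` values: space grows linearly in the order instead of
#' as \eqn{K^{2^n}}.
#'
#' With `decode_mode = TRUE`, all orders below `max_order` are estimated
#' with an exact Dirac delta kernel and only the final step uses
#' `kernel`. Repeated applications of a wide kernel compound temporal
#' blur, which penalizes higher orders in timepoint-resolved analyses
#' such as temporal decoding; restricting the blur to the last step puts
#' feature orders on an even temporal footing.
#'
#' @param x Numeric `T x K` matrix (timepoints by features), order 0.
#' @param max_order Highest correlation order to estimate (`>= 0`).
#' @param kernel Analysis kernel ([kernel_spec()]); default Laplace,
#'   width 20 samples.
#' @param mode Estimator variant passed to [dynamic_corr()].
#' @param projection `"pca"` (default) or `"eigenvector_centrality"`.
#' @param decode_mode Logical; see Details.
#' @param keep_corrs Keep the final order's vectorized correlation
#'   stream in the returned object (default `TRUE`).
#' @return An object of class `"hocorr"`: a list with `stack` (list of
#'   `T x K` matrices, orders `0..max_order`), `corrs` (the order-
#'   `max_order` `corr_series`, if kept), `projections` (fitted
#'   projection per step), `kernels` (kernel used per step), plus the
#'   call and configuration. Methods: [print.hocorr()],
#'   [summary.hocorr()], [coef.hocorr()], [plot.hocorr()].
#' @examples
#' X <- matrix(rnorm(60 * 4), 60)
#' fit <- hocorr(X, max_order = 2, kernel = gaussian_kernel(10))
#' fit
#' dim(coef(fit))        # 60 x 10: vectorized order-2 correlations
#' stack_storage(fit)    # 3 * 60 * 4 values
#' @export
hocorr <- function(x, max_order = 1L,
                   kernel = laplace_kernel(20),
                   mode = c("as_printed", "fully_weighted"),
                   projection = c("pca", "eigenvector_centrality"),
                   decode_mode = FALSE,
                   keep_corrs = TRUE) {
  mode <- match.arg(mode)
  projection <- match.arg(projection)
  check_timeseries(x)
  max_order <- as.integer(max_order)
  if (max_order < 0L) stop("max_order must be >= 0", call. = FALSE)

  stack <- list(`0` = unclass(x))   # order 0 passes through untouched
  projections <- list()
  kernels <- list()
  corrs <- NULL
  if (max_order > 0L) {
    for (n in seq_len(max_order)) {
      spec_n <- if (decode_mode && n < max_order) dirac_kernel() else kernel
      Y <- dynamic_corr(stack[[n]], spec_n, mode)
      pr <- project_corrs(Y, method = projection, K = ncol(x))
      stack[[as.character(n)]] <- pr$values
      projections[[n]] <- pr$projection
      kernels[[n]] <- spec_n
      if (n == max_order && keep_corrs) corrs <- Y
    }
  }
  structure(list(stack = stack, corrs = corrs, projections = projections,
                 kernels = kernels, max_order = max_order, mode = mode,
                 projection = projection, decode_mode = decode_mode,
                 kernel = kernel, call = match.call()),
            class = "hocorr")
}

#' One step of the higher-order recursion
#'
#' Maps an order-`n` feature matrix to order `n+1`:
#' `project(dynamic_corr(X))`. Exposed for composing custom pipelines;
#' [hocorr()] iterates this.
#'
#' @inheritParams hocorr
#' @param X Numeric `T x K` matrix (order-`n` features).
#' @param projection Projection method or a fitted `"corr_projection"`
#'   to reuse.
#' @return A list with `values` (the order-`n+1` `T x K` matrix),
#'   `corrs` (the intermediate `corr_series`) and `projection`.
#' @export
correlation_step <- function(X, kernel, mode = c("as_printed", "fully_weighted"),
                             projection = "pca") {
  mode <- match.arg(mode)
  Y <- dynamic_corr(X, kernel, mode)
  pr <- project_corrs(Y, method = projection, K = ncol(X))
  list(values = pr$values, corrs = Y, projection = pr$projection)
}

#' Values stored by an order stack
#'
#' Total count of numeric values held by the `T x K` matrices for orders
#' `0..max_order` — the package's linear-space contract:
#' `(max_order + 1) * T * K`.
#'
#' @param object A `"hocorr"` fit.
#' @return Integer count.
#' @export
stack_storage <- function(object) {
  stopifnot(inherits(object, "hocorr"))
  sum(vapply(object$stack, length, integer(1L)))
}

#' @export
print.hocorr <- function(x, ...) {
  T <- nrow(x$stack[[1L]]); K <- ncol(x$stack[[1L]])
  cat("Dynamic higher-order correlation fit\n")
  cat(sprintf("  data: %d timepoints x %d features\n", T, K))
  cat(sprintf("  orders: 0..%d   kernel: %s   mode: %s   projection: %s\n",
              x$max_order, format(x$kernel), x$mode, x$projection))
  if (x$decode_mode)
    cat("  decode mode: dirac_delta below the top order\n")
  invisible(x)
}

#' @export
#' @rdname print.hocorr
summary.hocorr <- function(object, ...) {
  T <- nrow(object$stack[[1L]]); K <- ncol(object$stack[[1L]])
  per_order <- t(vapply(object$stack, function(M)
    c(mean = mean(M), sd = stats::sd(M)), numeric(2L)))
  out <- list(T = T, K = K, max_order = object$max_order,
              kernel = format(object$kernel), mode = object$mode,
              projection = object$projection,
              storage = stack_storage(object),
              per_order = per_order)
  class(out) <- "summary.hocorr"
  out
}

#' @export
print.summary.hocorr <- function(x, ...) {
  cat("Dynamic higher-order correlation fit\n")
  cat(sprintf("  %d timepoints x %d features, orders 0..%d\n",
              x$T, x$K, x$max_order))
  cat(sprintf("  kernel %s, mode %s, projection %s\n",
              x$kernel, x$mode, x$projection))
  cat(sprintf("  stack storage: %d values ((n+1)*T*K = %d)\n",
              x$storage, (x$max_order + 1L) * x$T * x$K))
  cat("  per-order feature summaries:\n")
  print(round(x$per_order, 4))
  invisible(x)
}

#' Extract estimated correlations or order features
#'
#' `coef()` returns the vectorized correlation stream of the top order
#' (rows are timepoints; see [vectorize_corr()] for the entry order).
#' Use `order` to retrieve a lower order's `T x K` feature matrix from
#' the stack.
#'
#' @param object A `"hocorr"` fit.
#' @param order `NULL` (default: top-order correlation stream) or an
#'   order in `0..max_order` for the projected features.
#' @param ... Unused.
#' @export
coef.hocorr <- function(object, order = NULL, ...) {
  if (is.null(order)) {
    if (is.null(object$corrs))
      stop("correlation stream was not kept; refit with keep_corrs = TRUE",
           call. = FALSE)
    return(object$corrs)
  }
  order <- as.character(as.integer(order))
  if (is.null(object$stack[[order]]))
    stop("order ", order, " not present in the stack", call. = FALSE)
  object$stack[[order]]
}

#' Plot a higher-order correlation fit
#'
#' Draws the timecourses of the largest-variance off-diagonal
#' correlation pairs of the top order.
#'
#' @param x A `"hocorr"` fit (with `keep_corrs = TRUE`).
#' @param n_pairs Number of correlation pairs to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hocorr <- function(x, n_pairs = 5L, ...) {
  if (is.null(x$corrs))
    stop("correlation stream was not kept; refit with keep_corrs = TRUE",
         call. = FALSE)
  Y <- unclass(x$corrs)
  off <- vec_offdiag(attr(x$corrs, "K"))
  Y <- Y[, off, drop = FALSE]
  v <- apply(Y, 2L, stats::var)
  sel <- order(v, decreasing = TRUE)[seq_len(min(n_pairs, ncol(Y)))]
  graphics::matplot(Y[, sel, drop = FALSE], type = "l", lty = 1,
                    xlab = "timepoint", ylab = "correlation",
                    main = sprintf("order-%d dynamic correlations",
                                   x$max_order), ...)
  invisible(x)
}
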