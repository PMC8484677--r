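## Dynamic inter-subject functional connectivity (DISFC): correlations
## between each participant's features and the leave-one-out average of
## everyone else's, Fisher-z averaged across participants. Stimulus-driven
## structure survives the across-participant averaging; idiosyncratic
## structure does not.

CLIP <- 1 - 1e-10

#' Fisher z-transformation and its inverse
#'
#' `fisher_z` maps a correlation to `atanh(r) = (log(1+r) - log(1-r))/2`;
#' `inv_fisher_z` maps back via `tanh(z) = (exp(2z)-1)/(exp(2z)+1)`.
#' Correlations are clipped to `+/-(1 - 1e-10)` before transforming so
#' that exact `+/-1` values stay finite; the clip is applied identically
#' everywhere the transform is used in this package.
#'
#' @param r Numeric vector or matrix of correlations in `[-1, 1]`.
#' @return Transformed values of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)))
    stop("non-finite correlation passed to fisher_z", call. = FALSE)
  atanh(pmin(pmax(r, -CLIP), CLIP))
}

#' @rdname fisher_z
#' @param z Numeric vector or matrix of z-values.
#' @export
inv_fisher_z <- function(z) {
  if (any(!is.finite(z)))
    stop("non-finite value passed to inv_fisher_z", call. = FALSE)
  tanh(z)
}

#' Group of participants with matched timeseries
#'
#' Validates and wraps a list of `T x K` matrices (one per participant)
#' sharing dimensions exactly.
#'
#' @param members List of numeric `T x K` matrices.
#' @return The list, classed `"participant_group"`.
#' @export
participant_group <- function(members) {
  if (!is.list(members) || length(members) < 1L)
    stop("members must be a non-empty list of matrices", call. = FALSE)
  for (i in seq_along(members)) check_timeseries(members[[i]],
                                                 paste0("member ", i))
  d <- dim(members[[1L]])
  for (i in seq_along(members))
    if (!identical(dim(members[[i]]), d))
      stop("member ", i, " has dimensions ",
           paste(dim(members[[i]]), collapse = "x"),
           " but member 1 has ", paste(d, collapse = "x"), call. = FALSE)
  structure(members, class = "participant_group")
}

#' @export
print.participant_group <- function(x, ...) {
  cat(sprintf("<participant_group: P = %d, T = %d, K = %d>\n",
              length(x), nrow(x[[1L]]), ncol(x[[1L]])))
  invisible(x)
}

as_group <- function(x) {
  if (inherits(x, "participant_group")) x else participant_group(x)
}

#' Leave-one-out average timeseries
#'
#' Elementwise mean of all group members except participant `p`.
#'
#' @param group A [participant_group()] (or plain list of matched
#'   matrices) with at least 2 members.
#' @param p Index of the member to leave out.
#' @return A `T x K` matrix.
#' @export
loo_average <- function(group, p) {
  group <- as_group(group)
  P <- length(group)
  if (P < 2L) stop("leave-one-out average requires P >= 2", call. = FALSE)
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 1L || p > P)
    stop("participant index out of range", call. = FALSE)
  Reduce(`+`, group[-p]) / (P - 1L)
}

#' Dynamic inter-subject functional connectivity
#'
#' For each participant `p`, computes the dynamic cross-correlation
#' between `p`'s features and the leave-one-out average of the remaining
#' participants, Fisher-z transforms it, averages the symmetrized
#' z-matrices across participants
#' (\eqn{\frac{1}{2P}\sum_p Z(Y^p)^\top + Z(Y^p)}), maps back to
#' correlation space, and vectorizes each timepoint's matrix. The
#' symmetrization makes each output row devectorize to an exactly
#' symmetric matrix. Diagonal entries of the per-participant
#' cross-correlations are generally below 1 (a participant is correlated
#' with the average of the others, not with itself) and are passed
#' through untouched.
#'
#' @inheritParams loo_average
#' @inheritParams dynamic_corr
#' @return A `corr_series` (`T x ((K^2-K)/2 + K)`).
#' @export
disfc <- function(group, kernel, mode = c("as_printed", "fully_weighted")) {
  mode <- match.arg(mode)
  group <- as_group(group)
  P <- length(group)
  if (P < 2L) stop("disfc requires P >= 2 participants", call. = FALSE)
  T <- nrow(group[[1L]])
  K <- ncol(group[[1L]])
  acc <- array(0, c(K, K, T))
  for (p in seq_len(P)) {
    Yp <- dynamic_xcorr(group[[p]], loo_average(group, p), kernel, mode)
    for (t in seq_len(T)) {
      Z <- fisher_z(Yp[[t]])
      acc[, , t] <- acc[, , t] + (t(Z) + Z) / (2 * P)
    }
  }
  idx <- vec_index(K)
  out <- t(apply(acc, 3L, function(M) inv_fisher_z(M)[idx]))
  new_corr_series(out, K = K, kernel = kernel, mode = mode)
}
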