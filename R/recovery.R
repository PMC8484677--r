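## Recovery benchmark: how well do kernel-based estimates reconstruct
## the known dynamic correlations of a synthetic dataset?
##
## Scoring correlates, at each timepoint, the vectorized recovered
## correlation matrix with a reference (usually the ground-truth
## template at that timepoint). Scoring uses the strict upper triangle:
## the unit diagonal is identical in both vectors by construction and
## including it would inflate every score with a constant matched
## component (set include_diagonal = TRUE to keep it anyway).

## row-wise Pearson correlation between two matched matrices
row_cor <- function(A, B) {
  A <- A - rowMeans(A); B <- B - rowMeans(B)
  rowSums(A * B) / sqrt(rowSums(A^2) * rowSums(B^2))
}

## row-major i<j pair ordering matching the off-diagonal entries of the
## vectorization in vectorize_corr()
pair_index <- function(K) {
  pr <- which(upper.tri(diag(K)), arr.ind = TRUE)
  pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
}

## Estimate the order-`order` correlation stream of a dataset's
## observations. Order 1 applies the kernel estimator directly. For
## higher orders, the correlation entries themselves become the next
## features: the strict upper triangle of each estimated matrix (the
## unit-diagonal entries are constant and carry no signal), giving
## (K^2-K)/2 features per step, with the same kernel at every step.
## Keeping every off-diagonal entry (rather than a K-column projection)
## preserves the one-to-one mapping onto the Kronecker-template truth.
recovered_stream <- function(X, kernel, mode, order) {
  feats <- X
  for (j in seq_len(order)) {
    Y <- dynamic_corr(feats, kernel, mode)
    if (j == order) return(Y)
    feats <- unclass(Y)[, vec_offdiag(attr(Y, "K")), drop = FALSE]
  }
}

## Truth for the order-`order` recovered stream, as the matching
## submatrix of the Kronecker template: for first-order pairs (a, b) and
## (c, d) (a < b, c < d), the template similarity is
## m_{j-1}(a, c) * m_{j-1}(b, d), iterated down from the order-1
## template. Returns a T x (P*(P+1)/2) matrix, P = number of pairs.
truth_stream <- function(dataset, order) {
  m1 <- true_corr(dataset, 1L)
  K <- attr(m1, "K")
  m1 <- unclass(m1)
  if (order == 1L) return(m1)
  ## iterate the pair lift order - 1 times
  cur <- m1; curK <- K
  for (j in seq_len(order - 1L)) {
    pr <- pair_index(curK)
    P <- nrow(pr)
    out <- matrix(NA_real_, nrow(cur), P * (P + 1) / 2)
    idx <- vec_index(P)
    for (t in seq_len(nrow(cur))) {
      M <- devectorize_corr(cur[t, ])
      S <- M[pr[, 1L], pr[, 1L]] * M[pr[, 2L], pr[, 2L]]
      out[t, ] <- S[idx]
    }
    cur <- out; curK <- P
  }
  cur
}

#' Score recovery of known dynamic correlations
#'
#' Estimates the order-`order` dynamic correlations of a synthetic
#' dataset's observations and correlates, at each timepoint, the
#' vectorized estimate with a reference row: the ground truth at that
#' timepoint (`"truth"`), the truth at the first or last timepoint
#' (`"first_timepoint"`, `"last_timepoint"`; the ramping-regime
#' references), or each event's template (`"event_template"`, one
#' timecourse per event).
#'
#' @param dataset A `"hoc_sim"` dataset.
#' @param kernel Analysis kernel ([kernel_spec()]).
#' @param mode Estimator variant, see [dynamic_corr()].
#' @param order Correlation order to score (up to the dataset's
#'   simulated order).
#' @param reference Reference kind (see Details).
#' @param include_diagonal Keep the unit-diagonal entries in the scored
#'   vectors (default `FALSE`).
#' @return An object of class `"recovery_result"`: list with `values`
#'   (length-`T` numeric, or `n_events x T` matrix for
#'   `"event_template"`), plus the scoring metadata.
#' @export
recovery_timecourse <- function(dataset, kernel,
                                mode = c("as_printed", "fully_weighted"),
                                order = 1L,
                                reference = c("truth", "first_timepoint",
                                              "last_timepoint",
                                              "event_template"),
                                include_diagonal = FALSE) {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  stopifnot(inherits(dataset, "hoc_sim"))
  order <- as.integer(order)
  if (order > dataset$regime$order)
    stop("dataset was simulated to order ", dataset$regime$order,
         "; cannot score order ", order, call. = FALSE)

  rec <- recovered_stream(dataset$observations, kernel, mode, order)
  tru <- truth_stream(dataset, order)
  keep <- if (include_diagonal) rep(TRUE, ncol(tru)) else
    vec_offdiag(attr(rec, "K"))
  R <- unclass(rec)[, keep, drop = FALSE]
  U <- tru[, keep, drop = FALSE]

  values <- switch(reference,
    truth = row_cor(R, U),
    first_timepoint = row_cor(R, matrix(U[1L, ], nrow(R), ncol(U),
                                        byrow = TRUE)),
    last_timepoint = row_cor(R, matrix(U[nrow(U), ], nrow(R), ncol(U),
                                       byrow = TRUE)),
    event_template = {
      if (dataset$regime$category != "event")
        stop("event_template reference needs an event-regime dataset",
             call. = FALSE)
      ne <- dataset$regime$n_events
      len <- nrow(U) / ne
      tmpl <- U[seq(1L, nrow(U), by = len), , drop = FALSE]
      t(vapply(seq_len(ne), function(e)
        row_cor(R, matrix(tmpl[e, ], nrow(R), ncol(U), byrow = TRUE)),
        numeric(nrow(R))))
    })
  structure(list(values = values, kernel = kernel, mode = mode,
                 order = order, reference = reference,
                 regime = dataset$regime),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery: %s regime, order %d, kernel %s, mean %.3f>\n",
              x$regime$category, x$order, format(x$kernel),
              mean(x$values)))
  invisible(x)
}

#' Summarize recovery across replicate datasets
#'
#' Per-timepoint mean and t-distribution 95% confidence interval of the
#' mean, across a list of [recovery_timecourse()] results with equal
#' length.
#'
#' @param results List of `"recovery_result"` objects (>= 2), each with
#'   a vector-valued timecourse.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `timepoint`, `mean`, `lower`,
#'   `upper`.
#' @export
summarize_recovery <- function(results, level = 0.95) {
  if (length(results) < 2L)
    stop("need at least 2 results", call. = FALSE)
  vals <- lapply(results, function(r)
    if (inherits(r, "recovery_result")) r$values else r)
  len <- vapply(vals, length, integer(1L))
  if (length(unique(len)) != 1L)
    stop("results have mismatched lengths", call. = FALSE)
  M <- do.call(rbind, vals)                    # datasets x timepoints
  n <- nrow(M)
  mu <- colMeans(M)
  se <- apply(M, 2L, stats::sd) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
  data.frame(timepoint = seq_along(mu), mean = mu,
             lower = mu - q * se, upper = mu + q * se)
}

#' Factorial recovery sweep
#'
#' Runs the recovery benchmark over a grid of regimes, kernels, orders
#' and dimensions, returning one tidy row per dataset x kernel x order
#' (recovery averaged over timepoints).
#'
#' @param categories Character vector of regime categories.
#' @param kernels List of [kernel_spec()] objects.
#' @param orders Integer vector of orders to score.
#' @param reps Replicate datasets per cell (0 gives an empty table).
#' @param K,T Dataset dimensions (vectors allowed; crossed).
#' @param mode Estimator variant.
#' @param seed Base seed; replicate r of each cell uses `seed + r`.
#' @return A data frame with columns `category`, `K`, `T`, `rep`,
#'   `kernel`, `width`, `mode`, `order`, `mean_recovery`.
#' @export
recovery_sweep <- function(categories, kernels, orders = 1L, reps = 1L,
                           K = 50L, T = 300L,
                           mode = c("as_printed", "fully_weighted"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (!is.list(kernels)) kernels <- list(kernels)
  rows <- list()
  i <- 0L
  for (cat_ in categories) for (Ki in K) for (Ti in T) {
    for (r in seq_len(reps)) {
      sim_order <- max(orders)
      sp <- regime_spec(cat_, K = Ki, T = Ti, order = sim_order,
                        seed = seed + r + 1000L * i)
      ds <- if (sim_order > 1L) simulate_higher_order(sp) else
        simulate_first_order(sp)
      for (kn in kernels) for (o in orders) {
        rec <- recovery_timecourse(ds, kn, mode = mode, order = o)
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat_, K = Ki, T = Ti, rep = r,
          kernel = kn$family, width = kn$width, mode = mode, order = o,
          mean_recovery = mean(rec$values))
      }
    }
    i <- i + 1L
  }
  if (!length(rows))
    return(data.frame(category = character(0), K = integer(0),
                      T = integer(0), rep = integer(0),
                      kernel = character(0), width = numeric(0),
                      mode = character(0), order = integer(0),
                      mean_recovery = numeric(0)))
  do.call(rbind, rows)
}
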