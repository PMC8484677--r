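## Across-participant temporal decoding: can a held-out group's
## timepoints be labelled by correlating its per-timepoint feature
## patterns (group DISFC at each order, plus the order-0 mean activity)
## with a template group's patterns? Decoding accuracy above chance
## (1/T) indicates stimulus-driven structure that is consistent across
## participants.

#' Random template/decode group split
#'
#' Seeded uniform partition of `P` participants into two groups whose
#' sizes differ by at most 1, plus a nested split of the training group
#' into two halves (used for feature-weight optimization).
#'
#' @param P Number of participants (`>= 4`, so the nested halves are
#'   non-empty pairs).
#' @param seed Optional integer seed.
#' @return A list with integer index vectors `train`, `test`, `train1`,
#'   `train2`.
#' @export
split_groups <- function(P, seed = NULL) {
  P <- as.integer(P)
  if (P < 4L) stop("P must be >= 4", call. = FALSE)
  with_seed(seed, {
    perm <- sample.int(P)
    n_train <- ceiling(P / 2)
    train <- sort(perm[seq_len(n_train)])
    test <- sort(perm[-seq_len(n_train)])
    h <- sample(train)
    n1 <- ceiling(length(train) / 2)
    list(train = train, test = test,
         train1 = sort(h[seq_len(n1)]), train2 = sort(h[-seq_len(n1)]))
  })
}

check_feature_rows <- function(M, what) {
  v <- apply(M, 1L, stats::var)
  if (any(v <= 0))
    stop("degenerate ", what, ": timepoint ", which(v <= 0)[1L],
         " has an all-constant feature row", call. = FALSE)
  invisible(M)
}

#' Timepoint decoding matrix
#'
#' `Lambda[i, j]` is the Pearson correlation between row `i` of the
#' template features and row `j` of the to-be-decoded features.
#'
#' @param template,decode Matched `T x F` feature matrices.
#' @return A `T x T` matrix.
#' @export
decode_matrix <- function(template, decode) {
  template <- unclass(as.matrix(template))
  decode <- unclass(as.matrix(decode))
  if (!identical(dim(template), dim(decode)))
    stop("template and decode features must share dimensions",
         call. = FALSE)
  if (nrow(template) < 2L)
    stop("need at least 2 timepoints", call. = FALSE)
  check_feature_rows(template, "template features")
  check_feature_rows(decode, "decode features")
  stats::cor(t(template), t(decode))
}

accuracy_from_lambda <- function(L) {
  ## label each decode timepoint (column) with the best template row;
  ## ties break to the lowest template index (which.max)
  labels <- apply(L, 2L, which.max)
  mean(labels == seq_len(ncol(L)))
}

combine_lambdas <- function(lambdas, weights) {
  L <- lambdas[[1L]] * weights[1L]
  if (length(lambdas) > 1L)
    for (i in 2L:length(lambdas)) L <- L + lambdas[[i]] * weights[i]
  L
}

#' Across-participant correlation-based decoding accuracy
#'
#' Builds one decoding matrix per feature order (row-wise correlations
#' between the two groups' feature matrices), combines them as
#' \eqn{\Lambda = \sum_i \phi_i \Lambda_i}, labels each to-be-decoded
#' timepoint with the most correlated template timepoint, and returns
#' the proportion of correct labels averaged over both decoding
#' directions (each group serves once as template and once as decode
#' target).
#'
#' @param template,decode Lists of matched `T x F_i` per-order feature
#'   matrices (a single matrix is treated as a list of one).
#' @param weights Non-negative weights summing to 1, one per order;
#'   default uniform.
#' @return Decoding accuracy in `[0, 1]`.
#' @export
decode_pair <- function(template, decode, weights = NULL) {
  if (is.matrix(template)) template <- list(template)
  if (is.matrix(decode)) decode <- list(decode)
  if (length(template) != length(decode))
    stop("template and decode must have the same number of orders",
         call. = FALSE)
  n <- length(template)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < -1e-8) ||
      abs(sum(weights) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  lambdas <- mapply(decode_matrix, template, decode, SIMPLIFY = FALSE)
  L <- combine_lambdas(lambdas, weights)
  (accuracy_from_lambda(L) + accuracy_from_lambda(t(L))) / 2
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

## differentiable surrogate for the discrete accuracy: softmax
## probability mass on the correct timepoint, averaged over timepoints
## and both decoding directions
surrogate_obj <- function(lambdas, weights, temperature) {
  L <- combine_lambdas(lambdas, weights)
  p1 <- mean(vapply(seq_len(ncol(L)), function(j) {
    softmax(L[, j] / temperature)[j]
  }, numeric(1L)))
  p2 <- mean(vapply(seq_len(nrow(L)), function(i) {
    softmax(L[i, ] / temperature)[i]
  }, numeric(1L)))
  (p1 + p2) / 2
}

lambda_accuracy <- function(lambdas, weights) {
  L <- combine_lambdas(lambdas, weights)
  (accuracy_from_lambda(L) + accuracy_from_lambda(t(L))) / 2
}

#' Optimize per-order feature weights on the probability simplex
#'
#' Finds non-negative weights (summing to 1) over the `n + 1` feature
#' orders that maximize the decoding accuracy between two halves of the
#' training group. Decoding accuracy is piecewise constant in the
#' weights, so the search ascends a differentiable surrogate — the
#' softmax probability mass on the correct timepoint (temperature
#' `temperature`) — by quasi-Newton (BFGS) ascent on
#' softmax-reparameterized weights, from multiple starts (the uniform
#' weights and each simplex vertex). The uniform weights and every
#' vertex are also evaluated directly as candidates, and the candidate
#' with the highest *true* (unsmoothed) accuracy is returned; the
#' returned accuracy therefore never falls below the uniform-weight
#' accuracy.
#'
#' @param train1,train2 Lists of matched per-order feature matrices for
#'   the two training halves.
#' @param temperature Softmax temperature of the surrogate objective.
#' @return A list with `weights` (length `n + 1`, non-negative, summing
#'   to 1) and `accuracy` (true between-half accuracy at those weights).
#' @export
optimize_weights <- function(train1, train2, temperature = 0.1) {
  if (is.matrix(train1)) train1 <- list(train1)
  if (is.matrix(train2)) train2 <- list(train2)
  n <- length(train1)
  lambdas <- mapply(decode_matrix, train1, train2, SIMPLIFY = FALSE)
  if (n == 1L)
    return(list(weights = 1, accuracy = lambda_accuracy(lambdas, 1)))

  cands <- list(rep(1 / n, n))
  for (i in seq_len(n)) {
    v <- rep(0, n); v[i] <- 1
    cands[[length(cands) + 1L]] <- v
  }
  starts <- list(rep(0, n))
  for (i in seq_len(n)) {
    th <- rep(0, n); th[i] <- 4
    starts[[length(starts) + 1L]] <- th
  }
  for (th in starts) {
    opt <- try(stats::optim(th, function(theta)
      -surrogate_obj(lambdas, softmax(theta), temperature),
      method = "BFGS", control = list(maxit = 200)), silent = TRUE)
    if (!inherits(opt, "try-error"))
      cands[[length(cands) + 1L]] <- softmax(opt$par)
  }
  accs <- vapply(cands, function(w) lambda_accuracy(lambdas, w),
                 numeric(1L))
  best <- cands[[which.max(accs)]]
  best <- pmax(best, 0); best <- best / sum(best)   # exact simplex
  list(weights = best, accuracy = max(accs))
}

group_features <- function(members, stacks, order, kernel, mode) {
  if (order == 0L) {
    Reduce(`+`, members) / length(members)
  } else {
    sub <- lapply(stacks, function(s) s[[order]])   # X_{order-1} per member
    unclass(disfc(participant_group(sub), kernel, mode))
  }
}

#' Run the full across-participant decoding analysis
#'
#' For each of `folds` random group assignments and each kernel in the
#' bank: participants' order stacks are built once with exact Dirac
#' delta kernels (temporal blur enters only through the final DISFC
#' step), with PCA projections fitted jointly across all participants
#' per order so every group lives in one shared space. For each
#' feature-set size `n'` in `0..max_order`, per-order weights are
#' optimized on a nested split of the training group and the weighted
#' classifier is evaluated on the held-out test group. Order-0 features
#' are each group's mean timeseries; order-`n` features are the group's
#' DISFC over the members' order-`n-1` stack entries, computed with the
#' analysis kernel.
#'
#' @param group A [participant_group()] (or list of matched `T x K`
#'   matrices), `P >= 4`.
#' @param max_order Highest feature order to include.
#' @param kernel_bank List of analysis kernels (default
#'   [default_kernel_bank()]).
#' @param mode Estimator variant, see [dynamic_corr()].
#' @param folds Number of random group assignments (default 10).
#' @param seed Integer seed; fold `f` splits with `seed + f`.
#' @param temperature Surrogate temperature for [optimize_weights()].
#' @return An object of class `"decode_result"`: list with `records` (a
#'   data frame: fold x kernel x max_order accuracies and relative
#'   accuracies), `weights` (optimized weights per record),
#'   `by_order` (kernel-averaged mean accuracy and 95% t-interval per
#'   feature-set size), `T`, `folds`, and the configuration.
#' @export
run_decoding <- function(group, max_order = 1L,
                         kernel_bank = default_kernel_bank(),
                         mode = c("as_printed", "fully_weighted"),
                         folds = 10L, seed = 1L, temperature = 0.1) {
  mode <- match.arg(mode)
  group <- as_group(group)
  P <- length(group)
  if (P < 4L) stop("decoding requires P >= 4 participants", call. = FALSE)
  max_order <- as.integer(max_order)
  T <- nrow(group[[1L]])
  if (!is.list(kernel_bank)) kernel_bank <- list(kernel_bank)
  if (is.null(names(kernel_bank)))
    names(kernel_bank) <- vapply(kernel_bank, format, character(1L))

  ## participant stacks X_0..X_{max_order-1} under the delta kernel,
  ## PCA fitted on all participants jointly per order (so groups share
  ## one space), reused across folds and kernels
  stacks <- lapply(group, function(m) list(unclass(m)))
  if (max_order >= 2L) {
    for (o in seq_len(max_order - 1L)) {
      Ys <- lapply(stacks, function(s)
        dynamic_corr(s[[o]], dirac_kernel(), mode))
      pca <- pca_fit(Ys, K = ncol(group[[1L]]))
      for (p in seq_len(P))
        stacks[[p]][[o + 1L]] <- pca_apply(pca, Ys[[p]])
    }
  }

  members_all <- unclass(group)
  records <- list()
  weights_out <- list()
  for (f in seq_len(folds)) {
    sp <- split_groups(P, seed = seed + f)
    mem <- lapply(sp, function(ix) members_all[ix])
    stk <- lapply(sp, function(ix) stacks[ix])
    ## order-0 features are kernel independent
    f0 <- lapply(names(sp), function(g)
      group_features(mem[[g]], stk[[g]], 0L, NULL, mode))
    names(f0) <- names(sp)
    for (kname in names(kernel_bank)) {
      kern <- kernel_bank[[kname]]
      feats <- lapply(names(sp), function(g) {
        fs <- vector("list", max_order + 1L)
        fs[[1L]] <- f0[[g]]
        if (max_order >= 1L) for (o in seq_len(max_order))
          fs[[o + 1L]] <- group_features(mem[[g]], stk[[g]], o, kern, mode)
        fs
      })
      names(feats) <- names(sp)
      for (n_set in 0:max_order) {
        ix <- seq_len(n_set + 1L)
        w <- optimize_weights(feats$train1[ix], feats$train2[ix],
                              temperature = temperature)
        acc <- decode_pair(feats$train[ix], feats$test[ix], w$weights)
        records[[length(records) + 1L]] <- data.frame(
          fold = f, kernel = kname, family = kern$family,
          width = kern$width, max_order = n_set,
          accuracy = acc, relative_accuracy = acc - 1 / T,
          train_accuracy = w$accuracy)
        weights_out[[length(weights_out) + 1L]] <- w$weights
      }
    }
  }
  records <- do.call(rbind, records)

  ## kernel-averaged accuracy per fold and feature-set size, then
  ## mean and t-interval across folds
  by_order <- do.call(rbind, lapply(0:max_order, function(n_set) {
    sub <- records[records$max_order == n_set, ]
    per_fold <- tapply(sub$accuracy, sub$fold, mean)
    mu <- mean(per_fold)
    se <- stats::sd(per_fold) / sqrt(length(per_fold))
    q <- if (length(per_fold) > 1L)
      stats::qt(0.975, df = length(per_fold) - 1L) else NA_real_
    data.frame(max_order = n_set, mean_accuracy = mu,
               lower = mu - q * se, upper = mu + q * se,
               mean_relative = mu - 1 / T)
  }))

  structure(list(records = records, weights = weights_out,
                 by_order = by_order, T = T, folds = folds,
                 max_order = max_order,
                 kernel_bank = kernel_bank, mode = mode, seed = seed),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Across-participant temporal decoding (T = %d, chance = %.4f)\n",
              x$T, 1 / x$T))
  cat(sprintf("  %d folds x %d kernels, feature sets up to order %d\n",
              x$folds, length(x$kernel_bank), x$max_order))
  cat("  kernel-averaged accuracy by feature-set size:\n")
  print(x$by_order, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare decoding feature sets
#'
#' Paired two-tailed t-tests across folds on the kernel-averaged
#' decoding accuracies, for every pair of feature-set sizes and for
#' each size against the mean of all others. The summary matrix carries
#' the pairwise t-statistics off the diagonal and, on the diagonal, the
#' mean optimized weight assigned to that order in the full
#' (`max_order`) feature set, averaged over folds and kernels
#' (weights sum to 1 across orders, so these are relative weights).
#'
#' @param result A `"decode_result"` from [run_decoding()].
#' @return A list with matrices `t` and `p` (pairwise tests), data
#'   frame `vs_rest` (each set against the mean of the others), vector
#'   `mean_weights`, and `summary_matrix` as described.
#' @export
compare_feature_sets <- function(result) {
  stopifnot(inherits(result, "decode_result"))
  rec <- result$records
  if (result$folds < 2L) stop("need >= 2 folds", call. = FALSE)
  sizes <- sort(unique(rec$max_order))
  per_fold <- sapply(sizes, function(n_set) {
    sub <- rec[rec$max_order == n_set, ]
    tapply(sub$accuracy, sub$fold, mean)
  })                                            # folds x sizes
  ns <- length(sizes)
  ## paired two-tailed t across folds; a constant non-zero difference
  ## has zero variance, which we report as an infinite t with p = 0
  paired_t <- function(d) {
    n <- length(d)
    s <- stats::sd(d)
    if (s < 1e-12 * max(1, abs(mean(d)))) {
      if (abs(mean(d)) < 1e-15) return(c(t = 0, p = 1))
      return(c(t = sign(mean(d)) * Inf, p = 0))
    }
    tt <- mean(d) / (s / sqrt(n))
    c(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1L))
  }
  tmat <- pmat <- matrix(NA_real_, ns, ns,
                         dimnames = list(sizes, sizes))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    r <- paired_t(per_fold[, i] - per_fold[, j])
    tmat[i, j] <- r["t"]; pmat[i, j] <- r["p"]
  }
  vs_rest <- do.call(rbind, lapply(seq_len(ns), function(i) {
    rest <- rowMeans(per_fold[, -i, drop = FALSE])
    r <- paired_t(per_fold[, i] - rest)
    data.frame(max_order = sizes[i], t = unname(r["t"]),
               p = unname(r["p"]))
  }))
  ## mean optimized weights from the full feature set
  full <- which(rec$max_order == result$max_order)
  W <- do.call(rbind, result$weights[full])
  mean_weights <- colMeans(W)
  smat <- tmat
  diag(smat) <- c(mean_weights,
                  rep(NA_real_, ns - length(mean_weights)))[seq_len(ns)]
  list(t = tmat, p = pmat, vs_rest = vs_rest,
       mean_weights = mean_weights, summary_matrix = smat)
}

#' Permutation chance band for decoding accuracy
#'
#' Simulates the null distribution of the (two-direction average)
#' decoding accuracy when timepoint labels are assigned by a random
#' permutation, optionally averaged over `n_average` independent folds,
#' and returns the central `level` band.
#'
#' @param T Number of timepoints.
#' @param n_average How many fold-level accuracies are averaged in the
#'   statistic whose band is required.
#' @param n_perm Number of permutation draws.
#' @param level Band coverage (default 0.95).
#' @param seed Optional seed.
#' @return Named numeric: `lower`, `upper` (band around `1/T`).
#' @export
chance_accuracy_band <- function(T, n_average = 1L, n_perm = 2000L,
                                 level = 0.95, seed = NULL) {
  with_seed(seed, {
    draws <- vapply(seq_len(n_perm), function(i) {
      mean(vapply(seq_len(n_average), function(j) {
        a1 <- mean(sample.int(T) == seq_len(T))
        a2 <- mean(sample.int(T) == seq_len(T))
        (a1 + a2) / 2
      }, numeric(1L)))
    }, numeric(1L))
    q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2))
    c(lower = unname(q[1L]), upper = unname(q[2L]))
  })
}
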