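## Simulators for multivariate Gaussian timeseries with known dynamic
## correlations. Observations at each timepoint are drawn independently
## from N(0, Sigma_t); the regimes differ only in how Sigma_t moves:
##
##   constant - one covariance for the whole series
##   random   - a fresh covariance at every timepoint
##   ramping  - linear interpolation between two anchor covariances
##   event    - n_events covariances, each spanning T/n_events samples
##
## Higher-order datasets lift the first-order correlation template to
## order n by repeated Kronecker self-products and then sample backwards
## (order n -> ... -> order 0), so the observations carry known dynamic
## correlations at every order.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Simulation regime specification
#'
#' Describes one synthetic dataset: the temporal regime of the
#' underlying correlations, the dimensions, and the highest simulated
#' correlation order. Defaults follow the package's benchmark scales:
#' `K = 50` features over `T = 300` timepoints for first-order datasets
#' and `K = 10` for higher-order datasets (higher-order generation needs
#' \eqn{O(K^4)} memory at order 2, so fewer base features keep the two
#' benchmarks on an even footing).
#'
#' @param category `"constant"`, `"random"`, `"ramping"` or `"event"`.
#' @param K Number of order-0 features (`>= 2`).
#' @param T Number of timepoints (`>= 2`; divisible by `n_events` for
#'   the event regime).
#' @param order Highest simulated correlation order (`>= 1`).
#' @param n_events Number of piecewise-constant covariance blocks
#'   (event regime only).
#' @param seed Optional integer seed; a given spec + seed reproduces the
#'   dataset exactly.
#' @return An object of class `"regime_spec"`.
#' @export
regime_spec <- function(category = c("constant", "random", "ramping", "event"),
                        K = if (order > 1L) 10L else 50L, T = 300L,
                        order = 1L, n_events = 5L, seed = NULL) {
  category <- match.arg(category)
  order <- as.integer(order)
  K <- as.integer(K); T <- as.integer(T); n_events <- as.integer(n_events)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (K < 2L || T < 2L) stop("need K >= 2 and T >= 2", call. = FALSE)
  if (category == "event" && T %% n_events != 0L)
    stop("T must be divisible by n_events for the event regime",
         call. = FALSE)
  structure(list(category = category, K = K, T = T, order = order,
                 n_events = n_events, seed = seed),
            class = "regime_spec")
}

#' @export
print.regime_spec <- function(x, ...) {
  cat(sprintf("<regime_spec: %s, K = %d, T = %d, order = %d%s%s>\n",
              x$category, x$K, x$T, x$order,
              if (x$category == "event")
                paste0(", n_events = ", x$n_events) else "",
              if (!is.null(x$seed)) paste0(", seed = ", x$seed) else ""))
  invisible(x)
}

#' Random Wishart-type covariance matrix
#'
#' \eqn{\Sigma = CC^\top} with `C` entries i.i.d. standard normal:
#' symmetric, positive semidefinite, expectation `K * I`.
#'
#' @param K Dimension (`>= 1`).
#' @return A `K x K` covariance matrix.
#' @export
random_covariance <- function(K) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  C <- matrix(stats::rnorm(K * K), K, K)
  tcrossprod(C)
}

cov_to_corr <- function(S) {
  d <- 1 / sqrt(diag(S))
  S * outer(d, d)
}

## covariance timecourse for a regime, run-length encoded:
## $covs = list of unique covariance matrices, $index = length-T map
regime_cov_path <- function(spec) {
  K <- spec$K; T <- spec$T
  switch(spec$category,
    constant = list(covs = list(random_covariance(K)), index = rep(1L, T)),
    random   = list(covs = lapply(seq_len(T), function(i) random_covariance(K)),
                    index = seq_len(T)),
    ramping  = {
      A <- random_covariance(K); B <- random_covariance(K)
      f <- (seq_len(T) - 1) / (T - 1)          # t in 0..T-1, denominator T-1
      list(covs = lapply(f, function(a) (1 - a) * A + a * B),
           index = seq_len(T))
    },
    event    = {
      covs <- lapply(seq_len(spec$n_events), function(i) random_covariance(K))
      list(covs = covs, index = rep(seq_len(spec$n_events),
                                    each = T / spec$n_events))
    })
}

sym_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

rmvn0 <- function(sqrtS) drop(sqrtS %*% stats::rnorm(nrow(sqrtS)))

## eigenvalue clipping + diagonal re-unitization: the reshaped,
## symmetrized backward draw is not guaranteed PSD
psd_repair_corr <- function(A, floor = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  B <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
  cov_to_corr(B)
}

new_sim <- function(observations, truth, realized, regime) {
  structure(list(observations = observations, truth = truth,
                 realized = realized, regime = regime,
                 seed = regime$seed),
            class = "hoc_sim")
}

#' @export
print.hoc_sim <- function(x, ...) {
  cat(sprintf("<synthetic dataset: %s regime, T = %d, K = %d, orders 1..%d>\n",
              x$regime$category, x$regime$T, x$regime$K, x$regime$order))
  invisible(x)
}

#' Simulate a timeseries with known dynamic first-order correlations
#'
#' Draws `T` independent observations \eqn{s_t \sim N(0, \Sigma_t)}
#' where \eqn{\Sigma_t} follows the regime. The stored ground truth is
#' the correlation normalization \eqn{D^{-1/2}\Sigma_t D^{-1/2}} of each
#' generating covariance, as a vectorized `corr_series`.
#'
#' @param spec A [regime_spec()] with `order = 1`.
#' @return An object of class `"hoc_sim"` with elements `observations`
#'   (`T x K`), `truth` (list with the order-1 `corr_series`), and
#'   `regime`.
#' @export
simulate_first_order <- function(spec) {
  stopifnot(inherits(spec, "regime_spec"))
  if (spec$order != 1L)
    stop("spec$order must be 1; use simulate_higher_order otherwise",
         call. = FALSE)
  with_seed(spec$seed, {
    path <- regime_cov_path(spec)
    chols <- lapply(path$covs, chol)
    obs <- t(vapply(path$index,
                    function(i) drop(stats::rnorm(spec$K) %*% chols[[i]]),
                    numeric(spec$K)))
    idx <- vec_index(spec$K)
    truth_u <- t(vapply(path$covs,
                        function(S) cov_to_corr(S)[idx],
                        numeric(length(idx))))
    truth <- new_corr_series(truth_u[path$index, , drop = FALSE],
                             K = spec$K)
    new_sim(obs, list(`1` = truth), NULL, spec)
  })
}

#' Simulate a timeseries with known dynamic higher-order correlations
#'
#' Builds an order-1 correlation template timecourse \eqn{m_1(t)} from
#' the regime, lifts it to order `n` by Kronecker self-products
#' (\eqn{m_{j+1} = m_j \otimes m_j}, applied independently at each
#' timepoint), then samples backwards: at each order `j` from `n` down
#' to 1, a draw from \eqn{N(0, m_j)} is reshaped to a square matrix,
#' symmetrized by reflecting its upper triangle, and repaired to a valid
#' correlation matrix (eigenvalue clipping at `1e-10` plus diagonal
#' re-unitization) to serve as the realized order-`j-1` correlation; the
#' final `K`-dimensional draw is the observation. The stored `truth`
#' holds the noiseless per-order templates; the realized (noisy)
#' intermediate matrices are kept in `realized`.
#'
#' @param spec A [regime_spec()] with `order >= 2`.
#' @param mem_budget Maximum number of values allowed for any single
#'   template matrix (\eqn{K^{2^{n-1}}} squared must stay below it).
#' @return An object of class `"hoc_sim"`; `truth` is a list of
#'   `corr_series`, one per order `1..order`.
#' @export
simulate_higher_order <- function(spec, mem_budget = 1e7) {
  stopifnot(inherits(spec, "regime_spec"))
  n <- spec$order
  if (n < 2L)
    stop("spec$order must be >= 2; use simulate_first_order otherwise",
         call. = FALSE)
  dims <- spec$K ^ (2 ^ (seq_len(n) - 1L))     # dim of m_j, j = 1..n
  if (max(dims)^2 > mem_budget)
    stop("order-", n, " template needs ", max(dims), "^2 = ",
         max(dims)^2, " values, above mem_budget = ", mem_budget,
         call. = FALSE)
  with_seed(spec$seed, {
    path <- regime_cov_path(spec)
    m1 <- lapply(path$covs, cov_to_corr)
    T <- spec$T; K <- spec$K

    ## per-order Kronecker templates for the unique covariances
    templates <- vector("list", n)              # templates[[j]][[u]]
    templates[[1L]] <- m1
    if (n > 1L) for (j in 2L:n)
      templates[[j]] <- lapply(templates[[j - 1L]],
                               function(m) kronecker(m, m))
    ## symmetric square roots of the order n-1 templates (top-order
    ## draws N(0, m_n) reshape to S G S with S = sqrt(m_{n-1}))
    sq_top <- lapply(templates[[n - 1L]], sym_sqrt)

    obs <- matrix(NA_real_, T, K)
    realized <- lapply(seq_len(n - 1L), function(j)
      matrix(NA_real_, T, dims[j] * (dims[j] + 1) / 2))

    for (t in seq_len(T)) {
      u <- path$index[t]
      ## top step: a draw from N(0, m_n) reshaped (row-major) to a
      ## d_{n-1} x d_{n-1} matrix equals S G S with S = sqrt(m_{n-1})
      d <- dims[n - 1L]
      G <- matrix(stats::rnorm(d * d), d, d)
      V <- sq_top[[u]] %*% G %*% sq_top[[u]]
      for (j in seq(n - 1L, 1L)) {
        V[lower.tri(V)] <- t(V)[lower.tri(V)]   # reflect upper triangle
        A <- psd_repair_corr(V)
        realized[[j]][t, ] <- A[vec_index(nrow(A))]
        v <- rmvn0(sym_sqrt(A))
        if (j == 1L) {
          obs[t, ] <- v                         # the observation
        } else {
          V <- matrix(v, dims[j - 1L], dims[j - 1L], byrow = TRUE)
        }
      }
    }

    truth <- list()
    for (j in seq_len(n)) {
      idx <- vec_index(dims[j])
      tu <- t(vapply(templates[[j]], function(m) m[idx],
                     numeric(length(idx))))
      truth[[as.character(j)]] <- new_corr_series(
        tu[path$index, , drop = FALSE], K = dims[j])
    }
    realized <- lapply(seq_along(realized), function(j)
      new_corr_series(realized[[j]], K = dims[j]))
    names(realized) <- as.character(seq_along(realized))
    new_sim(obs, truth, realized, spec)
  })
}

#' Ground-truth correlations of a synthetic dataset
#'
#' @param dataset A `"hoc_sim"` object.
#' @param order Correlation order (`1..regime$order`).
#' @return The `corr_series` of true (template) correlations.
#' @export
true_corr <- function(dataset, order = 1L) {
  stopifnot(inherits(dataset, "hoc_sim"))
  tr <- dataset$truth[[as.character(as.integer(order))]]
  if (is.null(tr))
    stop("dataset does not store truth at order ", order, call. = FALSE)
  tr
}

#' Simulate a multi-participant dataset with shared dynamics
#'
#' All participants share one stimulus-driven covariance timecourse
#' \eqn{\Sigma_t} (and, for `order > 1`, one realized backward-sampling
#' chain). Each participant's observation at timepoint `t` is
#' \deqn{s^p_t = \sqrt{1 - a}\, z_t + \sqrt{a}\, \epsilon^p_t,}
#' where \eqn{z_t \sim N(0, \Sigma_t)} is a shared signal draw,
#' \eqn{\epsilon^p_t \sim N(0, \Sigma_t)} is participant noise, and
#' `a = noise_weight`. Both components share the covariance, so the
#' marginal distribution of every participant is exactly
#' \eqn{N(0, \Sigma_t)} for any `a`. The default `a = 1` gives fully
#' independent draws (sharing only the correlation structure, the ISFC
#' premise); `a = 0` gives identical (noiseless) participants.
#'
#' @param spec A [regime_spec()].
#' @param P Number of participants (`>= 2`).
#' @param noise_weight Share of participant-specific variance in
#'   `[0, 1]`.
#' @return A list with `group` (a [participant_group()]) and `truth`
#'   (the shared ground-truth correlation streams, as in the
#'   single-participant simulators).
#' @export
simulate_group <- function(spec, P, noise_weight = 1) {
  stopifnot(inherits(spec, "regime_spec"))
  P <- as.integer(P)
  if (P < 2L) stop("P must be >= 2", call. = FALSE)
  if (!is.numeric(noise_weight) || noise_weight < 0 || noise_weight > 1)
    stop("noise_weight must lie in [0, 1]", call. = FALSE)
  a <- noise_weight
  with_seed(spec$seed, {
    base <- if (spec$order == 1L) {
      sp <- spec; sp$seed <- NULL
      simulate_first_order(sp)
    } else {
      sp <- spec; sp$seed <- NULL
      simulate_higher_order(sp)
    }
    ## per-timepoint generating correlation: template at order 1, or the
    ## realized order-1 chain for higher-order data
    gen <- if (spec$order == 1L) base$truth[["1"]] else base$realized[["1"]]
    genm <- unclass(gen)
    chols <- lapply(seq_len(nrow(genm)), function(t)
      sym_sqrt(devectorize_corr(genm[t, ])))
    T <- spec$T; K <- spec$K
    z <- t(vapply(chols, rmvn0, numeric(K)))
    members <- lapply(seq_len(P), function(p) {
      eps <- t(vapply(chols, rmvn0, numeric(K)))
      sqrt(1 - a) * z + sqrt(a) * eps
    })
    list(group = participant_group(members), truth = base$truth,
         regime = spec)
  })
}
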