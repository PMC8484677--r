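## Independent oracles used across the suite. These deliberately avoid
## the package's computational shortcuts: sums are written out term by
## term so they can disagree with a buggy fast path.

## static Pearson correlation of two vectors, written as the defining
## sums (mean, per-timepoint deviations, normalized product)
oracle_pearson <- function(x, y) {
  T <- length(x)
  mx <- sum(x) / T; my <- sum(y) / T
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## instantaneous correlation at timepoint t, literal evaluation: the
## centring uses the kernel-weighted mean, the product and deviation
## sums run unweighted over all timepoints
oracle_timecorr <- function(x, y, w) {
  mx <- sum(w * x); my <- sum(w * y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## fully weighted variant: the kernel weights every sum
oracle_timecorr_weighted <- function(x, y, w) {
  mx <- sum(w * x); my <- sum(w * y)
  num <- sum(w * (x - mx) * (y - my))
  num / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

## principal eigenvector by power iteration
oracle_power_iteration <- function(A, tol = 1e-10, max_iter = 10000) {
  v <- rep(1, nrow(A)) / sqrt(nrow(A))
  for (i in seq_len(max_iter)) {
    v_new <- A %*% v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < tol) break
    v <- v_new
  }
  v <- drop(v_new)
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}

## textbook t-interval for the mean
oracle_t_interval <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(m - half, m + half)
}

## textbook paired t statistic
oracle_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

random_symmetric <- function(K) {
  A <- matrix(rnorm(K * K), K)
  (A + t(A)) / 2
}
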