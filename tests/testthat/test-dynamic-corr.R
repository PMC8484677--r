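test_that("static correlation matches the term-by-term Pearson oracle", {
  X <- matrix(c(1, 2, 3, 2, 1, 4), ncol = 2)   # T = 3, K = 2
  S <- static_corr(X)
  expect_equal(S[1, 2], oracle_pearson(X[, 1], X[, 2]), tolerance = 1e-12)
  expect_true(isSymmetric(S))
  expect_equal(diag(S), c(1, 1))

  Y <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = -c(1, 2, 3))
  S2 <- static_corr(Y)
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[1, 3], -1)
})

test_that("a zero-variance column is reported by name", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(static_corr(X), "'b'")
})

test_that("vectorize/devectorize use the fixed ordering and invert exactly", {
  expect_length(vectorize_corr(diag(3)), 6L)
  expect_equal(vectorize_corr(diag(2)), c(1, 0, 1))
  ## row-major upper triangle: (1,1),(1,2),(1,3),(2,2),(2,3),(3,3)
  S <- matrix(c(1, 4, 5, 4, 2, 6, 5, 6, 3), 3)
  expect_equal(vectorize_corr(S), c(1, 4, 5, 2, 6, 3))
  set.seed(42)
  for (K in c(2, 5, 8)) {
    R <- random_symmetric(K)
    expect_equal(devectorize_corr(vectorize_corr(R)), R)
  }
  expect_equal(devectorize_corr(c(1, 0, 1)), diag(2))
  expect_error(devectorize_corr(numeric(5)), "integer K")
  expect_error(vectorize_corr(matrix(rnorm(9), 3)), "symmetric")
})

test_that("uniform-kernel dynamic correlations equal static Pearson in both modes", {
  set.seed(7)
  X <- matrix(rnorm(40 * 6), 40)
  target <- vectorize_corr(static_corr(X))
  for (mode in c("as_printed", "fully_weighted")) {
    Y <- unclass(dynamic_corr(X, uniform_kernel(), mode))
    for (t in c(1, 17, 40))
      expect_equal(Y[t, ], target, tolerance = 1e-12)
  }
})

test_that("instantaneous estimates match literal evaluation of the defining sums", {
  ## T = 6, K = 2 toy series, gaussian width 2, every timepoint
  X <- cbind(c(0.2, 1.5, -0.7, 2.2, 0.1, -1.0),
             c(1.1, -0.4, 0.8, 0.3, -1.6, 0.9))
  for (mode in c("as_printed", "fully_weighted")) {
    Y <- unclass(dynamic_corr(X, gaussian_kernel(2), mode))
    oracle <- if (mode == "as_printed") oracle_timecorr else
      oracle_timecorr_weighted
    for (t in 1:6) {
      w <- kernel_weights(gaussian_kernel(2), t, 6L)
      expect_equal(Y[t, 2], oracle(X[, 1], X[, 2], w), tolerance = 1e-10,
                   label = paste("mode", mode, "t", t))
    }
  }
})

test_that("dirac as_printed centres on the observation at t", {
  set.seed(3)
  X <- matrix(rnorm(20 * 2), 20)
  Y <- unclass(dynamic_corr(X, dirac_kernel(), "as_printed"))
  for (t in c(1, 9, 20)) {
    w <- numeric(20); w[t] <- 1
    expect_equal(Y[t, 2], oracle_timecorr(X[, 1], X[, 2], w),
                 tolerance = 1e-10)
  }
})

test_that("perfectly correlated columns stay at 1 for every timepoint and kernel", {
  set.seed(11)
  base <- rnorm(30)
  X <- cbind(base, 2 * base + 5, rnorm(30))
  for (spec in list(dirac_kernel(), gaussian_kernel(5), laplace_kernel(10))) {
    Y <- unclass(dynamic_corr(X, spec))
    expect_equal(Y[, 2], rep(1, 30), tolerance = 1e-8)  # pair (1,2)
  }
})

test_that("estimates are bounded, unit-diagonal, and shift/scale invariant", {
  set.seed(19)
  for (rep in 1:5) {
    X <- matrix(rnorm(25 * 4), 25)
    spec <- list(gaussian_kernel(3), laplace_kernel(7),
                 dirac_kernel())[[1 + rep %% 3]]
    Y <- unclass(dynamic_corr(X, spec))
    expect_true(all(Y >= -1 - 1e-12 & Y <= 1 + 1e-12))
    diag_cols <- which(!hocorr:::vec_offdiag(4))
    expect_equal(unname(Y[, diag_cols]), matrix(1, 25, 4))
    ## shifting and positively rescaling columns changes nothing
    X2 <- sweep(sweep(X, 2, c(100, -3, 0, 2e4), "+"), 2,
                c(2, 0.01, 5, 1), "*")
    expect_equal(unclass(dynamic_corr(X2, spec)), Y, tolerance = 1e-7)
  }
})

test_that("undefined estimator configurations raise errors", {
  X <- matrix(rnorm(20 * 3), 20)
  expect_error(dynamic_corr(X, dirac_kernel(), "fully_weighted"),
               "as_printed")
  expect_error(dynamic_corr(cbind(X, 1), laplace_kernel(5)), "variance")
  expect_error(dynamic_corr(matrix(1:4, 1), laplace_kernel(5)),
               "2 timepoints")
})

test_that("cross-correlation agrees with self- and permuted variants", {
  set.seed(23)
  X <- matrix(rnorm(15 * 3), 15)
  spec <- gaussian_kernel(4)
  Yx <- dynamic_xcorr(X, X, spec)
  Y <- unclass(dynamic_corr(X, spec))
  for (t in c(1, 8, 15))
    expect_equal(Yx[[t]], devectorize_corr(Y[t, ]), tolerance = 1e-10)
  ## permuting B's columns permutes the output columns
  perm <- c(3, 1, 2)
  Yp <- dynamic_xcorr(X, X[, perm], spec)
  for (t in c(2, 12))
    expect_equal(Yp[[t]], Yx[[t]][, perm], tolerance = 1e-12)
})

test_that("uniform-kernel cross-correlation equals the static oracle", {
  set.seed(29)
  A <- matrix(rnorm(12 * 2), 12)
  B <- matrix(rnorm(12 * 2), 12)
  Yx <- dynamic_xcorr(A, B, uniform_kernel())
  for (i in 1:2) for (j in 1:2)
    expect_equal(Yx[[5]][i, j], oracle_pearson(A[, i], B[, j]),
                 tolerance = 1e-12)
  expect_error(dynamic_xcorr(A, B[1:10, ], uniform_kernel()),
               "share the number of timepoints")
})
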