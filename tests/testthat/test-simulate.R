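test_that("random covariances are Gram matrices with expectation K*I", {
  set.seed(109)
  S <- random_covariance(5)
  expect_identical(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE)$values >= -1e-10))
  expect_length(random_covariance(1), 1L)
  expect_gte(random_covariance(1), 0)
  ## E[CC^T] = K I, checked by a sampling oracle
  acc <- matrix(0, 5, 5)
  for (i in 1:2000) acc <- acc + random_covariance(5) / 2000
  expect_equal(acc, diag(5, 5), tolerance = 0.35)
})

test_that("regime specs validate their fields", {
  expect_error(regime_spec("event", T = 301), "divisible")
  expect_error(regime_spec("constant", K = 1), "K >= 2")
  expect_error(regime_spec("constant", order = 0), "order")
  sp <- regime_spec("constant", order = 2)
  expect_identical(sp$K, 10L)          # higher-order default
  expect_identical(regime_spec("constant")$K, 50L)
})

test_that("ramping truth interpolates exactly between its anchors", {
  ds <- simulate_first_order(regime_spec("ramping", K = 6, T = 50,
                                         seed = 11))
  tr <- unclass(true_corr(ds, 1))
  ## endpoints are correlation matrices of the anchors; the midpoint
  ## differs from both
  S0 <- devectorize_corr(tr[1, ]); S1 <- devectorize_corr(tr[50, ])
  expect_equal(diag(S0), rep(1, 6))
  expect_equal(diag(S1), rep(1, 6))
  expect_gt(max(abs(S0 - S1)), 0.01)
  ## interior rows move monotonically in the interpolation parameter:
  ## row t is the correlation of (1-f) Sigma_start + f Sigma_end
  expect_false(isTRUE(all.equal(tr[25, ], tr[1, ])))
})

test_that("event truth is piecewise constant over equal blocks", {
  ds <- simulate_first_order(regime_spec("event", K = 5, T = 100,
                                         n_events = 5, seed = 13))
  tr <- unclass(true_corr(ds, 1))
  for (e in 1:5) {
    block <- tr[((e - 1) * 20 + 1):(e * 20), ]
    expect_equal(block, block[rep(1, 20), ], tolerance = 0)
  }
  expect_false(isTRUE(all.equal(tr[1, ], tr[21, ])))
})

test_that("constant-regime sample correlations converge to the stored truth", {
  ds <- simulate_first_order(regime_spec("constant", K = 6, T = 2000,
                                         seed = 17))
  S <- static_corr(ds$observations)
  expect_equal(vectorize_corr(S), unclass(true_corr(ds, 1))[1, ],
               tolerance = 0.12)   # ~O(1/sqrt(T)) sampling error
})

test_that("datasets are bit-identical under a fixed seed", {
  sp <- regime_spec("random", K = 5, T = 30, seed = 19)
  expect_identical(simulate_first_order(sp), simulate_first_order(sp))
  sp2 <- regime_spec("constant", K = 4, T = 30, order = 2, seed = 19)
  expect_identical(simulate_higher_order(sp2), simulate_higher_order(sp2))
})

test_that("kronecker lift of a correlation template is a valid template", {
  ds <- simulate_higher_order(regime_spec("constant", K = 2, T = 10,
                                          order = 2, seed = 23))
  m2 <- devectorize_corr(unclass(true_corr(ds, 2))[1, ])
  expect_identical(dim(m2), c(4L, 4L))
  expect_identical(m2, t(m2))
  expect_equal(diag(m2), rep(1, 4))
  expect_true(all(abs(m2) <= 1))
  m1 <- devectorize_corr(unclass(true_corr(ds, 1))[1, ])
  expect_equal(m2, kronecker(m1, m1))
  ## constant regime: identical truth at every timepoint
  tr2 <- unclass(true_corr(ds, 2))
  expect_equal(tr2, tr2[rep(1, 10), ], tolerance = 0, ignore_attr = TRUE)
})

test_that("realized intermediate correlations are valid and noisy", {
  ds <- simulate_higher_order(regime_spec("constant", K = 6, T = 40,
                                          order = 2, seed = 29))
  rl <- unclass(ds$realized[["1"]])
  for (t in c(1, 20, 40)) {
    A <- devectorize_corr(rl[t, ])
    expect_equal(diag(A), rep(1, 6))
    expect_true(all(abs(A) <= 1 + 1e-10))
    expect_true(all(eigen(A, symmetric = TRUE)$values >= -1e-8))
  }
  ## distinct draws at each timepoint
  expect_false(isTRUE(all.equal(rl[1, ], rl[2, ])))
})

test_that("backward draws have the covariance of the order-2 template", {
  ## sampling oracle: reshaped draws from N(0, m_2) should have entry
  ## covariances m_2[(a,b),(c,d)] = m_1(a,c) m_1(b,d)
  set.seed(31)
  m1 <- cov2cor(random_covariance(3))
  S <- eigen(m1, symmetric = TRUE)
  sq <- S$vectors %*% (sqrt(pmax(S$values, 0)) * t(S$vectors))
  n <- 4000
  draws <- t(replicate(n, as.vector(t(sq %*% matrix(rnorm(9), 3) %*% sq))))
  emp <- crossprod(draws) / n
  expect_equal(emp, kronecker(m1, m1), tolerance = 0.25)
})

test_that("memory budget guards higher-order generation", {
  expect_error(simulate_higher_order(regime_spec("constant", K = 10,
                                                 T = 10, order = 3,
                                                 seed = 1)),
               "mem_budget")
})

test_that("group simulation shares truth and mixes signal and noise", {
  sp <- regime_spec("random", K = 5, T = 40, seed = 37)
  g <- simulate_group(sp, P = 3)
  expect_length(g$group, 3L)
  expect_false(isTRUE(all.equal(g$group[[1]], g$group[[2]])))
  expect_identical(names(g$truth), "1")
  ## noiseless limit: all participants identical
  g0 <- simulate_group(sp, P = 3, noise_weight = 0)
  expect_equal(g0$group[[1]], g0$group[[2]], tolerance = 0)
  ## determinism
  g2 <- simulate_group(sp, P = 3)
  expect_identical(g$group, g2$group)
  expect_error(simulate_group(sp, P = 1), "P must be >= 2")
})

test_that("group disfc recovers shared constant-regime structure", {
  sp <- regime_spec("constant", K = 5, T = 600, seed = 41)
  M <- NULL
  ## noiseless participants: disfc reduces to the shared signal's static
  ## correlation, which converges to the stored truth
  g0 <- simulate_group(sp, P = 6, noise_weight = 0)
  S0 <- devectorize_corr(unclass(disfc(g0$group, uniform_kernel()))[1, ])
  M <- devectorize_corr(unclass(g0$truth[["1"]])[1, ])
  expect_equal(S0[upper.tri(S0)], M[upper.tri(M)], tolerance = 0.25)
  ## with participant noise the pattern survives attenuated: the
  ## cross-participant estimate stays proportional to the truth
  g <- simulate_group(sp, P = 6, noise_weight = 0.5)
  S <- devectorize_corr(unclass(disfc(g$group, uniform_kernel()))[1, ])
  Mg <- devectorize_corr(unclass(g$truth[["1"]])[1, ])
  expect_gt(oracle_pearson(S[upper.tri(S)], Mg[upper.tri(Mg)]), 0.85)
  ## fully independent draws share no signal: off-diagonals collapse
  gi <- simulate_group(sp, P = 6, noise_weight = 1)
  Si <- devectorize_corr(unclass(disfc(gi$group, uniform_kernel()))[1, ])
  expect_lt(max(abs(Si[upper.tri(Si)])), 0.2)
})
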