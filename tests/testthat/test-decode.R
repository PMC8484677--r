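test_that("group splits obey the size rules and are reproducible", {
  s <- split_groups(10, seed = 1)
  expect_length(s$train, 5L)
  expect_length(s$test, 5L)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_setequal(c(s$train1, s$train2), s$train)
  expect_lte(abs(length(s$train1) - length(s$train2)), 1L)
  s7 <- split_groups(7, seed = 2)
  expect_setequal(sort(c(length(s7$train), length(s7$test))), c(3L, 4L))
  expect_identical(split_groups(9, seed = 5), split_groups(9, seed = 5))
  expect_error(split_groups(3), "P must be >= 4")
})

test_that("self-decoding with distinct rows is perfect", {
  set.seed(151)
  F1 <- matrix(rnorm(20 * 6), 20)
  expect_equal(decode_pair(F1, F1), 1)
})

test_that("label assignment matches a brute-force argmax on a toy case", {
  set.seed(157)
  A <- matrix(rnorm(4 * 5), 4)
  B <- matrix(rnorm(4 * 5), 4)
  L <- decode_matrix(A, B)
  expect_equal(L[2, 3], oracle_pearson(A[2, ], B[3, ]), tolerance = 1e-12)
  lab_fwd <- integer(4); lab_bwd <- integer(4)
  for (j in 1:4) {
    best <- 1
    for (i in 2:4) if (L[i, j] > L[best, j]) best <- i
    lab_fwd[j] <- best
  }
  Lt <- t(L)
  for (j in 1:4) {
    best <- 1
    for (i in 2:4) if (Lt[i, j] > Lt[best, j]) best <- i
    lab_bwd[j] <- best
  }
  acc_oracle <- (mean(lab_fwd == 1:4) + mean(lab_bwd == 1:4)) / 2
  expect_equal(decode_pair(A, B), acc_oracle)
})

test_that("noise features decode at chance and common permutations are harmless", {
  set.seed(163)
  accs <- replicate(300, {
    decode_pair(matrix(rnorm(12 * 8), 12), matrix(rnorm(12 * 8), 12))
  })
  expect_lt(abs(mean(accs) - 1 / 12), 0.015)
  ## permuting the feature columns of both groups identically
  A <- matrix(rnorm(15 * 6), 15); B <- matrix(rnorm(15 * 6), 15)
  perm <- sample(6)
  expect_equal(decode_pair(A, B), decode_pair(A[, perm], B[, perm]))
  expect_error(decode_pair(A, B[1:10, ]), "dimensions")
  expect_error(decode_matrix(rbind(A, 0)[1:15, ] * 0 + 1, A),
               "all-constant")
})

test_that("weight optimization favours the informative order", {
  set.seed(167)
  T <- 30
  shared <- matrix(rnorm(T * 10), T)
  f1 <- list(matrix(rnorm(T * 10), T),                       # order 0: noise
             shared + 0.35 * matrix(rnorm(T * 10), T))       # order 1: signal
  f2 <- list(matrix(rnorm(T * 10), T),
             shared + 0.35 * matrix(rnorm(T * 10), T))
  w <- optimize_weights(f1, f2)
  expect_gt(w$weights[2], w$weights[1])
  expect_equal(sum(w$weights), 1, tolerance = 1e-8)
  expect_true(all(w$weights >= 0))
  ## admissibility: never worse than uniform weights
  expect_gte(w$accuracy, decode_pair(f1, f2, c(0.5, 0.5)))
  ## and competitive with a dense grid search over the 2-simplex
  grid <- seq(0, 1, by = 0.01)
  grid_best <- max(vapply(grid, function(a)
    decode_pair(f1, f2, c(a, 1 - a)), numeric(1)))
  expect_gte(w$accuracy + 1e-12, grid_best - 0.05)
  ## single feasible point at n = 0
  w0 <- optimize_weights(f1[1], f2[1])
  expect_identical(w0$weights, 1)
})

test_that("run_decoding bookkeeping counts folds x kernels x orders", {
  set.seed(173)
  g <- simulate_group(regime_spec("random", K = 6, T = 30, seed = 7),
                      P = 8, noise_weight = 0.5)
  bank <- list(d = dirac_kernel(), g5 = gaussian_kernel(5))
  res <- run_decoding(g$group, max_order = 2, kernel_bank = bank,
                      folds = 2, seed = 9)
  expect_identical(nrow(res$records), 2L * 2L * 3L)
  expect_equal(res$records$relative_accuracy,
               res$records$accuracy - 1 / 30)
  expect_true(all(res$records$accuracy >= 0 &
                  res$records$accuracy <= 1))
  expect_identical(nrow(res$by_order), 3L)
  ## reproducible end to end
  res2 <- run_decoding(g$group, max_order = 2, kernel_bank = bank,
                       folds = 2, seed = 9)
  expect_identical(res$records, res2$records)
})

test_that("noiseless shared signal decodes near ceiling at order 0", {
  g <- simulate_group(regime_spec("random", K = 8, T = 40, seed = 11),
                      P = 8, noise_weight = 0)
  res <- run_decoding(g$group, max_order = 0,
                      kernel_bank = list(dirac_kernel()),
                      folds = 2, seed = 13)
  expect_gt(res$by_order$mean_accuracy[1], 0.9)
})

test_that("feature-set comparisons match the paired-t oracle", {
  set.seed(179)
  g <- simulate_group(regime_spec("random", K = 6, T = 30, seed = 17),
                      P = 8, noise_weight = 0.5)
  res <- run_decoding(g$group, max_order = 1,
                      kernel_bank = list(dirac_kernel()),
                      folds = 4, seed = 19)
  cmp <- compare_feature_sets(res)
  rec <- res$records
  a0 <- tapply(rec$accuracy[rec$max_order == 0],
               rec$fold[rec$max_order == 0], mean)
  a1 <- tapply(rec$accuracy[rec$max_order == 1],
               rec$fold[rec$max_order == 1], mean)
  if (stats::sd(a1 - a0) > 0)
    expect_equal(cmp$t["1", "0"], oracle_paired_t(a1, a0),
                 tolerance = 1e-10)
  expect_equal(unname(diag(cmp$summary_matrix)), unname(cmp$mean_weights))
  expect_equal(sum(cmp$mean_weights), 1, tolerance = 1e-8)
  ## identical distributions give t = 0, p = 1; a uniform shift gives
  ## a positive t
  ident <- list(records = data.frame(
    fold = rep(1:4, 2), kernel = "k", family = "f", width = 1,
    max_order = rep(0:1, each = 4),
    accuracy = rep(c(0.2, 0.3, 0.25, 0.35), 2),
    relative_accuracy = 0, train_accuracy = 0),
    weights = rep(list(c(0.5, 0.5)), 8), folds = 4L, max_order = 1L)
  class(ident) <- "decode_result"
  cmp2 <- compare_feature_sets(ident)
  expect_equal(cmp2$t["0", "1"], 0)
  expect_equal(cmp2$p["0", "1"], 1)
  shifted <- ident
  shifted$records$accuracy[shifted$records$max_order == 1] <-
    shifted$records$accuracy[shifted$records$max_order == 1] + 0.1
  cmp3 <- compare_feature_sets(shifted)
  expect_gt(cmp3$t["1", "0"], 0)
})

test_that("the permutation chance band brackets 1/T", {
  band <- chance_accuracy_band(50, n_average = 3, n_perm = 500, seed = 21)
  expect_lt(band["lower"], 1 / 50 + 1e-9)
  expect_gt(band["upper"], 1 / 50 - 1e-9)
  expect_lt(band["upper"], 0.2)
})
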