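test_that("framewise displacement reproduces hand-computed values", {
  m <- matrix(0, 10, 6)
  expect_true(all(framewise_displacement(m)$fd == 0))
  expect_equal(glance(framewise_displacement(m))$prop_below_threshold, 1)

  # sustained 0.3 mm x-translation step: one FD value of 0.3
  m1 <- m; m1[5:10, 1] <- 0.3
  fd1 <- framewise_displacement(m1)
  expect_equal(fd1$fd[5], 0.3)
  expect_equal(sum(fd1$fd != 0), 1)
  expect_equal(fd1$fd[1], 0)

  # 0.01 rad rotation step at 50 mm radius: 0.5 mm contribution
  m2 <- m; m2[5:10, 4] <- 0.01
  expect_equal(framewise_displacement(m2)$fd[5], 0.5)

  # translation-order invariance under permutation of the 3 translations
  set.seed(51)
  mr <- cbind(matrix(rnorm(60), 20), matrix(rnorm(60, sd = 0.01), 20))
  perm <- mr[, c(3, 1, 2, 4, 5, 6)]
  expect_equal(framewise_displacement(mr)$fd,
               framewise_displacement(perm)$fd, tolerance = 1e-12)
  expect_error(framewise_displacement(mr[, 1:5]), "6 columns")
})

test_that("TOST reproduces the printed worked examples", {
  res <- tost_equivalence(d = 0.33, delta = 0.68, n = 30)
  expect_equal(res$df, 29)
  expect_equal(res$t_upper, -1.92, tolerance = 0.005)
  # printed to two significant figures: 0.0326 prints as 0.032/0.033
  expect_lt(abs(res$p_upper - 0.032), 0.001)
  expect_true(res$equivalent)
  expect_lt(abs(one_sided_t_p(2.77, 29, "upper") - 0.005), 5e-4)

  # boundary: d at the bound gives t = 0, p = 0.5
  res2 <- tost_equivalence(d = 0.68, delta = 0.68, n = 30)
  expect_equal(res2$t_upper, 0)
  expect_equal(res2$p_upper, 0.5)
  expect_false(res2$equivalent)

  # raw-score entry converts via the SD
  res3 <- tost_equivalence(mean_diff = 0.48, sd = 1.455, n = 30,
                           delta_raw = 1.07)
  expect_equal(res3$d, 0.48 / 1.455)
  expect_equal(res3$delta, 1.07 / 1.455)
  expect_error(tost_equivalence(d = 0.1, delta = 0.5, n = 1), "n")
})

test_that("TOST verdict is monotone in the equivalence bound", {
  set.seed(52)
  for (k in 1:50) {
    d <- runif(1, -1, 1)
    n <- sample(5:50, 1)
    deltas <- sort(runif(2, 0.05, 1.5))
    lo <- tost_equivalence(d = d, delta = deltas[1], n = n)$equivalent
    hi <- tost_equivalence(d = d, delta = deltas[2], n = n)$equivalent
    expect_true(!lo || hi)   # equivalent at small bound implies at larger
  }
})

test_that("mantel test matches brute force and the reference oracle", {
  set.seed(53)
  n <- 12
  a <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
  b <- a + matrix(runif(n * n, 0, 0.5), n)
  b <- (b + t(b)) / 2; diag(b) <- 0
  res <- mantel_test(a, b, n_permutations = 500, seed = 2)
  ut <- upper.tri(a)
  expect_equal(res$r, cor(a[ut], b[ut]), tolerance = 1e-12)

  # identical matrices: r = 1 and p at the resolution floor
  res_id <- mantel_test(a, a, n_permutations = 500, seed = 2)
  expect_equal(res_id$r, 1)
  expect_equal(res_id$p, 1 / 501)

  # invariant to adding a constant off-diagonal to one matrix
  b_shift <- b + 5; diag(b_shift) <- 0
  res_shift <- mantel_test(a, b_shift, n_permutations = 300, seed = 4)
  expect_equal(res_shift$r, res$r, tolerance = 1e-10)

  expect_error(mantel_test(a, matrix(rnorm(16), 4)), "equal size")
  asym <- a; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(a, asym), "symmetric")
})

test_that("mantel r and p agree with the independent reference", {
  skip_if_not_installed("vegan")
  set.seed(54)
  n <- 15
  a <- as.matrix(stats::dist(matrix(rnorm(n * 2), n)))
  b <- as.matrix(stats::dist(matrix(rnorm(n * 2), n) +
                               0.5 * matrix(rnorm(n * 2), n)))
  ours <- mantel_test(a, b, n_permutations = 2000, seed = 5)
  ref <- vegan::mantel(a, b, permutations = 2000)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("similarity permutation test detects planted trace sharing", {
  set.seed(55)
  Tn <- 120
  shared <- rnorm(Tn)
  traces <- c(
    lapply(1:15, function(k) 0.8 * shared + rnorm(Tn)),  # condition A
    lapply(1:15, function(k) rnorm(Tn)))                  # condition B
  labels <- rep(c("gen", "non"), each = 15)
  res <- similarity_perm_test(traces, labels, mode = "trace",
                              n_permutations = 500, seed = 6)
  expect_lt(res$p_two_sided, 0.01)
  expect_gt(res$t, 0)

  # same generative process in both classes: t near 0, p large
  null_tr <- lapply(1:16, function(k) rnorm(Tn))
  res0 <- similarity_perm_test(null_tr, rep(c("gen", "non"), each = 8),
                               mode = "trace", n_permutations = 500,
                               seed = 7)
  expect_gt(res0$p_two_sided, 0.05)
  expect_error(similarity_perm_test(1:4, c("a", "a", "a", "b"),
                                    n_permutations = 100), ">= 2")
})

test_that("scalar similarity test keeps its nominal type-I rate", {
  set.seed(56)
  hits <- vapply(1:200, function(k) {
    x <- rnorm(16)
    similarity_perm_test(x, rep(c("gen", "non"), each = 8),
                         mode = "scalar", n_permutations = 120,
                         seed = 1000 + k)$p_two_sided <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("timepoint tests flag planted epochs and respect FDR nesting", {
  set.seed(57)
  n_t <- 60
  a <- matrix(rnorm(12 * n_t), 12)
  b <- matrix(rnorm(12 * n_t), 12)
  res0 <- timepoint_perm_test(a, b, n_permutations = 300, seed = 1)
  expect_equal(sum(res0$significant), 0)

  b2 <- b; b2[, 20:30] <- b2[, 20:30] + 2.5
  res1 <- timepoint_perm_test(a, b2, n_permutations = 300, seed = 2)
  expect_gt(mean(res1$significant[20:30]), 0.8)
  expect_lt(mean(res1$significant[-(20:30)]), 0.05)
  # corrected mask nested in the uncorrected p < 0.05 mask
  expect_true(all(!res1$significant | res1$p < 0.05))
  expect_error(timepoint_perm_test(a, b[, 1:10]), "equal length")
})

test_that("block averaging maps 5 Hz ratings onto the TR grid", {
  x <- rep(1:6, each = 10)
  expect_equal(block_average(x, rate_hz = 5, tr_seconds = 2), 1:6)
  expect_length(block_average(rnorm(7120), 5, 2), 712)
})
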