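test_that("pair counts match the closed form and brute force", {
  expect_equal(nrow(enumerate_pairs(30, 2)), 1740)
  expect_equal(nrow(enumerate_pairs(2, 1)), 1)
  expect_equal(nrow(enumerate_pairs(4, 2)), 24)
  expect_error(enumerate_pairs(1), ">= 2")
  for (n in 2:8) {
    for (s in 1:3) {
      # brute force: all cross-subject session pairs, unordered subjects
      brute <- 0L
      for (i in seq_len(n - 1)) for (j in (i + 1):n) brute <- brute + s * s
      p <- enumerate_pairs(n, s)
      expect_equal(nrow(p), brute)
      expect_equal(nrow(p), s^2 * n * (n - 1) / 2)
      expect_true(all(p$subject_i < p$subject_j))
      expect_equal(p$matched, seq_len(nrow(p)))
    }
  }
})

make_runs <- function(mats, conditions = NULL, subjects = NULL) {
  mask <- array(TRUE, c(nrow(mats[[1]]), 1, 1))
  lapply(seq_along(mats), function(k) {
    bold_run(mats[[k]],
             subject_id = if (is.null(subjects)) k else subjects[k],
             condition = if (is.null(conditions)) "genetic"
             else conditions[k],
             session = 1, mask = mask)
  })
}

test_that("pairwise ISC recovers exact correlations and flags degeneracy", {
  set.seed(1)
  x <- matrix(rnorm(5 * 40), 5, 40)
  runs <- make_runs(list(x, x))          # identical copy, other subject
  pz <- pairwise_isc(runs, enumerate_pairs(2, 1))
  expect_true(all(pz$z == atanh(1 - 1e-7)))

  # sine vs cosine over whole periods: exactly orthogonal
  t <- seq(0, 2 * pi, length.out = 41)[-41]
  runs2 <- make_runs(list(rbind(sin(t)), rbind(cos(t))))
  pz2 <- pairwise_isc(runs2, enumerate_pairs(2, 1))
  expect_equal(as.vector(pz2$z), 0, tolerance = 1e-12)

  # zero-variance series become missing, with a warning
  runs3 <- make_runs(list(rbind(rep(1, 40), rnorm(40)),
                          rbind(rnorm(40), rnorm(40))))
  expect_warning(pz3 <- pairwise_isc(runs3, enumerate_pairs(2, 1)),
                 "missing")
  expect_true(is.na(pz3$z[1, 1]))
  expect_false(is.na(pz3$z[2, 1]))
})

test_that("pairwise ISC is symmetric in pair order and affine-invariant", {
  set.seed(2)
  a <- matrix(rnorm(4 * 60), 4, 60)
  b <- matrix(rnorm(4 * 60), 4, 60)
  z_ab <- pairwise_isc(make_runs(list(a, b)), enumerate_pairs(2, 1))$z
  z_ba <- pairwise_isc(make_runs(list(b, a)), enumerate_pairs(2, 1))$z
  expect_equal(z_ab, z_ba, tolerance = 1e-12)
  z_scaled <- pairwise_isc(make_runs(list(3 * a - 7, b)),
                           enumerate_pairs(2, 1))$z
  expect_equal(z_ab, z_scaled, tolerance = 1e-10)
})

test_that("mean ISC equals the brute-force z-average", {
  set.seed(3)
  z <- matrix(rnorm(6 * 10, sd = 0.4), 6, 10)
  tensor <- structure(list(z = z, pairs = NULL,
                           mask = array(TRUE, c(6, 1, 1)), n_trs = 50),
                      class = "isc_tensor")
  expect_equal(mean_isc(tensor)$isc, tanh(rowMeans(z)), tolerance = 1e-12)
  # all pairs at r = 0.3 average to exactly 0.3; symmetric z cancels
  t2 <- tensor; t2$z <- matrix(atanh(0.3), 6, 10)
  expect_equal(mean_isc(t2)$isc, rep(0.3, 6))
  t3 <- tensor; t3$z <- cbind(rep(0.7, 6), rep(-0.7, 6))
  expect_equal(mean_isc(t3)$isc, rep(0, 6))
})

test_that("similarity matrix is symmetric, unit-diagonal, near zero for noise", {
  set.seed(4)
  x <- matrix(rnorm(8 * 300), 8, 300)
  runs <- make_runs(list(x, x))
  S <- assemble_similarity_matrix(runs)$matrix
  expect_equal(dim(S), c(2, 2))
  expect_equal(S[1, 2], 1, tolerance = 1e-10)
  expect_equal(diag(S), c(1, 1), ignore_attr = TRUE)

  noise <- make_runs(lapply(1:6, function(k) matrix(rnorm(8 * 300), 8)))
  Sn <- assemble_similarity_matrix(noise)$matrix
  expect_equal(Sn, t(Sn))
  off <- Sn[upper.tri(Sn)]
  expect_lt(abs(mean(off)), 3 / sqrt(300))
  # single-voxel variant agrees with direct correlation
  S1 <- assemble_similarity_matrix(noise, summary = 3)$matrix
  expect_equal(S1[1, 2], cor(noise[[1]]$data[3, ], noise[[2]]$data[3, ]),
               tolerance = 1e-10)
})

test_that("nuisance cleaning projects out confounds exactly", {
  set.seed(5)
  Tn <- 120
  mask <- array(TRUE, c(3, 1, 1))
  dat <- matrix(rnorm(3 * Tn), 3, Tn)
  run <- bold_run(dat, 1, "genetic", 1, mask)

  # a confound equal to a voxel series annihilates that voxel
  cleaned <- clean_bold(run, confounds = cbind(dat[2, ]), highpass_hz = 0)
  expect_lt(max(abs(cleaned$data[2, ])), 1e-10)

  # residuals orthogonal to every regressor column
  conf <- matrix(rnorm(Tn * 4), Tn)
  cl <- clean_bold(run, confounds = conf, highpass_hz = 0.01)
  X <- cbind(1, conf, dct_basis(Tn, 2, 0.01))
  ip <- abs(cl$data %*% X)
  norms <- sqrt(rowSums(cl$data^2)) %o% sqrt(colSums(X^2))
  expect_true(all(ip < 1e-8 * norms))

  expect_error(clean_bold(run, confounds = matrix(0, Tn + 1, 2)), "rows")
})

test_that("slow sinusoids are removed by the high-pass basis", {
  Tn <- 400; tr <- 2
  t <- (seq_len(Tn) - 1) * tr
  slow <- sin(2 * pi * 0.005 * t)
  run <- bold_run(rbind(slow), 1, "genetic", 1, array(TRUE, c(1, 1, 1)),
                  tr_seconds = tr)
  out <- clean_bold(run, highpass_hz = 0.01)$data[1, ]
  # oracle: direct regression on the sinusoid pair at that frequency
  oracle <- stats::lm.fit(cbind(1, sin(2 * pi * 0.005 * t),
                                cos(2 * pi * 0.005 * t)),
                          slow)$residuals
  expect_lt(sum(out^2) / sum(slow^2), 0.01)
  expect_lt(sum(out^2), sum(oracle^2) + 0.01 * sum(slow^2))
})

test_that("white-noise variance drops by the degrees-of-freedom fraction", {
  set.seed(6)
  Tn <- 250
  reps <- 40
  conf <- matrix(rnorm(Tn * 20), Tn)
  ratio <- vapply(seq_len(reps), function(k) {
    x <- rnorm(Tn)
    run <- bold_run(rbind(x), 1, "genetic", 1, array(TRUE, c(1, 1, 1)))
    sum(clean_bold(run, conf, highpass_hz = 0)$data^2) / sum((x - mean(x))^2)
  }, numeric(1))
  expect_equal(mean(ratio), 1 - 20 / Tn, tolerance = 0.02)
})

test_that("friston-24 expansion has the documented structure", {
  expect_error(build_friston24(matrix(0, 10, 5)), "6 columns")
  z <- build_friston24(matrix(0, 10, 6))
  expect_equal(dim(z), c(10, 24))
  expect_true(all(z == 0))

  step <- matrix(0, 10, 6); step[5:10, 1] <- 1
  f <- build_friston24(step)
  expect_equal(sum(f[, 7] != 0), 1)     # one 1 in the x-difference column
  expect_equal(unname(f[5, 7]), 1)

  set.seed(7)
  m <- matrix(rnorm(60), 10, 6)
  f2 <- build_friston24(m)
  expect_equal(f2[, 13:24], f2[, 1:12]^2, ignore_attr = TRUE)
  expect_equal(f2[1, 7:12], rep(0, 6), ignore_attr = TRUE)
})
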