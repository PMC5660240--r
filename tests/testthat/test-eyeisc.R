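make_stream <- function(x, y, fs = 250, t0 = 0) {
  n <- length(x)
  tibble::tibble(t = t0 + (seq_len(n) - 1) / fs, x = x, y = y,
                 valid = TRUE)
}

test_that("fixation detection handles the canonical cases", {
  fs <- 250
  # constant gaze for 10 s: one fixation of ~10 s at that point
  g <- make_stream(rep(1.5, 10 * fs), rep(-0.5, 10 * fs))
  fx <- detect_fixations(g)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration, 10, tolerance = 0.01)
  expect_equal(c(fx$x, fx$y), c(1.5, -0.5))

  # instantaneous 10 degree jump between stable epochs: exactly 2 fixations
  g2 <- make_stream(c(rep(0, 2 * fs), rep(10, 2 * fs)), rep(0, 4 * fs))
  fx2 <- detect_fixations(g2)
  expect_equal(nrow(fx2), 2)
  expect_equal(fx2$x, c(0, 10), tolerance = 1e-6)

  # sub-threshold jitter at 250 Hz: a reflected random walk with 0.015
  # degree steps keeps velocity <= 5.3 deg/s and acceleration well below
  # 4000 deg/s^2, so it must remain a single fixation
  set.seed(41)
  n <- 5 * fs
  jx <- cumsum(runif(n, -0.015, 0.015))
  jx <- 0.05 * sin(jx / 0.05)     # smooth reflection into [-0.05, 0.05]
  fx3 <- detect_fixations(make_stream(jx, jx * 0))
  expect_equal(nrow(fx3), 1)

  # empty stream: empty set
  expect_equal(nrow(detect_fixations(make_stream(numeric(0), numeric(0)))),
               0)
  # invalid samples split fixations
  g4 <- make_stream(rep(0, 2 * fs), rep(0, 2 * fs))
  g4$valid[200:260] <- FALSE
  expect_equal(nrow(detect_fixations(g4)), 2)
})

test_that("jitter inside thresholds never splits; drift correction is exact", {
  at <- scan_attractors(20)
  sp <- gaze_spec(20, attractors_a = at, seed = 6)
  recs <- simulate_gaze(sp, c(3, 0),
                        drift = rbind(c(0, 0), c(2, 1), c(0, 0)))
  fx <- lapply(recs, function(r) detect_fixations(r$gaze))
  corrected <- drift_correct(fx)
  means <- vapply(corrected, function(f) c(mean(f$x), mean(f$y)),
                  numeric(2))
  expect_equal(means[, 1], means[, 2], tolerance = 1e-9)
  expect_equal(means[, 1], means[, 3], tolerance = 1e-9)
  # a pure translation of the same fixations is removed exactly
  f1 <- fx[[1]]
  f2 <- f1; f2$x <- f2$x + 2; f2$y <- f2$y + 1
  cc <- drift_correct(list(f1, f2))
  expect_equal(cc[[1]]$x, cc[[2]]$x, tolerance = 1e-12)
  expect_equal(cc[[1]]$y, cc[[2]]$y, tolerance = 1e-12)
  # single recording: unchanged
  one <- drift_correct(list(f1))
  expect_equal(one[[1]]$x, f1$x, tolerance = 1e-12)
})

test_that("a 23 min 44 s recording yields 712 two-second windows", {
  dur <- 23 * 60 + 44
  fx <- tibble::tibble(onset = c(1, dur - 3), duration = c(2, 2),
                       x = c(0, 1), y = c(0, 1))
  class(fx) <- c("fixation_set", class(fx))
  hm <- window_heatmaps(fx, duration_s = dur)
  expect_equal(dim(hm$grids)[3], 712)
  expect_equal(ceiling(dur / 2), 712)
})

test_that("heatmap mass equals the number of contributing fixations", {
  fx <- tibble::tibble(onset = c(0.2, 0.5, 3.5), duration = c(0.2, 0.3, 1),
                       x = c(0, 0, 3), y = c(0, 0, -2))
  class(fx) <- c("fixation_set", class(fx))
  hm <- window_heatmaps(fx, duration_s = 4)
  expect_equal(sum(hm$grids[, , 1]), 2, tolerance = 0.004 * 2)
  expect_equal(sum(hm$grids[, , 2]), 1, tolerance = 0.004)
  expect_identical(hm$missing, rep(FALSE, 2))
  # two fixations at the same point double the peak exactly
  peak1 <- max(window_heatmaps(fx[2, ], duration_s = 2)$grids[, , 1])
  expect_equal(max(hm$grids[, , 1]), 2 * peak1, tolerance = 1e-12)
  # a fixation spanning a window boundary contributes to both windows
  fxb <- fx[3, ]                    # onset 3.5, duration 1 -> windows 2,3
  hmb <- window_heatmaps(fxb, duration_s = 6)
  expect_identical(hmb$missing, c(TRUE, FALSE, FALSE))
  expect_error(window_heatmaps(fx, duration_s = 4, resolution = 0.8),
               "resolution")
})

test_that("pairwise eISC recovers identity and spatial opposition", {
  fx_at <- function(x, y) {
    f <- tibble::tibble(onset = 0.1, duration = 1.5, x = x, y = y)
    class(f) <- c("fixation_set", class(f))
    f
  }
  hm <- lapply(list(fx_at(0, 0), fx_at(0, 0), fx_at(10, 0)),
               window_heatmaps, duration_s = 2)
  em <- eisc_pairwise(hm, groups = c("A", "A", "B"))
  # identical recordings: z at the clamp
  z12 <- em$z[1, em$pairs$rec_a == 1 & em$pairs$rec_b == 2]
  expect_equal(z12, atanh(1 - 1e-7))
  # heatmaps 10 degrees apart (disjoint support): negative correlation
  z13 <- em$z[1, em$pairs$rec_a == 1 & em$pairs$rec_b == 3]
  expect_lt(z13, 0)
  expect_equal(em$pairs$pair_class, c("both-A", "mixed", "mixed"))
})

test_that("mean eISC equals its brute-force recomputation", {
  at <- scan_attractors(12)
  recs <- simulate_gaze(gaze_spec(12, attractors_a = at, seed = 8),
                        c(3, 2))
  em <- run_gaze_pipeline(recs, 12)
  zbar <- colMeans(em$z, na.rm = TRUE)
  res <- eisc_group_test(em, n_permutations = 200, seed = 1)
  both_a <- with(em$pairs, em$groups[rec_a] == "A" & em$groups[rec_b] == "A")
  both_b <- with(em$pairs, em$groups[rec_a] == "B" & em$groups[rec_b] == "B")
  expect_equal(res$mean_eisc_a, tanh(mean(zbar[both_a])), tolerance = 1e-12)
  expect_equal(res$difference,
               tanh(mean(zbar[both_a])) - tanh(mean(zbar[both_b])),
               tolerance = 1e-12)
})

test_that("group test is invariant to label swap and coherent shifts", {
  at <- scan_attractors(16)
  sp <- gaze_spec(16, attractors_a = at, seed = 9)
  recs <- simulate_gaze(sp, c(4, 4))
  em <- run_gaze_pipeline(recs, 16)
  r1 <- eisc_group_test(em, n_permutations = 500, seed = 3)
  em2 <- em
  em2$groups <- ifelse(em$groups == "A", "B", "A")
  em2$pairs$pair_class <- ifelse(
    em$pairs$pair_class == "mixed", "mixed",
    ifelse(em$pairs$pair_class == "both-A", "both-B", "both-A"))
  r2 <- eisc_group_test(em2, n_permutations = 500, seed = 3)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$difference, -r2$difference, tolerance = 1e-12)

  # a displacement shared by every group-B recording does not move the
  # within-group statistic: same generative coherence in both groups
  at_b <- at; at_b$x <- at_b$x + 4
  sp3 <- gaze_spec(16, attractors_a = at, attractors_b = at_b, seed = 10)
  em3 <- run_gaze_pipeline(simulate_gaze(sp3, c(5, 5)), 16)
  r3 <- eisc_group_test(em3, n_permutations = 500, seed = 4)
  expect_gt(r3$p, 0.05)

  em_bad <- em
  em_bad$groups <- c(rep("A", length(em$groups) - 1), "B")
  expect_error(eisc_group_test(em_bad), "at least 2")
})

test_that("gaze QC applies the blink and event-duration rules", {
  fs <- 250
  g <- make_stream(rep(0, 10 * fs), rep(0, 10 * fs))
  expect_true(gaze_qc(g)$pass)
  g_blink <- g
  g_blink$valid[1:(3 * fs)] <- FALSE      # 30% blink time
  qc <- gaze_qc(g_blink)
  expect_gt(qc$blink_fraction, 0.25)
  expect_false(qc$pass)
})
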