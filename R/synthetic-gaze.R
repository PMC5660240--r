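#' Specify synthetic gaze recordings
#'
#' Describes how [simulate_gaze()] builds eye-position streams: fixations
#' are drawn around a time-varying sequence of spatial attractors (per
#' group), separated by fast saccadic jumps, with optional per-recording
#' constant drift. Coordinates are in degrees of visual angle, centred on
#' the screen.
#'
#' In-fixation jitter steps are bounded at 0.02 degrees per sample so
#' that, at the default 250 Hz, neither the 30 deg/s velocity nor the
#' 4000 deg/s^2 acceleration saccade threshold can fire inside a
#' fixation by construction.
#'
#' @param duration_s Recording length in seconds.
#' @param sampling_rate Samples per second (default 250).
#' @param screen_extent Degrees of visual angle, `c(width, height)`.
#' @param attractors_a,attractors_b Tibbles with columns
#'   `t0, t1, x, y, spread` describing where each group's fixations
#'   cluster in each time window; `attractors_b = NULL` reuses group A's
#'   (a null configuration).
#' @param dwell_mean_s Mean fixation dwell time (gamma-distributed).
#' @param b_displacement_deg Magnitude of a per-recording attractor
#'   displacement applied to group B in the windows listed in
#'   `b_displacement_rows`, each recording drawing its own random
#'   direction. This models divergent attention: it lowers group B's
#'   internal gaze coherence, which is what a within-group eISC contrast
#'   can detect. (A displacement shared by all group-B recordings leaves
#'   their mutual similarity — and hence the group test — unchanged.)
#' @param b_displacement_rows Integer rows of `attractors_b` affected;
#'   default all.
#' @param seed Integer seed.
#' @return Object of class `gaze_spec`.
#' @export
gaze_spec <- function(duration_s, sampling_rate = 250,
                      screen_extent = c(30, 20),
                      attractors_a = NULL, attractors_b = NULL,
                      dwell_mean_s = 0.4, b_displacement_deg = 0,
                      b_displacement_rows = NULL, seed = 1) {
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive")
  if (duration_s <= 0) abort("`duration_s` must be positive")
  if (dwell_mean_s <= 0) abort("`dwell_mean_s` must be positive")
  if (is.null(attractors_a)) {
    attractors_a <- tibble(t0 = 0, t1 = duration_s, x = 0, y = 0,
                           spread = 2)
  }
  attractors_a <- as_tibble(attractors_a)
  if (is.null(attractors_b)) attractors_b <- attractors_a
  attractors_b <- as_tibble(attractors_b)
  for (at in list(attractors_a, attractors_b)) {
    if (any(abs(at$x) > screen_extent[1] / 2 |
              abs(at$y) > screen_extent[2] / 2)) {
      abort("attractor means must lie inside `screen_extent`")
    }
  }
  if (is.null(b_displacement_rows)) {
    b_displacement_rows <- seq_len(nrow(attractors_b))
  }
  structure(list(duration_s = duration_s, sampling_rate = sampling_rate,
                 screen_extent = screen_extent,
                 attractors = list(A = attractors_a, B = attractors_b),
                 dwell_mean_s = dwell_mean_s,
                 b_displacement_deg = b_displacement_deg,
                 b_displacement_rows = b_displacement_rows,
                 seed = as.integer(seed)),
            class = "gaze_spec")
}

# one recording: sample stream following attractor-driven fixations
simulate_one_gaze <- function(spec, group, drift = c(0, 0)) {
  fs <- spec$sampling_rate
  at <- spec$attractors[[group]]
  if (group == "B" && spec$b_displacement_deg > 0) {
    theta <- runif(1, 0, 2 * pi)
    rows <- spec$b_displacement_rows
    at$x[rows] <- at$x[rows] + spec$b_displacement_deg * cos(theta)
    at$y[rows] <- at$y[rows] + spec$b_displacement_deg * sin(theta)
  }
  n <- floor(spec$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n); y <- numeric(n)
  t_cur <- 0
  i_cur <- 1L
  sacc_samples <- max(2L, round(0.02 * fs))
  pos <- c(at$x[1], at$y[1])
  while (i_cur <= n) {
    row <- which(at$t0 <= t_cur & t_cur < at$t1)
    row <- if (length(row)) row[1] else nrow(at)
    target <- c(rnorm(1, at$x[row], at$spread[row]),
                rnorm(1, at$y[row], at$spread[row]))
    half <- spec$screen_extent / 2 - 0.5
    target <- pmin(pmax(target, -half), half)
    dwell <- rgamma(1, shape = 4, rate = 4 / spec$dwell_mean_s)
    n_dwell <- max(2L, round(dwell * fs))
    # saccade: linear interpolation, velocity far above threshold
    n_s <- min(sacc_samples, n - i_cur + 1L)
    if (n_s > 0 && any(pos != target)) {
      frac <- seq_len(n_s) / n_s
      idx <- i_cur:(i_cur + n_s - 1L)
      x[idx] <- pos[1] + frac * (target[1] - pos[1])
      y[idx] <- pos[2] + frac * (target[2] - pos[2])
      i_cur <- i_cur + n_s
    }
    n_f <- min(n_dwell, n - i_cur + 1L)
    if (n_f > 0) {
      idx <- i_cur:(i_cur + n_f - 1L)
      # constant position plus bounded white jitter (sub-threshold)
      x[idx] <- target[1] + runif(n_f, -0.02, 0.02)
      y[idx] <- target[2] + runif(n_f, -0.02, 0.02)
      i_cur <- i_cur + n_f
    }
    pos <- target
    t_cur <- tt[min(i_cur, n)]
    if (n_f == 0 && n_s == 0) break
  }
  tibble(t = tt, x = x + drift[1], y = y + drift[2], valid = TRUE)
}

#' Simulate gaze recordings for two groups
#'
#' @param spec A [gaze_spec()].
#' @param n_per_group Integer vector `c(nA, nB)`; groups may be
#'   unbalanced.
#' @param drift Optional list/matrix of per-recording constant offsets
#'   (degrees); default none.
#' @return List of recordings, each a list with `gaze` (tibble
#'   `t, x, y, valid`), `group` (`"A"`/`"B"`) and `id`.
#' @export
simulate_gaze <- function(spec, n_per_group = c(10, 10), drift = NULL) {
  stopifnot(inherits(spec, "gaze_spec"))
  set.seed(spec$seed)
  n_tot <- sum(n_per_group)
  if (is.null(drift)) drift <- matrix(0, n_tot, 2)
  drift <- matrix(unlist(drift), ncol = 2, byrow = is.list(drift))
  groups <- rep(c("A", "B"), n_per_group)
  lapply(seq_len(n_tot), function(k) {
    list(gaze = simulate_one_gaze(spec, groups[k], drift[k, ]),
         group = groups[k], id = k)
  })
}
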