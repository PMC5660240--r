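#' Detect fixations in a gaze stream
#'
#' Samples whose instantaneous velocity exceeds `velocity_thresh` or
#' whose instantaneous acceleration (rate of change of speed) exceeds
#' `accel_thresh` are classed as saccade samples. Maximal runs of
#' remaining valid samples become fixations at their centroid; invalid
#' samples (blinks) split fixations.
#'
#' @param gaze Tibble/data frame with columns `t` (seconds, monotone),
#'   `x`, `y` (degrees) and optionally `valid` (logical; missing
#'   coordinates also mark samples invalid).
#' @param velocity_thresh Saccade velocity threshold in deg/s
#'   (default 30).
#' @param accel_thresh Saccade acceleration threshold in deg/s^2
#'   (default 4000).
#' @return A tibble of class `fixation_set` with columns `onset`,
#'   `duration`, `x`, `y` (time-ordered, non-overlapping).
#' @export
detect_fixations <- function(gaze, velocity_thresh = 30,
                             accel_thresh = 4000) {
  gaze <- as_tibble(gaze)
  if (!nrow(gaze)) {
    out <- tibble(onset = double(), duration = double(),
                  x = double(), y = double())
    class(out) <- c("fixation_set", class(out))
    return(out)
  }
  if (is.unsorted(gaze$t)) abort("timestamps must be monotone")
  valid <- if ("valid" %in% names(gaze)) gaze$valid else TRUE
  valid <- valid & is.finite(gaze$x) & is.finite(gaze$y)
  n <- nrow(gaze)
  dt <- diff(gaze$t)
  step <- sqrt(diff(gaze$x)^2 + diff(gaze$y)^2)
  speed <- c(0, step / dt)
  accel <- c(0, abs(diff(speed)) / dt)
  saccade <- speed > velocity_thresh | accel > accel_thresh
  # a saccade-flagged velocity implicates both samples of the step
  saccade <- saccade | c(saccade[-1], FALSE)
  keep <- valid & !saccade
  grp <- cumsum(c(TRUE, diff(keep) != 0 | !keep[-n]))
  dt_med <- if (n > 1) median(dt) else 0
  fix <- tibble(t = gaze$t, x = gaze$x, y = gaze$y,
                keep = keep, grp = grp) |>
    filter(.data$keep) |>
    group_by(.data$grp) |>
    summarise(onset = min(.data$t),
              duration = max(.data$t) - min(.data$t) + dt_med,
              x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    arrange(.data$onset) |>
    select("onset", "duration", "x", "y")
  class(fix) <- c("fixation_set", class(fix))
  fix
}

#' Quality control for a gaze recording
#'
#' Two rejection rules: the summed blink (invalid-sample) time may not
#' exceed `max_blink_fraction` of the recording, and the majority of
#' blink and saccade events must be shorter than `max_event_s`.
#'
#' @param gaze Gaze tibble as in [detect_fixations()].
#' @param velocity_thresh,accel_thresh Saccade thresholds.
#' @param max_blink_fraction Maximum tolerated blink time fraction
#'   (default 0.10).
#' @param max_event_s Blink/saccade events at least this long count
#'   against the majority rule (default 1 s).
#' @return One-row tibble: `blink_fraction`, `short_event_fraction`,
#'   `pass`.
#' @export
gaze_qc <- function(gaze, velocity_thresh = 30, accel_thresh = 4000,
                    max_blink_fraction = 0.10, max_event_s = 1) {
  gaze <- as_tibble(gaze)
  valid <- if ("valid" %in% names(gaze)) gaze$valid else
    rep(TRUE, nrow(gaze))
  valid <- valid & is.finite(gaze$x) & is.finite(gaze$y)
  n <- nrow(gaze)
  dur <- diff(range(gaze$t))
  dt <- diff(gaze$t)
  step <- sqrt(diff(gaze$x)^2 + diff(gaze$y)^2)
  speed <- c(0, step / dt)
  accel <- c(0, abs(diff(speed)) / dt)
  bad <- !valid | speed > velocity_thresh | accel > accel_thresh
  blink_fraction <- sum(!valid) / n
  runs <- rle(bad)
  dt_med <- median(dt)
  ev_dur <- runs$lengths[runs$values] * dt_med
  short_frac <- if (length(ev_dur)) mean(ev_dur < max_event_s) else 1
  tibble(blink_fraction = blink_fraction,
         short_event_fraction = short_frac,
         pass = blink_fraction <= max_blink_fraction & short_frac > 0.5,
         duration_s = dur)
}

#' Rigid drift correction of fixation sets
#'
#' Translates each recording's fixations by one constant vector so its
#' mean fixation location coincides exactly with the grand mean over all
#' recordings (the mean of per-recording means).
#'
#' @param fixation_sets List of `fixation_set` tibbles.
#' @return The corrected list; each element gains attribute `shift`
#'   (the applied translation).
#' @export
drift_correct <- function(fixation_sets) {
  if (!length(fixation_sets)) abort("need at least one fixation set")
  means <- do.call(rbind, lapply(fixation_sets, function(f) {
    c(mean(f$x), mean(f$y))
  }))
  grand <- colMeans(means)
  purrr::map2(fixation_sets, seq_along(fixation_sets), function(f, k) {
    shift <- grand - means[k, ]
    f$x <- f$x + shift[1]
    f$y <- f$y + shift[2]
    attr(f, "shift") <- shift
    f
  })
}

# truncated, unit-sum discrete Gaussian stamp (matrix of cell weights)
gaussian_stamp <- function(sigma_deg, radius_sigmas, resolution) {
  r_cells <- ceiling(sigma_deg * radius_sigmas / resolution)
  d <- (-r_cells:r_cells) * resolution
  k <- outer(d, d, function(a, b) exp(-(a^2 + b^2) / (2 * sigma_deg^2)))
  k[outer(d, d, function(a, b) sqrt(a^2 + b^2)) >
      sigma_deg * radius_sigmas] <- 0
  k / sum(k)
}

#' Windowed gaze heatmaps
#'
#' Splits the recording into consecutive windows of `window_s` seconds
#' (matching the fMRI TR) and renders, per window, the sum of unit-mass
#' Gaussian stamps (sd `sigma_deg`, truncated at `radius_sigmas` sigmas,
#' discretised and renormalised to unit sum) centred at each fixation
#' overlapping the window. Windows containing no fixation are flagged
#' missing.
#'
#' @param fixations A `fixation_set`.
#' @param duration_s Recording duration; the window count is
#'   `ceiling(duration_s / window_s)`.
#' @param window_s Window length in seconds (default 2).
#' @param sigma_deg Kernel standard deviation in degrees (default 1).
#' @param radius_sigmas Truncation radius in sigmas (default 3).
#' @param resolution Grid cell size in degrees (default 0.25, well below
#'   sigma).
#' @param screen_extent `c(width, height)` in degrees, centred on 0.
#' @return Object of class `gaze_heatmaps`: list with `grids` (3D array
#'   nx x ny x windows), `missing` (logical), geometry fields.
#' @export
window_heatmaps <- function(fixations, duration_s, window_s = 2,
                            sigma_deg = 1, radius_sigmas = 3,
                            resolution = 0.25, screen_extent = c(30, 20)) {
  if (resolution > sigma_deg / 2) {
    abort("`resolution` must be at most sigma_deg / 2")
  }
  n_win <- ceiling(duration_s / window_s)
  nx <- round(screen_extent[1] / resolution)
  ny <- round(screen_extent[2] / resolution)
  grids <- array(0, c(nx, ny, n_win))
  stamp <- gaussian_stamp(sigma_deg, radius_sigmas, resolution)
  rs <- (nrow(stamp) - 1L) / 2L
  cx <- function(x) round((x + screen_extent[1] / 2) / resolution + 0.5)
  cy <- function(y) round((y + screen_extent[2] / 2) / resolution + 0.5)
  missing <- rep(TRUE, n_win)
  for (k in seq_len(nrow(fixations))) {
    w0 <- max(1L, floor(fixations$onset[k] / window_s) + 1L)
    end <- fixations$onset[k] + fixations$duration[k]
    w1 <- min(n_win, ceiling(end / window_s))
    if (w1 < w0) next
    ix <- cx(fixations$x[k]); iy <- cy(fixations$y[k])
    sx <- max(1L, ix - rs):min(nx, ix + rs)
    sy <- max(1L, iy - rs):min(ny, iy + rs)
    if (!length(sx) || !length(sy)) next
    patch <- stamp[sx - ix + rs + 1L, sy - iy + rs + 1L, drop = FALSE]
    for (w in w0:w1) {
      grids[sx, sy, w] <- grids[sx, sy, w] + patch
      missing[w] <- FALSE
    }
  }
  structure(list(grids = grids, missing = missing, window_s = window_s,
                 resolution = resolution, screen_extent = screen_extent,
                 sigma_deg = sigma_deg),
            class = "gaze_heatmaps")
}

#' @export
print.gaze_heatmaps <- function(x, ...) {
  cat(sprintf("<gaze_heatmaps> %d windows of %gs on a %dx%d grid (%g deg/cell), %d empty\n",
              dim(x$grids)[3], x$window_s, dim(x$grids)[1],
              dim(x$grids)[2], x$resolution, sum(x$missing)))
  invisible(x)
}

#' Pairwise eye-gaze ISC matrix
#'
#' For every window and every pair of recordings, the Pearson
#' correlation between the two flattened heatmaps, stored as Fisher-Z.
#' Window-pairs where either heatmap is missing or constant are missing.
#'
#' @param heatmap_list List of `gaze_heatmaps` with identical geometry.
#' @param groups Character vector of group labels, one per recording.
#' @return Object of class `eisc_matrix`: `z` (windows x pairs),
#'   `pairs` tibble with `rec_a`, `rec_b`, `pair_class`
#'   (`"both-A"`, `"both-B"`, `"mixed"`).
#' @export
eisc_pairwise <- function(heatmap_list, groups) {
  n_rec <- length(heatmap_list)
  if (n_rec < 2) abort("need at least 2 recordings")
  if (length(groups) != n_rec) abort("one group label per recording")
  geom <- lapply(heatmap_list, function(h) dim(h$grids))
  if (length(unique(vapply(geom, paste, character(1), collapse = "x"))) != 1) {
    abort("heatmaps must share one grid geometry")
  }
  n_win <- dim(heatmap_list[[1]]$grids)[3]
  ij <- utils::combn(n_rec, 2)
  lab <- sort(unique(groups))
  pair_class <- ifelse(groups[ij[1, ]] == groups[ij[2, ]],
                       paste0("both-", groups[ij[1, ]]), "mixed")
  z <- matrix(NA_real_, n_win, ncol(ij))
  ncell <- prod(dim(heatmap_list[[1]]$grids)[1:2])
  flat <- lapply(heatmap_list, function(h) {
    matrix(h$grids, nrow = ncell)
  })
  for (w in seq_len(n_win)) {
    M <- vapply(seq_len(n_rec), function(k) flat[[k]][, w], numeric(ncell))
    ok <- !vapply(heatmap_list, function(h) h$missing[w], logical(1)) &
      apply(M, 2, sd) > 0
    if (sum(ok) < 2) next
    C <- suppressWarnings(cor(M[, ok, drop = FALSE]))
    idx_ok <- which(ok)
    for (p in seq_len(ncol(ij))) {
      a <- match(ij[1, p], idx_ok); b <- match(ij[2, p], idx_ok)
      if (!is.na(a) && !is.na(b)) z[w, p] <- fisher_z(C[a, b])
    }
  }
  structure(list(z = z,
                 pairs = tibble(pair = seq_len(ncol(ij)),
                                rec_a = ij[1, ], rec_b = ij[2, ],
                                pair_class = pair_class),
                 groups = groups),
            class = "eisc_matrix")
}

#' @export
print.eisc_matrix <- function(x, ...) {
  cat(sprintf("<eisc_matrix> %d windows x %d pairs (%s)\n",
              nrow(x$z), ncol(x$z),
              paste(names(table(x$pairs$pair_class)),
                    table(x$pairs$pair_class), collapse = ", ",
                    sep = ": ")))
  invisible(x)
}

#' Permutation group test on mean eye-gaze ISC
#'
#' Each pair's windowed Fisher-Z values are averaged over windows and
#' back-transformed to a per-pair mean eISC. The statistic contrasts the
#' (z-averaged, back-transformed) mean of both-in-group-A pairs against
#' both-in-group-B pairs; mixed pairs are excluded. The null randomly
#' relabels recordings' groups and recomputes the difference; the
#' two-sided p is the fraction of permuted |differences| at least as
#' large as observed (with the add-one floor).
#'
#' @param em An `eisc_matrix` from [eisc_pairwise()].
#' @param n_permutations Number of label permutations (default 1e5).
#' @param seed Integer seed.
#' @return One-row tibble: group means, `difference`, `p`,
#'   `n_permutations`.
#' @export
eisc_group_test <- function(em, n_permutations = 100000, seed = 1) {
  stopifnot(inherits(em, "eisc_matrix"))
  groups <- em$groups
  lab <- sort(unique(groups))
  if (length(lab) != 2) abort("exactly two groups required")
  if (any(table(groups) < 2)) abort("each group needs at least 2 recordings")
  zbar <- colMeans(em$z, na.rm = TRUE)
  zbar[is.nan(zbar)] <- NA_real_
  p1 <- em$pairs$rec_a
  p2 <- em$pairs$rec_b
  stat_for <- function(g) {
    both_a <- g[p1] == lab[1] & g[p2] == lab[1]
    both_b <- g[p1] == lab[2] & g[p2] == lab[2]
    tanh(mean(zbar[both_a], na.rm = TRUE)) -
      tanh(mean(zbar[both_b], na.rm = TRUE))
  }
  obs <- stat_for(groups)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    d <- stat_for(sample(groups))
    if (abs(d) >= abs(obs) - 1e-15) exceed <- exceed + 1L
  }
  both_a <- groups[p1] == lab[1] & groups[p2] == lab[1]
  both_b <- groups[p1] == lab[2] & groups[p2] == lab[2]
  tibble(mean_eisc_a = tanh(mean(zbar[both_a], na.rm = TRUE)),
         mean_eisc_b = tanh(mean(zbar[both_b], na.rm = TRUE)),
         difference = obs,
         p = (1 + exceed) / (1 + n_permutations),
         n_permutations = n_permutations)
}
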