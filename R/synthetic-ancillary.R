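#' Simulate ancillary recordings for a cohort
#'
#' Generates, per run of the cohort design, a 6-column rigid-body motion
#' table (3 translations in mm, 3 rotations in rad) as smooth random
#' walks with optional planted spikes, smooth positive heart- and
#' breathing-rate traces (one value per TR), and per subject-condition
#' continuous rating traces sampled at 5 Hz (valence in `[-1, 1]`,
#' arousal in `[0, 1]`).
#'
#' @param spec A [cohort_spec()]; run order matches
#'   [simulate_bold_cohort()] (subject-major, condition then session).
#' @param motion_sd Per-TR random-walk step sd for translations (mm);
#'   rotations use `motion_sd / 100` (rad). `0` gives zero motion.
#' @param spikes Optional tibble `run, tr, mm`: adds a sustained `mm`
#'   step to the x-translation of run `run` from TR `tr` on.
#' @param rating_hz Rating sampling rate (default 5).
#' @return List with `motion` (list of 6-column matrices), `heart_rate`,
#'   `breathing_rate` (lists of per-TR vectors), `valence`, `arousal`
#'   (tibble `subject_id`, `condition`, list-column `trace`), and
#'   `run_info`.
#' @export
simulate_ancillary <- function(spec, motion_sd = 0.02, spikes = NULL,
                               rating_hz = 5) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 1L)
  Tn <- spec$n_trs
  design <- tidyr::expand_grid(subject_id = seq_len(spec$n_subjects),
                               condition = c("genetic", "nongenetic"),
                               session = seq_len(spec$sessions_per_condition))
  n_runs <- nrow(design)

  motion <- lapply(seq_len(n_runs), function(k) {
    m <- cbind(
      apply(matrix(rnorm(Tn * 3, sd = motion_sd), Tn), 2, cumsum),
      apply(matrix(rnorm(Tn * 3, sd = motion_sd / 100), Tn), 2, cumsum))
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
  if (!is.null(spikes)) {
    spikes <- as_tibble(spikes)
    for (k in seq_len(nrow(spikes))) {
      r <- spikes$run[k]
      motion[[r]][spikes$tr[k]:Tn, 1] <-
        motion[[r]][spikes$tr[k]:Tn, 1] + spikes$mm[k]
    }
  }

  smooth_trace <- function(n, base, amp, floor_at = 1) {
    s <- lowpass_courses(n, 1, spec$tr_seconds, 0.03)[, 1]
    pmax(base + amp * s, floor_at)
  }
  heart <- lapply(seq_len(n_runs), function(k) smooth_trace(Tn, 62, 4))
  breathing <- lapply(seq_len(n_runs), function(k) smooth_trace(Tn, 15, 1.5))

  n_rating <- as.integer(round(Tn * spec$tr_seconds * rating_hz))
  rating_design <- tidyr::expand_grid(
    subject_id = seq_len(spec$n_subjects),
    condition = c("genetic", "nongenetic"))
  make_ratings <- function(link) {
    rating_design |>
      mutate(trace = lapply(seq_len(nrow(rating_design)), function(k) {
        link(lowpass_courses(n_rating, 1, 1 / rating_hz, 0.05)[, 1])
      }))
  }
  list(motion = motion, heart_rate = heart, breathing_rate = breathing,
       valence = make_ratings(function(s) tanh(s)),
       arousal = make_ratings(function(s) stats::plogis(s)),
       run_info = design)
}

#' Block-average a trace to the TR grid
#'
#' Averages consecutive blocks of `rate_hz * tr_seconds` samples, the
#' resampling used before comparing 5 Hz rating traces with per-TR
#' quantities.
#'
#' @param trace Numeric vector sampled at `rate_hz`.
#' @param rate_hz Input sampling rate.
#' @param tr_seconds Output block length in seconds.
#' @return Numeric vector of block means.
#' @export
block_average <- function(trace, rate_hz = 5, tr_seconds = 2) {
  k <- round(rate_hz * tr_seconds)
  n_out <- floor(length(trace) / k)
  colMeans(matrix(trace[seq_len(n_out * k)], nrow = k))
}
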