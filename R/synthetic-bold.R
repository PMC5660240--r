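#' Specify a synthetic movie-watching cohort
#'
#' Defines the study design emulated by [simulate_bold_cohort()]: every
#' subject watches the same stimulus four times, twice under each belief
#' condition (2 x 2 within-subject design), and each voxel's BOLD signal
#' is a condition-specific shared stimulus component plus subject-level
#' noise. Defaults mirror the acquisition this pipeline targets: 712 TRs
#' of 2 s (a 23 min 44 s film) on a desk-scale 16 x 16 x 8 phantom grid.
#'
#' Effect regions are voxel boxes (1-based inclusive index ranges) given a
#' coupling weight `w` in `[0, 1)` under one condition. Inside a region the
#' signal is `w * s_v(t) + noise`, where `s_v` is a per-voxel smooth
#' stimulus course shared across subjects (one independent draw per
#' condition), so the true ISC of a region voxel is
#' `c = w^2 / (w^2 + noise_sd^2)` with unit-variance courses. A region with
#' `condition = "both"` is driven by a single course shared across the two
#' conditions, which emulates the null hypothesis that belief does not
#' alter stimulus processing while keeping nonzero synchrony.
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_condition Viewings per condition per subject
#'   (default 2).
#' @param n_trs Time points per run (default 712).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @param effect_regions Tibble/data frame with columns
#'   `xmin, xmax, ymin, ymax, zmin, zmax, condition, weight`
#'   (condition in `"genetic"`, `"nongenetic"`, `"both"`). `NULL` means a
#'   pure-noise cohort.
#' @param noise_sd Standard deviation of the subject-specific noise.
#' @param lowpass_hz Cutoff of the low-pass filter shaping the shared
#'   stimulus courses (default 0.1 Hz, mimicking BOLD autocorrelation).
#' @param seed Integer seed; equal seeds give bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_bold_cohort()], [coupling_for_isc()]
#' @export
cohort_spec <- function(n_subjects, sessions_per_condition = 2,
                        n_trs = 712, tr_seconds = 2,
                        grid_shape = c(16, 16, 8),
                        effect_regions = NULL, noise_sd = 1,
                        lowpass_hz = 0.1, seed = 1) {
  if (n_subjects < 1) abort("invalid `n_subjects`: must be >= 1")
  if (sessions_per_condition < 1) {
    abort("invalid `sessions_per_condition`: must be >= 1")
  }
  if (n_trs < 2) abort("invalid `n_trs`: must be >= 2")
  if (tr_seconds <= 0) abort("invalid `tr_seconds`: must be positive")
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    abort("invalid `grid_shape`: need three positive dimensions")
  }
  if (noise_sd <= 0) abort("invalid `noise_sd`: must be positive")
  if (is.null(effect_regions)) {
    effect_regions <- tibble(xmin = integer(), xmax = integer(),
                             ymin = integer(), ymax = integer(),
                             zmin = integer(), zmax = integer(),
                             condition = character(), weight = double())
  }
  effect_regions <- as_tibble(effect_regions)
  need <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax",
            "condition", "weight")
  if (!all(need %in% names(effect_regions))) {
    abort("invalid `effect_regions`: missing columns")
  }
  if (any(!effect_regions$condition %in% c("genetic", "nongenetic", "both"))) {
    abort("invalid `effect_regions`: unknown condition label")
  }
  if (any(effect_regions$weight < 0 | effect_regions$weight >= 1)) {
    abort("invalid `effect_regions`: coupling weight must satisfy 0 <= w < 1")
  }
  with(effect_regions, {
    ok <- xmin >= 1 & ymin >= 1 & zmin >= 1 &
      xmax <= grid_shape[1] & ymax <= grid_shape[2] & zmax <= grid_shape[3] &
      xmin <= xmax & ymin <= ymax & zmin <= zmax
    if (!all(ok)) abort("invalid `effect_regions`: box outside `grid_shape`")
  })
  structure(
    list(n_subjects = as.integer(n_subjects),
         sessions_per_condition = as.integer(sessions_per_condition),
         n_trs = as.integer(n_trs), tr_seconds = tr_seconds,
         grid_shape = as.integer(grid_shape),
         effect_regions = effect_regions, noise_sd = noise_sd,
         lowpass_hz = lowpass_hz, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Coupling weight that yields a target true ISC
#'
#' Inverts `c = w^2 / (w^2 + noise_sd^2)`: `w = noise_sd * sqrt(c/(1-c))`.
#' Note `w` must stay below 1, which bounds the reachable ISC at
#' `1 / (1 + noise_sd^2)` for a given noise level.
#'
#' @param isc Target true inter-subject correlation in `[0, 1)`.
#' @param noise_sd Subject-noise standard deviation of the cohort.
#' @return The coupling weight `w`.
#' @export
coupling_for_isc <- function(isc, noise_sd = 1) {
  stopifnot(isc >= 0, isc < 1, noise_sd > 0)
  noise_sd * sqrt(isc / (1 - isc))
}

# unit-variance low-pass filtered Gaussian noise, one series per column
lowpass_courses <- function(n_trs, n_series, tr_seconds, cutoff_hz) {
  x <- matrix(rnorm(n_trs * n_series), nrow = n_trs)
  f <- seq_len(n_trs) - 1
  f <- pmin(f, n_trs - f) / (n_trs * tr_seconds)
  keep <- f <= cutoff_hz & f > 0   # drop DC; standardised below anyway
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0i
  s <- Re(stats::mvfft(xf, inverse = TRUE)) / n_trs
  s <- scale(s)                    # exactly zero mean, unit sd per course
  attr(s, "scaled:center") <- NULL
  attr(s, "scaled:scale") <- NULL
  s
}

# per-condition voxel weight vectors from the region table
region_weights <- function(spec) {
  V <- prod(spec$grid_shape)
  w <- list(genetic = numeric(V), nongenetic = numeric(V),
            both = numeric(V))
  if (nrow(spec$effect_regions)) {
    idx_grid <- array(seq_len(V), spec$grid_shape)
    for (k in seq_len(nrow(spec$effect_regions))) {
      r <- spec$effect_regions[k, ]
      vox <- as.vector(idx_grid[r$xmin:r$xmax, r$ymin:r$ymax, r$zmin:r$zmax])
      w[[r$condition]][vox] <- r$weight
    }
  }
  w
}

#' Simulate a synthetic BOLD cohort with known ground truth
#'
#' Generates `n_subjects x 2 x sessions_per_condition` runs. For a voxel
#' with coupling weight `w` under condition `k`, every run under `k`
#' carries `w * s_{k,v}(t)` (the same course for all subjects) plus
#' i.i.d. Gaussian noise, so cross-subject same-condition pairs are
#' correlated with expectation `w^2 / (w^2 + noise_sd^2)`. Voxels outside
#' all effect regions are pure noise (true ISC 0).
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `runs` (list of [bold_run], ordered
#'   subject-major, condition then session within subject) and `truth`
#'   (class `isc_ground_truth`: 3D arrays `isc_genetic`, `isc_nongenetic`
#'   and the logical `diff_mask` of voxels whose coupling differs between
#'   conditions).
#' @examples
#' regions <- tibble::tibble(xmin = 2, xmax = 4, ymin = 2, ymax = 4,
#'                           zmin = 1, zmax = 2, condition = "genetic",
#'                           weight = coupling_for_isc(0.5))
#' coh <- simulate_bold_cohort(cohort_spec(4, n_trs = 80,
#'   grid_shape = c(6, 6, 3), effect_regions = regions, seed = 7))
#' length(coh$runs)
#' @export
simulate_bold_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  V <- prod(spec$grid_shape)
  Tn <- spec$n_trs
  w <- region_weights(spec)
  mask <- array(TRUE, spec$grid_shape)

  # shared stimulus courses: only for voxels that need them
  courses <- lapply(w, function(wv) {
    act <- which(wv > 0)
    if (!length(act)) return(NULL)
    s <- lowpass_courses(Tn, length(act), spec$tr_seconds, spec$lowpass_hz)
    list(vox = act, s = t(s))      # voxels x time
  })

  signal_for <- function(cond) {
    sig <- matrix(0, V, Tn)
    for (key in c(cond, "both")) {
      cc <- courses[[key]]
      if (!is.null(cc)) {
        sig[cc$vox, ] <- sig[cc$vox, ] + w[[key]][cc$vox] * cc$s
      }
    }
    sig
  }
  signals <- list(genetic = signal_for("genetic"),
                  nongenetic = signal_for("nongenetic"))

  runs <- list()
  for (i in seq_len(spec$n_subjects)) {
    for (cond in c("genetic", "nongenetic")) {
      for (a in seq_len(spec$sessions_per_condition)) {
        eps <- matrix(rnorm(V * Tn, sd = spec$noise_sd), V, Tn)
        runs[[length(runs) + 1L]] <- bold_run(
          signals[[cond]] + eps, subject_id = i, condition = cond,
          session = a, mask = mask, tr_seconds = spec$tr_seconds)
      }
    }
  }

  isc_of <- function(cond) {
    s2 <- w[[cond]]^2 + w$both^2
    array(s2 / (s2 + spec$noise_sd^2), spec$grid_shape)
  }
  truth <- structure(
    list(isc_genetic = isc_of("genetic"),
         isc_nongenetic = isc_of("nongenetic"),
         diff_mask = array(w$genetic != w$nongenetic, spec$grid_shape),
         grid_shape = spec$grid_shape),
    class = "isc_ground_truth")
  list(runs = runs, truth = truth)
}

#' @export
print.isc_ground_truth <- function(x, ...) {
  cat(sprintf("<isc_ground_truth> %s grid, %d voxels with a planted condition difference\n",
              paste(x$grid_shape, collapse = "x"), sum(x$diff_mask)))
  invisible(x)
}

#' @rdname simulate_bold_cohort
#' @param x An `isc_ground_truth` object.
#' @param ... Unused.
#' @export
tidy.isc_ground_truth <- function(x, ...) {
  tibble(voxel = seq_along(x$isc_genetic),
         isc_genetic = as.vector(x$isc_genetic),
         isc_nongenetic = as.vector(x$isc_nongenetic),
         differs = as.vector(x$diff_mask))
}
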