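#' Canonical double-gamma haemodynamic response function
#'
#' The conventional two-gamma impulse response: a response gamma peaking
#' around 6 s minus an undershoot gamma peaking around 16 s scaled by
#' 1/6. These are the defaults of the major GLM packages for which
#' "canonical HRF" is shorthand.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay,undershoot_delay Gamma shape parameters (rate 1).
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values at `t` (zero for `t < 0`).
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 6) {
  h <- dgamma(t, shape = peak_delay, rate = 1) -
    dgamma(t, shape = undershoot_delay, rate = 1) / undershoot_ratio
  h[t < 0] <- 0
  h
}

#' Event table for the decision regressor
#'
#' One row per trial: the span from the revelation of the involved
#' identities to the button press. Events must be non-overlapping and lie
#' inside the run.
#'
#' @param onset,offset Numeric vectors of seconds into the run.
#' @param n_trs Run length in TRs.
#' @param tr_seconds Repetition time.
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(onset, offset, n_trs, tr_seconds = 2) {
  if (length(onset) != length(offset)) abort("onset/offset length mismatch")
  dur <- n_trs * tr_seconds
  if (length(onset)) {
    if (any(onset < 0) || any(offset > dur) || any(onset >= offset)) {
      abort("events must satisfy 0 <= onset < offset <= run duration")
    }
    o <- order(onset)
    onset <- onset[o]; offset <- offset[o]
    if (length(onset) > 1 && any(onset[-1] < offset[-length(offset)])) {
      abort("events overlap")
    }
  }
  out <- tibble(onset = onset, offset = offset)
  attr(out, "n_trs") <- as.integer(n_trs)
  attr(out, "tr_seconds") <- tr_seconds
  class(out) <- c("event_table", class(out))
  out
}

#' Build a first-level design matrix
#'
#' Convolves the decision boxcar (1 inside each event span) with the
#' canonical double-gamma HRF on an oversampled grid, samples it at the
#' TR acquisition times, and appends an intercept plus discrete-cosine
#' drift columns for periods longer than `highpass_seconds` (default
#' 128 s).
#'
#' @param events An [event_table()].
#' @param highpass_seconds Drift high-pass cutoff (period) in seconds.
#' @param oversample Convolution oversampling factor per TR.
#' @return List of class `glm_design`: `matrix` (TR x regressor),
#'   `names`, `decision_col`.
#' @export
build_design <- function(events, highpass_seconds = 128, oversample = 20) {
  stopifnot(inherits(events, "event_table"))
  n_trs <- attr(events, "n_trs")
  tr <- attr(events, "tr_seconds")
  dt <- tr / oversample
  tt <- seq(0, n_trs * tr - dt, by = dt)
  box <- numeric(length(tt))
  for (k in seq_len(nrow(events))) {
    box[tt >= events$onset[k] & tt < events$offset[k]] <- 1
  }
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  reg_fine <- convolve(box, rev(hrf), type = "open")[seq_along(tt)] * dt
  reg <- reg_fine[1 + (seq_len(n_trs) - 1) * oversample]
  drift <- dct_basis(n_trs, tr, 1 / highpass_seconds)
  X <- cbind(decision = reg, intercept = 1, drift)
  colnames(X) <- c("decision", "intercept",
                   if (ncol(drift)) paste0("drift", seq_len(ncol(drift))))
  structure(list(matrix = X, names = colnames(X), decision_col = 1L,
                 highpass_seconds = highpass_seconds),
            class = "glm_design")
}

#' Fit the first-level GLM per voxel
#'
#' Ordinary least squares of every voxel time series on the design;
#' returns the decision-regressor coefficient (effect size) map.
#'
#' @param run A [bold_run].
#' @param design A `glm_design` from [build_design()].
#' @return A tibble with `voxel` and `estimate` (decision beta); the 3D
#'   array version is attached as attribute `volume`.
#' @export
fit_first_level <- function(run, design) {
  stopifnot(inherits(run, "bold_run"), inherits(design, "glm_design"))
  X <- design$matrix
  if (nrow(X) != ncol(run$data)) {
    abort(sprintf("design has %d rows but the run has %d TRs",
                  nrow(X), ncol(run$data)))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- design$names[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(sprintf("design is rank deficient; collinear columns: %s",
                  paste(drop_cols, collapse = ", ")))
  }
  beta <- qr.coef(qr_x, t(run$data))
  est <- beta[design$decision_col, ]
  out <- tibble(voxel = seq_along(est), estimate = unname(est))
  attr(out, "volume") <- map_to_volume(est, run$mask)
  out
}

#' Threshold-free cluster enhancement
#'
#' Integrates, at each voxel and over all thresholds `h` in steps of
#' `dh`, the supporting-cluster extent to the power `E` times `h^H`.
#' Negative values are enhanced separately on the negated volume and
#' returned with negative sign, so both contrast directions are boosted.
#'
#' @param stat_volume 3D array of statistic values.
#' @param E,H TFCE exponents (defaults 0.5 and 2, the conventions of the
#'   permutation tools this mirrors).
#' @param dh Threshold step; default `max(abs(stat)) / 100`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D array of signed enhanced values.
#' @export
tfce_score <- function(stat_volume, E = 0.5, H = 2, dh = NULL,
                       connectivity = 26) {
  if (!is.array(stat_volume) || length(dim(stat_volume)) != 3L) {
    abort("`stat_volume` must be a 3D array")
  }
  if (!is.null(dh) && dh <= 0) abort("`dh` must be positive")
  mx <- max(abs(stat_volume), na.rm = TRUE)
  if (mx == 0) return(array(0, dim(stat_volume)))
  if (is.null(dh)) dh <- mx / 100
  v <- stat_volume
  v[is.na(v)] <- 0
  pos <- tfce_positive(array(pmax(v, 0), dim(v)), E, H, dh,
                       as.integer(connectivity))
  neg <- tfce_positive(array(pmax(-v, 0), dim(v)), E, H, dh,
                       as.integer(connectivity))
  out <- pos - neg
  array(out, dim(stat_volume))
}

#' Second-level one-sample test with TFCE and sign-flip permutations
#'
#' Computes the per-voxel one-sample t over subjects' first-level
#' contrast volumes, enhances it with [tfce_score()], and corrects
#' family-wise error by the max-TFCE distribution under random sign
#' flips of whole subject maps. Corrected p-values are one-sided in each
#' direction via the shared max-|TFCE| null.
#'
#' @param contrast_volumes List of 3D arrays (one per subject).
#' @param n_permutations Number of sign-flip permutations.
#' @param seed Integer seed.
#' @param alpha Family-wise threshold for the significance mask.
#' @param E,H,dh,connectivity TFCE parameters, see [tfce_score()].
#' @return An `isc_statmap` over all grid voxels (mask = whole grid),
#'   `statistic` = t, `p` = FWE-corrected p, plus extra element `tfce`.
#' @export
second_level_test <- function(contrast_volumes, n_permutations = 1000,
                              seed = 1, alpha = 0.05, E = 0.5, H = 2,
                              dh = NULL, connectivity = 26) {
  n <- length(contrast_volumes)
  if (n < 5) abort("need at least 5 contrast maps for sign-flip inference")
  dims <- dim(contrast_volumes[[1]])
  ok <- vapply(contrast_volumes, function(v) identical(dim(v), dims),
               logical(1))
  if (!all(ok)) abort("contrast maps must share one grid")
  M <- do.call(rbind, lapply(contrast_volumes, as.vector))

  tvec <- function(m) {
    mu <- colMeans(m)
    s <- sqrt(pmax(colSums(m^2) - n * mu^2, 0) / (n - 1))
    mu / (s / sqrt(n))
  }
  t_obs <- tvec(M)
  t_obs[!is.finite(t_obs)] <- 0
  if (is.null(dh)) dh <- max(abs(t_obs), 1e-8) / 100
  tf_obs <- tfce_score(array(t_obs, dims), E, H, dh, connectivity)

  set.seed(seed)
  max_null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    tb <- tvec(M * signs)
    tb[!is.finite(tb)] <- 0
    max_null[b] <- max(abs(tfce_score(array(tb, dims), E, H, dh,
                                      connectivity)))
  }
  p <- vapply(abs(as.vector(tf_obs)), function(v) {
    (1 + sum(max_null >= v - 1e-12)) / (1 + n_permutations)
  }, numeric(1))

  mask <- array(TRUE, dims)
  fwe_mask <- p <= alpha
  structure(
    list(statistic = t_obs, p = p, q = alpha, significant = fwe_mask,
         threshold_p = if (any(fwe_mask)) max(p[fwe_mask]) else NA_real_,
         t_threshold = if (any(fwe_mask)) min(abs(t_obs[fwe_mask]))
         else NA_real_,
         mask = mask, tail = "two-sided", n_permutations = n_permutations,
         seed = seed, tfce = tf_obs, correction = "FWE-maxTFCE"),
    class = "isc_statmap")
}
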