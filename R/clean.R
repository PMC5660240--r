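#' Discrete cosine drift basis
#'
#' Columns `cos(pi * k * (t + 0.5) / T)` for `k = 1 ... K`, the standard
#' slow-drift basis; column `k` has frequency `k / (2 * T * TR)` Hz.
#'
#' @param n_trs Run length in TRs.
#' @param tr_seconds Repetition time.
#' @param cutoff_hz Highest drift frequency to include.
#' @return Matrix with one column per retained frequency (possibly zero
#'   columns).
#' @export
dct_basis <- function(n_trs, tr_seconds, cutoff_hz) {
  k_max <- floor(2 * n_trs * tr_seconds * cutoff_hz)
  if (k_max < 1) return(matrix(numeric(0), nrow = n_trs, ncol = 0))
  t <- seq_len(n_trs) - 0.5
  vapply(seq_len(k_max),
         function(k) cos(pi * k * t / n_trs),
         numeric(n_trs))
}

#' Nuisance-clean a BOLD run
#'
#' Residualises every voxel time series against an intercept, the supplied
#' confound columns (e.g. a Friston-24 motion expansion plus tissue
#' signals) and a discrete-cosine drift basis covering frequencies below
#' `highpass_hz`, in one joint least-squares projection. Joint projection
#' (rather than sequential filtering) leaves the residuals exactly
#' orthogonal to every regressor.
#'
#' @param run A [bold_run].
#' @param confounds Numeric matrix/data frame with one row per TR, or
#'   `NULL` for drift-only cleaning.
#' @param highpass_hz High-pass cutoff in Hz (default 0.01); `0` disables
#'   the drift basis.
#' @return The cleaned [bold_run].
#' @export
clean_bold <- function(run, confounds = NULL, highpass_hz = 0.01) {
  stopifnot(inherits(run, "bold_run"))
  if (highpass_hz < 0) abort("`highpass_hz` must be >= 0")
  Tn <- ncol(run$data)
  X <- cbind(intercept = rep(1, Tn))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != Tn) {
      abort(sprintf("confounds have %d rows but the run has %d TRs",
                    nrow(confounds), Tn))
    }
    X <- cbind(X, confounds)
  }
  if (highpass_hz > 0) {
    X <- cbind(X, dct_basis(Tn, run$tr_seconds, highpass_hz))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warn(sprintf("regressor matrix rank-deficient (rank %d of %d columns); using least-squares pseudoinverse",
                 qr_x$rank, ncol(X)))
  }
  fitted <- t(qr.fitted(qr_x, t(run$data)))
  run$data <- run$data - fitted
  run
}

#' Friston-24 motion regressor expansion
#'
#' Expands 6 rigid-body motion parameters into the conventional 24-column
#' set: the parameters, their backward differences (first row zero), and
#' the element-wise squares of both.
#'
#' @param motion Matrix or data frame with 6 columns (3 translations in
#'   mm, 3 rotations in rad) and at least 2 rows.
#' @return Numeric matrix with 24 named columns.
#' @export
build_friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    abort(sprintf("motion table must have 6 columns, got %d", ncol(motion)))
  }
  if (nrow(motion) < 2L) abort("motion table must have at least 2 rows")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2, d^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp_d", 1:6),
                     paste0("mp_sq", 1:6), paste0("mp_dsq", 1:6))
  out
}
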