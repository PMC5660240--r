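#' Construct a BOLD run
#'
#' A `bold_run` holds one subject-session acquisition as a masked
#' voxel-by-time matrix together with the metadata the ISC pipeline needs:
#' subject id, belief condition (`"genetic"` / `"nongenetic"`), narrative
#' perspective, within-condition session index, the voxel mask and the
#' repetition time. The mask is a logical 3D array; row `v` of `data` is
#' the time series of the `v`-th `TRUE` voxel in array order.
#'
#' @param data Numeric matrix, masked voxels x time (TRs).
#' @param subject_id Integer or character subject identifier.
#' @param condition `"genetic"` or `"nongenetic"`.
#' @param session Within-condition session index (1-based).
#' @param mask Logical 3D array; `sum(mask)` must equal `nrow(data)`.
#' @param tr_seconds Repetition time in seconds.
#' @param perspective Optional label (`"donor"`, `"recipient"`, `"none"`).
#' @param affine Optional 4x4 voxel-to-world matrix, carried through to
#'   NIfTI output unchanged.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, subject_id, condition, session, mask,
                     tr_seconds = 2, perspective = "none", affine = NULL) {
  data <- as.matrix(data)
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a logical 3D array")
  }
  mask <- array(as.logical(mask), dim(mask))
  if (sum(mask) != nrow(data)) {
    abort(sprintf("mask selects %d voxels but `data` has %d rows",
                  sum(mask), nrow(data)))
  }
  if (!all(is.finite(data))) abort("`data` contains non-finite values")
  condition <- match.arg(condition, c("genetic", "nongenetic"))
  perspective <- match.arg(perspective, c("none", "donor", "recipient"))
  structure(
    list(data = data, subject_id = subject_id, condition = condition,
         session = as.integer(session), mask = mask,
         tr_seconds = tr_seconds, perspective = perspective,
         affine = affine),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> subject %s, %s condition, session %d: %d voxels x %d TRs (TR = %gs)\n",
              x$subject_id, x$condition, x$session,
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

# one-row tibble of run metadata
run_info <- function(run) {
  tibble(subject_id = run$subject_id, condition = run$condition,
         session = run$session, perspective = run$perspective,
         n_trs = ncol(run$data), tr_seconds = run$tr_seconds)
}

#' Summarise a list of BOLD runs
#'
#' @param runs List of [bold_run] objects.
#' @return A tibble with one row per run (subject, condition, session,
#'   perspective, length).
#' @export
runs_table <- function(runs) {
  out <- bind_rows(lapply(runs, run_info))
  out$run <- seq_len(nrow(out))
  out[, c("run", setdiff(names(out), "run"))]
}

# check runs share mask and length; returns common n_trs
check_run_compatibility <- function(runs) {
  if (length(runs) < 2L) abort("need at least 2 runs")
  lens <- vapply(runs, function(r) ncol(r$data), integer(1))
  if (length(unique(lens)) != 1L) {
    abort("all runs entering one analysis must have equal length")
  }
  m0 <- runs[[1]]$mask
  same <- vapply(runs, function(r) identical(dim(r$mask), dim(m0)) &&
                   all(r$mask == m0), logical(1))
  if (!all(same)) abort("all runs entering one analysis must share one mask")
  lens[1]
}

# rows standardised to zero mean, unit L2 norm (zero-variance rows -> NA)
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm < .Machine$double.eps^0.5 * ncol(x)] <- NA_real_
  x / nrm
}
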