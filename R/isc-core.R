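#' Enumerate cross-subject session pairs within a condition
#'
#' With two viewings per condition, each subject's two runs are compared
#' with the two runs of every other subject, so the same-condition pair
#' count is `sessions^2 * N * (N - 1) / 2` (1740 for N = 30 subjects and
#' 2 viewings). Within-subject (test-retest) pairs are excluded. The
#' `matched` column indexes the identically-constructed pair
#' `(i, j, session_a, session_b)` of the other condition, which is the
#' pairing used by matched condition contrasts.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sessions_per_condition Viewings per condition per subject.
#' @param condition Condition label carried on the pair set.
#' @return A tibble of class `isc_pairs` with columns `pair` (index),
#'   `subject_i`, `session_a`, `subject_j`, `session_b`, `condition`,
#'   `matched`.
#' @examples
#' nrow(enumerate_pairs(30, 2))  # 1740
#' @export
enumerate_pairs <- function(n_subjects, sessions_per_condition = 2,
                            condition = "genetic") {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2")
  if (sessions_per_condition < 1) abort("`sessions_per_condition` must be >= 1")
  ij <- utils::combn(n_subjects, 2)
  grid <- tidyr::expand_grid(
    k = seq_len(ncol(ij)),
    session_a = seq_len(sessions_per_condition),
    session_b = seq_len(sessions_per_condition))
  out <- tibble(
    pair = seq_len(nrow(grid)),
    subject_i = ij[1, grid$k],
    session_a = grid$session_a,
    subject_j = ij[2, grid$k],
    session_b = grid$session_b,
    condition = condition,
    matched = seq_len(nrow(grid)))
  class(out) <- c("isc_pairs", class(out))
  out
}

# index runs by (subject, condition, session); errors on gaps/duplicates
run_index <- function(runs) {
  info <- runs_table(runs)
  key <- paste(info$subject_id, info$condition, info$session)
  if (anyDuplicated(key)) abort("duplicate (subject, condition, session) run")
  stats::setNames(info$run, key)
}

#' Per-voxel pairwise inter-subject correlations
#'
#' For every pair in `pairs`, computes the Pearson correlation over time
#' between the two runs' time series at each voxel and stores the
#' Fisher-Z transform. Zero-variance time series yield a missing value
#' for that voxel-pair (never zero) and are excluded from downstream
#' averages.
#'
#' @param runs List of [bold_run] objects covering every run the pair set
#'   references (equal length, common mask).
#' @param pairs An `isc_pairs` tibble from [enumerate_pairs()].
#' @return An object of class `isc_tensor`: list with `z` (voxel x pair
#'   matrix of Fisher-Z values), `pairs`, `mask`, `n_trs`.
#' @export
pairwise_isc <- function(runs, pairs) {
  n_trs <- check_run_compatibility(runs)
  idx <- run_index(runs)
  Z <- lapply(runs, function(r) standardize_rows(r$data))
  cond <- unique(pairs$condition)
  get <- function(subj, sess, cond) {
    k <- idx[paste(subj, cond, sess)]
    if (is.na(k)) abort(sprintf("run not found: subject %s %s session %s",
                                subj, cond, sess))
    k
  }
  zmat <- matrix(NA_real_, nrow = nrow(runs[[1]]$data), ncol = nrow(pairs))
  n_missing <- 0L
  for (p in seq_len(nrow(pairs))) {
    a <- Z[[get(pairs$subject_i[p], pairs$session_a[p], pairs$condition[p])]]
    b <- Z[[get(pairs$subject_j[p], pairs$session_b[p], pairs$condition[p])]]
    r <- rowSums(a * b)
    zmat[, p] <- ifelse(is.na(r), NA_real_, fisher_z(ifelse(is.na(r), 0, r)))
    n_missing <- n_missing + sum(is.na(r))
  }
  if (n_missing > 0) {
    warn(sprintf("%d zero-variance voxel-pair cells recorded as missing",
                 n_missing))
  }
  structure(list(z = zmat, pairs = pairs, mask = runs[[1]]$mask,
                 n_trs = n_trs),
            class = "isc_tensor")
}

#' @export
print.isc_tensor <- function(x, ...) {
  cat(sprintf("<isc_tensor> %d voxels x %d pairs (T = %d)\n",
              nrow(x$z), ncol(x$z), x$n_trs))
  invisible(x)
}

#' Mean ISC map from a pair tensor
#'
#' Averages the Fisher-Z values over valid pairs at each voxel and
#' back-transforms to the correlation scale. Voxels with no valid pair
#' are missing.
#'
#' @param tensor An `isc_tensor` from [pairwise_isc()].
#' @return A tibble with columns `voxel` (mask-relative index) and `isc`.
#' @export
mean_isc <- function(tensor) {
  stopifnot(inherits(tensor, "isc_tensor"))
  tibble(voxel = seq_len(nrow(tensor$z)),
         isc = apply(tensor$z, 1, z_mean_r))
}

#' Assemble the full run-by-run similarity matrix
#'
#' Correlates every pair of runs — including a subject's own two viewings
#' and cross-condition cells — either at one voxel or averaged over all
#' mask voxels (the mean over voxels of the per-voxel Pearson r). For 30
#' subjects with 4 sessions each this is the 120 x 120 matrix summarising
#' the whole design.
#'
#' @param runs List of [bold_run] objects.
#' @param summary `"mean"` (average per-voxel correlation over the mask)
#'   or a single voxel index (mask-relative).
#' @return An object of class `isc_similarity`: the symmetric
#'   unit-diagonal matrix plus a `runs` label tibble.
#' @export
assemble_similarity_matrix <- function(runs, summary = "mean") {
  check_run_compatibility(runs)
  info <- runs_table(runs)
  if (identical(summary, "mean")) {
    V <- nrow(runs[[1]]$data)
    M <- do.call(rbind, lapply(runs, function(r) {
      as.vector(standardize_rows(r$data))
    }))
    M[is.na(M)] <- 0  # zero-variance voxels drop out of the average
    S <- tcrossprod(M) / V
  } else {
    v <- as.integer(summary)
    M <- do.call(rbind, lapply(runs, function(r) {
      x <- r$data[v, ]
      x <- x - mean(x)
      n <- sqrt(sum(x^2))
      if (n == 0) rep(NA_real_, length(x)) else x / n
    }))
    S <- tcrossprod(M)
  }
  diag(S) <- 1
  lab <- sprintf("s%s_%s_%d", info$subject_id, info$condition, info$session)
  dimnames(S) <- list(lab, lab)
  structure(list(matrix = S, runs = info), class = "isc_similarity")
}

#' @export
print.isc_similarity <- function(x, ...) {
  cat(sprintf("<isc_similarity> %d x %d runs, mean off-diagonal %.3f\n",
              nrow(x$matrix), ncol(x$matrix),
              mean(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' @rdname assemble_similarity_matrix
#' @param x An `isc_similarity` object.
#' @param ... Unused.
#' @export
tidy.isc_similarity <- function(x, ...) {
  S <- x$matrix
  ut <- which(upper.tri(S), arr.ind = TRUE)
  tibble(run_a = rownames(S)[ut[, 1]], run_b = colnames(S)[ut[, 2]],
         similarity = S[ut])
}
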