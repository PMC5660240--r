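#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up control of the false discovery rate at level `q`: sort the m
#' p-values, find the largest k with `p_(k) <= k * q / m`, and reject all
#' p-values up to `p_(k)`. Missing p-values are left out of m and never
#' rejected.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param q FDR level (default 0.05).
#' @return List with `mask` (logical rejections), `cutoff` (largest
#'   rejected p, `NA` if none) and `adjusted` (BH-adjusted p-values).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))$mask
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) return(list(mask = logical(0), cutoff = NA_real_,
                              adjusted = numeric(0)))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  adj[ok] <- p.adjust(p[ok], method = "BH")
  mask <- !is.na(adj) & adj <= q
  cutoff <- if (any(mask)) max(p[mask]) else NA_real_
  list(mask = mask, cutoff = cutoff, adjusted = adj)
}

# two-sided / one-sided permutation p with the (1 + k) / (1 + n) floor
perm_p <- function(obs, perm_mat, tail = c("two-sided", "greater", "less")) {
  tail <- match.arg(tail)
  n <- ncol(perm_mat)
  exceed <- switch(tail,
    "two-sided" = rowSums(abs(perm_mat) >= abs(obs) - 1e-12, na.rm = TRUE),
    "greater"   = rowSums(perm_mat >= obs - 1e-12, na.rm = TRUE),
    "less"      = rowSums(perm_mat <= obs + 1e-12, na.rm = TRUE))
  (1 + exceed) / (1 + n)
}

# rowwise one-sample t against 0, NA-aware
row_one_sample_t <- function(d) {
  nv <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  ss <- rowSums(d^2, na.rm = TRUE) - nv * m^2
  s <- sqrt(pmax(ss, 0) / pmax(nv - 1, 1))
  t <- m / (s / sqrt(nv))
  t[s == 0 & m == 0] <- 0   # degenerate all-equal differences
  t[nv < 2] <- NA_real_
  t
}

new_stat_map <- function(statistic, p, q, mask, tail, n_permutations, seed,
                         extra = list()) {
  fdr <- bh_fdr(p, q)
  structure(
    c(list(statistic = statistic, p = p, q = q,
           significant = fdr$mask, threshold_p = fdr$cutoff,
           t_threshold = if (any(fdr$mask))
             min(abs(statistic[fdr$mask]), na.rm = TRUE) else NA_real_,
           mask = mask, tail = tail,
           n_permutations = n_permutations, seed = seed),
      extra),
    class = "isc_statmap")
}

#' @export
print.isc_statmap <- function(x, ...) {
  cat(sprintf("<isc_statmap> %d voxels, %d significant at FDR q < %g (%s, %d permutations)\n",
              length(x$p), sum(x$significant), x$q, x$tail,
              x$n_permutations))
  invisible(x)
}

#' Tidy a statistical map
#'
#' @param x An `isc_statmap`.
#' @param ... Unused.
#' @return A tibble with one row per mask voxel: `voxel`, `statistic`,
#'   `p`, `significant`.
#' @export
tidy.isc_statmap <- function(x, ...) {
  tibble(voxel = seq_along(x$p), statistic = x$statistic, p = x$p,
         significant = x$significant)
}

#' @rdname tidy.isc_statmap
#' @return For `glance()`: a one-row tibble with the FDR level, adaptive
#'   thresholds, significant-voxel count and permutation settings.
#' @export
glance.isc_statmap <- function(x, ...) {
  tibble(n_voxels = length(x$p), n_significant = sum(x$significant),
         q = x$q, threshold_p = x$threshold_p,
         t_threshold = x$t_threshold, tail = x$tail,
         n_permutations = x$n_permutations)
}

# reconstruct a statistic vector into a 3D array over the mask
map_to_volume <- function(values, mask, fill = NA_real_) {
  vol <- array(fill, dim(mask))
  vol[mask] <- values
  vol
}

#' Extract a volume from a statistical map
#'
#' @param map An `isc_statmap`.
#' @param what `"statistic"`, `"p"` or `"significant"`.
#' @return A 3D array on the map's grid (`NA`/0 outside the mask).
#' @export
statmap_volume <- function(map, what = c("statistic", "p", "significant")) {
  what <- match.arg(what)
  v <- map[[what]]
  map_to_volume(if (is.logical(v)) v * 1 else v, map$mask)
}

# enumerate cross-subject run-index pairs from a run list
cross_subject_run_pairs <- function(info) {
  ij <- utils::combn(nrow(info), 2)
  keep <- info$subject_id[ij[1, ]] != info$subject_id[ij[2, ]]
  ij[, keep, drop = FALSE]
}

# Fisher-Z correlations for a set of run-index pairs (voxel x pair)
run_pair_z <- function(Zstd, pair_idx) {
  out <- matrix(NA_real_, nrow(Zstd[[1]]), ncol(pair_idx))
  for (p in seq_len(ncol(pair_idx))) {
    r <- rowSums(Zstd[[pair_idx[1, p]]] * Zstd[[pair_idx[2, p]]])
    out[, p] <- ifelse(is.na(r), NA_real_, fisher_z(ifelse(is.na(r), 0, r)))
  }
  out
}

#' One-group ISC significance test
#'
#' Tests, per voxel, whether the mean cross-subject Fisher-Z correlation
#' exceeds what survives destroying temporal alignment. The null is built
#' by circularly time-shifting every run by an independent random offset
#' (at least `min_shift` TRs) and recomputing the mean pairwise z-map;
#' the one-sided p compares the observed mean to this surrogate
#' distribution, followed by BH-FDR at `q`.
#'
#' @param runs List of [bold_run] objects forming the group (one or more
#'   sessions per subject; within-subject pairs are never formed).
#' @param n_permutations Number of surrogate shifts (>= 100).
#' @param seed Integer seed for the shift draws.
#' @param q FDR level.
#' @param min_shift Minimum circular offset in TRs.
#' @return An `isc_statmap` whose `statistic` is the per-voxel mean
#'   Fisher-Z ISC (additional element `mean_isc` holds the
#'   back-transformed map).
#' @export
isc_one_group_test <- function(runs, n_permutations = 1000, seed = 1,
                               q = 0.05, min_shift = 10) {
  if (length(runs) < 2) abort("need at least 2 runs")
  if (n_permutations < 100) abort("`n_permutations` must be >= 100")
  Tn <- check_run_compatibility(runs)
  if (Tn <= 2 * min_shift) abort("runs too short for the requested `min_shift`")
  info <- runs_table(runs)
  pair_idx <- cross_subject_run_pairs(info)
  if (!ncol(pair_idx)) abort("no cross-subject pairs available")
  Zstd <- lapply(runs, function(r) standardize_rows(r$data))

  obs <- rowMeans(run_pair_z(Zstd, pair_idx), na.rm = TRUE)

  set.seed(seed)
  perm <- matrix(NA_real_, length(obs), n_permutations)
  for (b in seq_len(n_permutations)) {
    shifts <- sample(seq(min_shift, Tn - min_shift), length(runs),
                     replace = TRUE)
    Zs <- map2(Zstd, shifts, function(z, s) {
      z[, c((s + 1):Tn, 1:s), drop = FALSE]
    })
    perm[, b] <- rowMeans(run_pair_z(Zs, pair_idx), na.rm = TRUE)
  }
  p <- perm_p(obs, perm, "greater")
  new_stat_map(obs, p, q, runs[[1]]$mask, "greater", n_permutations, seed,
               extra = list(mean_isc = tanh(obs)))
}

#' Build a matched condition-contrast design
#'
#' Computes the Fisher-Z correlation tensor over *all* cross-subject
#' session pairs of a 2-condition cohort — including the mixed-condition
#' cells — and records which columns form the matched genetic /
#' non-genetic pair sets. Keeping the mixed cells is what lets
#' [isc_condition_contrast()] re-pool the statistic exactly under
#' subject-level condition-label flips.
#'
#' @param runs List of [bold_run] objects: every subject must have the
#'   same number of sessions under each of the two conditions.
#' @return An object of class `isc_contrast_design`.
#' @export
contrast_design <- function(runs) {
  check_run_compatibility(runs)
  info <- runs_table(runs)
  subjects <- unique(info$subject_id)
  sess <- sort(unique(info$session))
  combos <- tidyr::expand_grid(subject_id = subjects,
                               condition = c("genetic", "nongenetic"),
                               session = sess)
  have <- dplyr::anti_join(combos, info,
                           by = c("subject_id", "condition", "session"))
  if (nrow(have)) {
    abort("every subject needs the same sessions under both conditions")
  }
  if (length(subjects) < 2) abort("need at least 2 subjects")

  Zstd <- lapply(runs, function(r) standardize_rows(r$data))
  pair_idx <- cross_subject_run_pairs(info)
  zmat <- run_pair_z(Zstd, pair_idx)

  n_runs <- nrow(info)
  colof <- matrix(NA_integer_, n_runs, n_runs)
  colof[t(pair_idx)] <- seq_len(ncol(pair_idx))
  colof[t(pair_idx[2:1, , drop = FALSE])] <- seq_len(ncol(pair_idx))

  # run id lookup: subject x condition x session
  runid <- array(NA_integer_,
                 c(length(subjects), 2, length(sess)),
                 dimnames = list(as.character(subjects),
                                 c("genetic", "nongenetic"), NULL))
  for (k in seq_len(n_runs)) {
    runid[as.character(info$subject_id[k]), info$condition[k],
          info$session[k]] <- k
  }

  si <- utils::combn(length(subjects), 2)
  slots <- tidyr::expand_grid(k = seq_len(ncol(si)),
                              session_a = sess, session_b = sess)
  structure(
    list(z = zmat, colof = colof, runid = runid,
         slot_i = si[1, slots$k], slot_j = si[2, slots$k],
         slot_a = slots$session_a, slot_b = slots$session_b,
         n_subjects = length(subjects),
         sessions_per_condition = length(sess),
         mask = runs[[1]]$mask),
    class = "isc_contrast_design")
}

#' @export
print.isc_contrast_design <- function(x, ...) {
  cat(sprintf("<isc_contrast_design> %d subjects x %d sessions/condition: %d matched pairs, %d tensor columns\n",
              x$n_subjects, x$sessions_per_condition,
              length(x$slot_i), ncol(x$z)))
  invisible(x)
}

# pooled matched-pair delta-z matrix under a condition assignment;
# flip[i] TRUE means subject i's labels are swapped
contrast_delta <- function(design, flip) {
  condA <- ifelse(flip, 2L, 1L)           # 1 = genetic, 2 = nongenetic
  condB <- 3L - condA
  a1 <- design$runid[cbind(design$slot_i, condA[design$slot_i], design$slot_a)]
  a2 <- design$runid[cbind(design$slot_j, condA[design$slot_j], design$slot_b)]
  b1 <- design$runid[cbind(design$slot_i, condB[design$slot_i], design$slot_a)]
  b2 <- design$runid[cbind(design$slot_j, condB[design$slot_j], design$slot_b)]
  design$z[, design$colof[cbind(a1, a2)], drop = FALSE] -
    design$z[, design$colof[cbind(b1, b2)], drop = FALSE]
}

#' Between-condition ISC contrast with subject-level permutations
#'
#' Per voxel, the statistic is the one-sample t of the matched pooled
#' pair differences `dz = z_genetic - z_nongenetic` (every cross-subject
#' session pair under one condition matched with the identically indexed
#' pair under the other). The null relabels conditions at the subject
#' level: each subject's sessions are swapped between conditions with
#' probability 1/2 and the full pooled statistic is recomputed from the
#' complete pair tensor (mixed-condition cells included). Two-sided
#' p-values are BH-FDR corrected at `q`.
#'
#' @param design An `isc_contrast_design` from [contrast_design()], or a
#'   list of [bold_run] objects (the design is then built internally).
#' @param n_permutations Number of subject-label permutations (>= 100).
#' @param seed Integer seed.
#' @param q FDR level (default 0.05).
#' @return An `isc_statmap` with the per-voxel t, permutation p, FDR mask
#'   and (extra element) `delta_z`, the mean pooled z-difference map.
#' @export
isc_condition_contrast <- function(design, n_permutations = 1000, seed = 1,
                                   q = 0.05) {
  if (!inherits(design, "isc_contrast_design")) {
    design <- contrast_design(design)
  }
  if (n_permutations < 100) abort("`n_permutations` must be >= 100")
  d_obs <- contrast_delta(design, rep(FALSE, design$n_subjects))
  if (all(is.na(d_obs))) abort("no matched pairs with valid correlations")
  t_obs <- row_one_sample_t(d_obs)

  set.seed(seed)
  perm <- matrix(NA_real_, length(t_obs), n_permutations)
  for (b in seq_len(n_permutations)) {
    flip <- sample(c(TRUE, FALSE), design$n_subjects, replace = TRUE)
    perm[, b] <- row_one_sample_t(contrast_delta(design, flip))
  }
  p <- perm_p(t_obs, perm, "two-sided")
  p[is.na(t_obs)] <- NA_real_
  new_stat_map(t_obs, p, q, design$mask, "two-sided", n_permutations, seed,
               extra = list(delta_z = rowMeans(d_obs, na.rm = TRUE)))
}

#' Cluster-extent filter for significance masks
#'
#' Removes connected components smaller than `min_extent` voxels from a
#' 3D significance mask (default 64 = 4 x 4 x 4). Connectivity is
#' 6-neighbour by default (faces only); 18 and 26 are available.
#'
#' @param mask Logical 3D array.
#' @param min_extent Minimum surviving component size in voxels.
#' @param connectivity 6, 18 or 26.
#' @return The filtered logical 3D array.
#' @export
cluster_filter <- function(mask, min_extent = 64, connectivity = 6) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3D array")
  }
  if (min_extent < 1) abort("`min_extent` must be >= 1")
  if (!connectivity %in% c(6, 18, 26)) abort("connectivity must be 6, 18 or 26")
  lab <- label_components_3d(array(as.double(mask != 0), dim(mask)),
                             as.integer(connectivity))
  keep <- which(tabulate(lab) >= min_extent)
  array(lab %in% keep, dim(mask))
}

#' Conjunction of two p-maps by the maximum p-value
#'
#' The intersection-union test: at each voxel the conjunction p is
#' `max(p_A, p_B)`, then BH-FDR is applied at `q`; a voxel survives only
#' if both analyses are individually reliable there.
#'
#' @param p_a,p_b Numeric vectors or arrays of p-values on the same grid.
#' @param q FDR level.
#' @return List with `p` (max-p values, same shape as input), `mask`
#'   (conjunction FDR mask) and `cutoff`.
#' @export
conjunction_max_p <- function(p_a, p_b, q = 0.05) {
  if (!identical(dim(p_a) %||% length(p_a), dim(p_b) %||% length(p_b))) {
    abort("p-maps must share one voxel space")
  }
  pmax_map <- pmax(p_a, p_b)
  fdr <- bh_fdr(as.vector(pmax_map), q)
  mask <- fdr$mask
  if (!is.null(dim(p_a))) {
    pmax_map <- array(pmax_map, dim(p_a))
    mask <- array(mask, dim(p_a))
  }
  list(p = pmax_map, mask = mask, cutoff = fdr$cutoff)
}
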