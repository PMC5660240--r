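#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum |d translations| + radius * sum |d rotations|`: backward
#' differences of the three translations (mm) plus the three rotations
#' (rad) converted to arc length on a sphere of `rotation_radius_mm`
#' (default 50 mm, the head-size convention of the motion-QC
#' literature). The first frame has FD 0.
#'
#' @param motion 6-column matrix/data frame: translations mm, rotations
#'   rad.
#' @param rotation_radius_mm Sphere radius for the rotation-to-mm
#'   conversion.
#' @param threshold_mm QC threshold (default 0.5 mm).
#' @return A tibble of class `fd_trace` with columns `tr`, `fd`;
#'   `glance()` reports mean FD, the fraction of TRs below threshold and
#'   the 90%-rule verdict.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50,
                                   threshold_mm = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    abort(sprintf("motion table must have 6 columns, got %d", ncol(motion)))
  }
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  out <- tibble(tr = seq_along(fd), fd = fd)
  attr(out, "threshold_mm") <- threshold_mm
  class(out) <- c("fd_trace", class(out))
  out
}

#' @rdname framewise_displacement
#' @param x An `fd_trace`.
#' @param ... Unused.
#' @export
glance.fd_trace <- function(x, ...) {
  thr <- attr(x, "threshold_mm")
  frac <- mean(x$fd < thr)
  tibble(mean_fd = mean(x$fd), prop_below_threshold = frac,
         threshold_mm = thr, pass_90pct_rule = frac >= 0.9)
}

#' Permutation test on pairwise similarity between conditions
#'
#' Builds a pairwise similarity for every pair of recordings — the
#' negative absolute difference of scalar summaries (`"scalar"` mode,
#' e.g. mean framewise displacement) or the Fisher-Z trace correlation
#' (`"trace"` mode, e.g. heart-rate traces) — and contrasts
#' same-condition-A against same-condition-B pair similarities with a
#' two-sample t. The null permutes the recordings' condition labels and
#' recomputes the statistic; mixed pairs never enter.
#'
#' @param x Numeric vector of scalars, or list of equal-length numeric
#'   traces (one per recording).
#' @param labels Condition label per recording (two levels).
#' @param mode `"scalar"` or `"trace"`.
#' @param n_permutations Number of label permutations (default 5000).
#' @param seed Integer seed.
#' @return One-row tibble: `t`, `p_two_sided`, `p_greater`,
#'   `n_permutations`.
#' @export
similarity_perm_test <- function(x, labels, mode = c("scalar", "trace"),
                                 n_permutations = 5000, seed = 1) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  lab <- sort(unique(labels))
  if (length(lab) != 2) abort("exactly two condition labels required")
  if (any(table(labels) < 2)) abort("each condition needs >= 2 recordings")
  n <- length(labels)
  if (mode == "scalar") {
    x <- as.numeric(x)
    if (length(x) != n) abort("one value per recording required")
    sim_mat <- -abs(outer(x, x, "-"))
  } else {
    if (!is.list(x) || length(x) != n) abort("one trace per recording required")
    lens <- lengths(x)
    if (length(unique(lens)) != 1) abort("traces must have equal length")
    M <- do.call(cbind, x)
    sim_mat <- fisher_z(cor(M))
  }
  ij <- utils::combn(n, 2)
  sims <- sim_mat[t(ij)]
  two_sample_t <- function(g) {
    a <- sims[g[ij[1, ]] == lab[1] & g[ij[2, ]] == lab[1]]
    b <- sims[g[ij[1, ]] == lab[2] & g[ij[2, ]] == lab[2]]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  t_obs <- two_sample_t(labels)
  set.seed(seed)
  n_two <- 0L
  n_ge <- 0L
  for (b in seq_len(n_permutations)) {
    tp <- two_sample_t(sample(labels))
    if (abs(tp) >= abs(t_obs) - 1e-12) n_two <- n_two + 1L
    if (tp >= t_obs - 1e-12) n_ge <- n_ge + 1L
  }
  tibble(t = t_obs,
         p_two_sided = (1 + n_two) / (1 + n_permutations),
         p_greater = (1 + n_ge) / (1 + n_permutations),
         n_permutations = n_permutations)
}

#' One-sided p-value from a t statistic
#'
#' @param t t statistic.
#' @param df Degrees of freedom.
#' @param tail `"lower"` (P(T <= t)) or `"upper"` (P(T >= t)).
#' @return The one-sided p-value.
#' @export
one_sided_t_p <- function(t, df, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  pt(t, df, lower.tail = tail == "lower")
}

#' TOST equivalence test on a standardised mean difference
#'
#' Two one-sided tests of H0 "the effect lies outside `[-delta, delta]`"
#' for a one-sample / paired design: `t_upper = (d - delta) * sqrt(n)`
#' tested against its lower tail and `t_lower = (d + delta) * sqrt(n)`
#' against its upper tail, both on `n - 1` degrees of freedom.
#' Equivalence is declared when both one-sided p-values fall below
#' `alpha`. Raw-score input (`mean_diff`, `sd`, `delta_raw`) is converted
#' to the d scale by the sample SD.
#'
#' @param d Observed standardised mean difference (Cohen's d).
#' @param delta Equivalence bound on the d scale (> 0).
#' @param n Sample size (>= 2).
#' @param alpha One-sided test level (default 0.05).
#' @param mean_diff,sd,delta_raw Raw-scale alternative to `d`/`delta`.
#' @return One-row tibble of class `tost_result`: `d`, `delta`, `n`,
#'   `df`, `t_upper`, `p_upper`, `t_lower`, `p_lower`, `equivalent`.
#' @examples
#' tost_equivalence(d = 0.33, delta = 0.68, n = 30)
#' @export
tost_equivalence <- function(d = NULL, delta = NULL, n, alpha = 0.05,
                             mean_diff = NULL, sd = NULL,
                             delta_raw = NULL) {
  if (n < 2) abort("`n` must be >= 2")
  if (is.null(d)) {
    if (is.null(mean_diff) || is.null(sd)) {
      abort("provide `d` or (`mean_diff`, `sd`)")
    }
    d <- mean_diff / sd
  }
  if (is.null(delta)) {
    if (is.null(delta_raw) || is.null(sd)) {
      abort("provide `delta` or (`delta_raw`, `sd`)")
    }
    delta <- delta_raw / sd
  }
  if (delta <= 0) abort("`delta` must be positive")
  df <- n - 1
  t_upper <- (d - delta) * sqrt(n)
  t_lower <- (d + delta) * sqrt(n)
  p_upper <- pt(t_upper, df)                      # H0: effect >= +delta
  p_lower <- pt(t_lower, df, lower.tail = FALSE)  # H0: effect <= -delta
  out <- tibble(d = d, delta = delta, n = as.integer(n), df = df,
                t_upper = t_upper, p_upper = p_upper,
                t_lower = t_lower, p_lower = p_lower,
                equivalent = p_upper < alpha & p_lower < alpha)
  class(out) <- c("tost_result", class(out))
  out
}

#' Mantel test between two similarity matrices
#'
#' Pearson correlation of the off-diagonal upper triangles; the null is
#' built by jointly permuting the rows and columns of the second matrix.
#' The p-value is one-sided for positive association with the add-one
#' floor.
#'
#' @param a,b Square symmetric matrices of equal size.
#' @param n_permutations Number of row/column permutations
#'   (default 5000).
#' @param seed Integer seed.
#' @return One-row tibble of class `mantel_result`: `r`, `p`,
#'   `n_permutations`.
#' @export
mantel_test <- function(a, b, n_permutations = 5000, seed = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || nrow(a) != ncol(a)) {
    abort("matrices must be square and of equal size")
  }
  if (!isSymmetric(unname(a), tol = 1e-8) ||
        !isSymmetric(unname(b), tol = 1e-8)) {
    abort("matrices must be symmetric")
  }
  ut <- upper.tri(a)
  r_obs <- cor(a[ut], b[ut])
  set.seed(seed)
  exceed <- 0L
  for (k in seq_len(n_permutations)) {
    idx <- sample(nrow(b))
    if (cor(a[ut], b[idx, idx][ut]) >= r_obs - 1e-12) exceed <- exceed + 1L
  }
  out <- tibble(r = r_obs, p = (1 + exceed) / (1 + n_permutations),
                n_permutations = n_permutations)
  class(out) <- c("mantel_result", class(out))
  out
}

#' Time-point-wise permutation t-tests on rating traces
#'
#' At each time point, a two-sample permutation t-test between the two
#' groups of traces; group labels are permuted jointly across time
#' points (whole traces are exchanged) and the per-time-point two-sided
#' p-values are BH-FDR corrected across time.
#'
#' @param ratings_a,ratings_b Matrices, one row per subject, one column
#'   per time point (equal column counts).
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param q FDR level across time points.
#' @return Tibble: `time`, `t`, `p`, `significant`.
#' @export
timepoint_perm_test <- function(ratings_a, ratings_b,
                                n_permutations = 1000, seed = 1,
                                q = 0.05) {
  ratings_a <- as.matrix(ratings_a); ratings_b <- as.matrix(ratings_b)
  if (ncol(ratings_a) != ncol(ratings_b)) {
    abort("trace sets must have equal length")
  }
  na <- nrow(ratings_a); nb <- nrow(ratings_b)
  M <- rbind(ratings_a, ratings_b)
  tvec <- function(is_a) {
    a <- M[is_a, , drop = FALSE]; b <- M[!is_a, , drop = FALSE]
    va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
    sp <- sqrt(((nrow(a) - 1) * va + (nrow(b) - 1) * vb) /
                 (nrow(a) + nrow(b) - 2))
    (colMeans(a) - colMeans(b)) / (sp * sqrt(1 / nrow(a) + 1 / nrow(b)))
  }
  obs <- tvec(c(rep(TRUE, na), rep(FALSE, nb)))
  set.seed(seed)
  perm <- matrix(NA_real_, length(obs), n_permutations)
  for (k in seq_len(n_permutations)) {
    idx <- sample(na + nb, na)
    perm[, k] <- tvec(seq_len(na + nb) %in% idx)
  }
  p <- perm_p(obs, perm, "two-sided")
  tibble(time = seq_along(obs), t = obs, p = p,
         significant = bh_fdr(p, q)$mask)
}
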