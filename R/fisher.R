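#' Fisher Z transform and its inverse
#'
#' `fisher_z()` maps a Pearson correlation to the variance-stabilised
#' z-scale, `z = atanh(r)`; `fisher_z_inv()` maps back with `tanh`. All
#' pairwise ISC values in this package are averaged on the z-scale and
#' back-transformed for reporting, the standard convention for pooling
#' correlations.
#'
#' Correlations within floating-point noise of |r| = 1 (degenerate pairs,
#' e.g. a run correlated with a copy of itself) are clamped to
#' `1 - 1e-7` in magnitude before `atanh` so the z-values stay finite.
#' `NA` values pass through unchanged.
#'
#' @param r Numeric vector of correlations, |r| <= 1.
#' @param z Numeric vector of Fisher z-values.
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(c(0, 0.5, 1))
#' fisher_z_inv(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1 + 1e-9
  if (any(bad)) {
    abort(sprintf("correlations out of range [-1, 1]: first offender %g",
                  r[which(bad)[1]]))
  }
  r <- pmin(pmax(r, -1), 1)
  clamp <- 1 - 1e-7
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# mean on the z scale, back-transformed; NA-aware
z_mean_r <- function(z) {
  m <- mean(z, na.rm = TRUE)
  if (is.nan(m)) NA_real_ else tanh(m)
}
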