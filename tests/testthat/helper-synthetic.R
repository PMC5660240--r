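# shared fixture builders; everything is generated in code at test time

region_box <- function(condition, weight, xmin = 1, xmax = 3, ymin = 1,
                       ymax = 3, zmin = 1, zmax = 2) {
  tibble::tibble(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 zmin = zmin, zmax = zmax, condition = condition,
                 weight = weight)
}

# cohort with a planted same-ISC-under-one-condition region
small_cohort <- function(n_subjects = 6, n_trs = 200,
                         grid = c(6, 6, 3), isc = 0.5, noise_sd = 0.8,
                         condition = "genetic", seed = 1, ...) {
  regions <- if (isc > 0) {
    region_box(condition, coupling_for_isc(isc, noise_sd))
  } else NULL
  simulate_bold_cohort(cohort_spec(
    n_subjects, n_trs = n_trs, grid_shape = grid,
    effect_regions = regions, noise_sd = noise_sd, seed = seed, ...))
}

# independent connected-component labelling oracle (igraph-based)
label_oracle <- function(mask, connectivity = 6) {
  idx <- which(mask)
  lab <- array(0L, dim(mask))
  if (!length(idx)) return(lab)
  co <- arrayInd(idx, dim(mask))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  id <- stats::setNames(seq_along(idx), key(co))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], `+`)
    hit <- id[key(nb)]
    ok <- !is.na(hit)
    if (any(ok)) edges <- rbind(edges, cbind(which(ok), unname(hit[ok])))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
  }
  lab[idx] <- comp
  lab
}

# brute-force TFCE oracle: independent threshold sweep over the labels
tfce_oracle <- function(vol, E = 0.5, H = 2, dh, connectivity = 26) {
  out <- array(0, dim(vol))
  mx <- max(vol)
  if (mx <= 0) return(out)
  for (h in dh * seq_len(floor(mx / dh + 1e-9))) {
    lab <- label_oracle(vol >= h, connectivity)
    sizes <- tabulate(lab)
    sup <- lab > 0
    out[sup] <- out[sup] + sizes[lab[sup]]^E * h^H * dh
  }
  out
}

# deterministic multi-attractor scan path specification
scan_attractors <- function(duration_s, spread = 1.5) {
  n <- duration_s / 2
  tibble::tibble(t0 = seq(0, duration_s - 2, 2),
                 t1 = seq(2, duration_s, 2),
                 x = rep_len(c(-5, 5, 0, -3, 3, 1), n),
                 y = rep_len(c(2, -2, 0, 3, -3, 1), n),
                 spread = spread)
}

run_gaze_pipeline <- function(recs, duration_s, resolution = 0.5,
                              screen_extent = c(30, 20)) {
  fx <- drift_correct(lapply(recs, function(r) detect_fixations(r$gaze)))
  hm <- lapply(fx, window_heatmaps, duration_s = duration_s,
               resolution = resolution, screen_extent = screen_extent)
  eisc_pairwise(hm, vapply(recs, function(r) r$group, character(1)))
}
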