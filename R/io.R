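#' Load and validate a run manifest
#'
#' A manifest is a tab-separated table with header and columns
#' `subject_id`, `session`, `condition`, `perspective`, `bold_path`,
#' `motion_path` (and optional `gaze_path`, `physio_path`,
#' `rating_path`). Validation rejects duplicate (subject, condition,
#' session) rows, unknown condition labels and missing files.
#'
#' @param path Path to the manifest file.
#' @param check_files Verify referenced files exist (default TRUE).
#' @return A validated tibble of class `run_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("subject_id", "session", "condition", "bold_path")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    abort(sprintf("manifest missing columns: %s", paste(miss, collapse = ", ")))
  }
  bad_cond <- !m$condition %in% c("genetic", "nongenetic")
  if (any(bad_cond)) {
    abort(sprintf("unknown condition in manifest row %d: '%s'",
                  which(bad_cond)[1], m$condition[which(bad_cond)[1]]))
  }
  key <- paste(m$subject_id, m$condition, m$session)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (subject, condition, session) in manifest row %d",
                  which(duplicated(key))[1]))
  }
  if (check_files) {
    paths <- unlist(m[grepl("_path$", names(m))], use.names = FALSE)
    paths <- paths[!is.na(paths)]
    gone <- paths[!file.exists(paths)]
    if (length(gone)) {
      abort(sprintf("manifest references missing file: %s", gone[1]))
    }
  }
  class(m) <- c("run_manifest", class(m))
  m
}

#' Write / read a BOLD run as NIfTI
#'
#' The 4D volume is reconstructed from the masked matrix (out-of-mask
#' voxels are zero) and written together with a 3D mask image. The
#' affine, if present on the run, is carried through unchanged.
#'
#' @param run A [bold_run].
#' @param path Output NIfTI path (`.nii` / `.nii.gz`).
#' @param mask_path Optional path for the 3D mask image.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path, mask_path = NULL) {
  dims <- c(dim(run$mask), ncol(run$data))
  vol <- array(0, dims)
  flat <- matrix(vol, prod(dim(run$mask)), dims[4])
  flat[as.vector(run$mask), ] <- run$data
  vol <- array(flat, dims)
  img <- RNifti::asNifti(vol)
  if (!is.null(run$affine)) {
    img <- RNifti::`sform<-`(img, structure(run$affine, code = 2L))
  }
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    RNifti::writeNifti(RNifti::asNifti(array(run$mask * 1L, dim(run$mask))),
                       mask_path)
  }
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param mask Logical 3D array; if `NULL` and `mask_path` given, read
#'   from there, else all voxels.
#' @param ... Metadata passed to [bold_run()] (`subject_id`, `condition`,
#'   `session`, ...).
#' @export
read_bold_nifti <- function(path, mask = NULL, mask_path = NULL, ...) {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  if (length(dim(vol)) != 4) abort("expected a 4D NIfTI volume")
  if (is.null(mask)) {
    mask <- if (!is.null(mask_path)) {
      as.array(RNifti::readNifti(mask_path)) != 0
    } else {
      array(TRUE, dim(vol)[1:3])
    }
  }
  data <- matrix(vol, prod(dim(vol)[1:3]), dim(vol)[4])[as.vector(mask), ,
                                                        drop = FALSE]
  bold_run(data, mask = array(mask, dim(vol)[1:3]),
           affine = structure(RNifti::xform(img), code = NULL), ...)
}

#' Write a statistical map as NIfTI volumes plus a JSON sidecar
#'
#' Emits `<prefix>_stat.nii.gz`, `<prefix>_p.nii.gz`,
#' `<prefix>_mask.nii.gz` and `<prefix>.json` recording the FDR level,
#' adaptive thresholds, permutation count and seed.
#'
#' @param map An `isc_statmap`.
#' @param prefix Output path prefix.
#' @param affine Optional 4x4 affine applied to the volumes.
#' @return The JSON sidecar path, invisibly.
#' @export
write_statmap <- function(map, prefix, affine = NULL) {
  wr <- function(vol, suffix) {
    img <- RNifti::asNifti(vol)
    if (!is.null(affine)) {
      img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    }
    RNifti::writeNifti(img, paste0(prefix, suffix))
  }
  wr(statmap_volume(map, "statistic"), "_stat.nii.gz")
  wr(statmap_volume(map, "p"), "_p.nii.gz")
  wr(statmap_volume(map, "significant"), "_mask.nii.gz")
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(q = map$q, threshold_p = map$threshold_p,
         t_threshold = map$t_threshold, tail = map$tail,
         n_permutations = map$n_permutations, seed = map$seed,
         n_significant = sum(map$significant),
         package_version = as.character(utils::packageVersion("natisc"))),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' Read a statistical map written by [write_statmap()]
#'
#' @param prefix Path prefix used at write time.
#' @return An `isc_statmap` (mask = voxels with finite statistic).
#' @export
read_statmap <- function(prefix) {
  stat <- as.array(RNifti::readNifti(paste0(prefix, "_stat.nii.gz")))
  p <- as.array(RNifti::readNifti(paste0(prefix, "_p.nii.gz")))
  sig <- as.array(RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))) != 0
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask <- is.finite(stat)
  structure(
    list(statistic = stat[mask], p = p[mask], q = meta$q,
         significant = sig[mask],
         threshold_p = meta$threshold_p %||% NA_real_,
         t_threshold = meta$t_threshold %||% NA_real_,
         mask = mask, tail = meta$tail,
         n_permutations = meta$n_permutations, seed = meta$seed),
    class = "isc_statmap")
}

#' Write / read delimited motion and gaze tables
#'
#' Plain tab-separated files with a header row.
#'
#' @param x Matrix or data frame.
#' @param path File path.
#' @return `path` (write) or a tibble (read), invisibly for writes.
#' @export
write_motion_table <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_motion_table
#' @export
read_motion_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname write_motion_table
#' @export
write_gaze_table <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_motion_table
#' @export
read_gaze_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write cohort ground truth as a JSON sidecar
#'
#' @param truth An `isc_ground_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(grid_shape = truth$grid_shape,
         isc_genetic = as.vector(truth$isc_genetic),
         isc_nongenetic = as.vector(truth$isc_nongenetic),
         diff_mask = as.vector(truth$diff_mask)),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(isc_genetic = array(x$isc_genetic, x$grid_shape),
         isc_nongenetic = array(x$isc_nongenetic, x$grid_shape),
         diff_mask = array(x$diff_mask, x$grid_shape),
         grid_shape = x$grid_shape),
    class = "isc_ground_truth")
}
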