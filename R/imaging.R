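#' White-matter probability map
#'
#' A 3D grid of white-matter membership probabilities in \[0, 1\] on the same
#' grid as the label atlas. Lesion voxels falling below the probability
#' threshold (30% by convention) are removed before volumetry, to limit
#' contamination by misclassified non-WMH lesions outside the white matter.
#'
#' @param probabilities 3D numeric array with values in \[0, 1\].
#' @param voxel_size_mm voxel edge lengths in mm (scalar or length 3).
#' @return An object of class `wm_probability_map`.
#' @export
wm_probability_map <- function(probabilities, voxel_size_mm) {
  stopifnot(length(dim(probabilities)) == 3L)
  rng <- range(probabilities)
  if (rng[1] < 0 || rng[2] > 1)
    stop("WM probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(probabilities = probabilities,
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L)),
            class = "wm_probability_map")
}

#' Binary WMH lesion mask for one subject
#'
#' @param mask 3D array with values in \{0, 1\} (logical accepted).
#' @param voxel_size_mm voxel edge lengths in mm (scalar or length 3).
#' @param subject_id subject identifier.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask, voxel_size_mm, subject_id = NA_character_) {
  stopifnot(length(dim(mask)) == 3L)
  if (is.logical(mask)) mask <- array(as.integer(mask), dim(mask))
  if (!all(mask %in% c(0L, 1L)))
    stop("lesion mask must be binary (0/1)", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 mask = array(as.integer(mask), dim(mask)),
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L)),
            class = "lesion_mask")
}

#' Read / write a binary lesion mask as NIfTI
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param subject_id subject id; defaults to the file name stem.
#' @return `read_lesion_mask()` returns a `lesion_mask`.
#' @export
read_lesion_mask <- function(path, subject_id = NULL) {
  g <- read_nifti_grid(path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(array(as.integer(round(g$data)), dim(g$data)),
              g$voxel_size_mm, subject_id)
}

#' @rdname read_lesion_mask
#' @param lesion a `lesion_mask`.
#' @export
write_lesion_mask <- function(lesion, path) {
  write_nifti_grid(lesion$mask, lesion$voxel_size_mm, path, datatype = "uint8")
  invisible(path)
}

#' @rdname wm_probability_map
#' @param path NIfTI file path.
#' @export
read_wm_map <- function(path) {
  g <- read_nifti_grid(path)
  wm_probability_map(g$data, g$voxel_size_mm)
}

#' @rdname wm_probability_map
#' @param wm a `wm_probability_map`.
#' @export
write_wm_map <- function(wm, path) {
  write_nifti_grid(wm$probabilities, wm$voxel_size_mm, path,
                   datatype = "float")
  invisible(path)
}

#' Remove lesion voxels outside the white matter
#'
#' Keeps a lesion voxel iff the WM probability at that voxel is at or above
#' `threshold`. The boundary is inclusive: a voxel at exactly the threshold
#' probability is retained, the usual convention for probabilistic tissue
#' maps. The operation is idempotent.
#'
#' @param lesion a [lesion_mask()].
#' @param wm a [wm_probability_map()] on the same grid.
#' @param threshold WM probability cutoff, default 0.30.
#' @return A `lesion_mask` with out-of-WM voxels zeroed.
#' @export
apply_wm_mask <- function(lesion, wm, threshold = 0.30) {
  stopifnot(inherits(lesion, "lesion_mask"), inherits(wm, "wm_probability_map"))
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    stop("threshold must be a single value in (0, 1)", call. = FALSE)
  check_same_grid(dim(lesion$mask), lesion$voxel_size_mm,
                  dim(wm$probabilities), wm$voxel_size_mm,
                  "lesion mask", "WM probability map")
  out <- lesion
  out$mask <- array(as.integer(lesion$mask == 1L & wm$probabilities >= threshold),
                    dim(lesion$mask))
  out
}

#' Regional WMH volumes for one subject
#'
#' Counts lesion voxels per merged atlas ROI and converts to millilitres
#' (voxel count x voxel volume in mm^3 / 1000). The total is the volume of
#' *all* lesion voxels, including those inside the white matter but outside
#' any atlas ROI, so the ROI volumes sum to at most the total.
#'
#' @param lesion a [lesion_mask()], already WM-masked.
#' @param atlas a [label_atlas()] on the same grid.
#' @return list with `volumes_ml` (named numeric, one entry per merged ROI in
#'   merged-id order) and `total_ml`.
#' @export
regional_volumes <- function(lesion, atlas) {
  stopifnot(inherits(lesion, "lesion_mask"), inherits(atlas, "label_atlas"))
  check_same_grid(dim(lesion$mask), lesion$voxel_size_mm,
                  dim(atlas$labels), atlas$voxel_size_mm,
                  "lesion mask", "label atlas")
  vox_ml <- prod(atlas$voxel_size_mm) / 1000
  tab <- atlas$label_table
  k <- n_rois(atlas)
  # raw label -> merged id lookup
  lut <- integer(max(tab$raw_id))
  lut[tab$raw_id] <- tab$merged_id
  raw <- atlas$labels[lesion$mask == 1L]
  raw <- raw[raw > 0L]
  counts <- tabulate(lut[raw], nbins = k)
  vols <- counts * vox_ml
  names(vols) <- roi_names(atlas)
  list(volumes_ml = vols, total_ml = sum(lesion$mask) * vox_ml)
}

#' Regional volume table for a set of subjects
#'
#' @param masks list of [lesion_mask()] objects (already WM-masked).
#' @param atlas a [label_atlas()].
#' @return data.frame: `subject_id`, one column per merged ROI (mL), and
#'   `total_wmh` (mL).
#' @export
regional_volume_table <- function(masks, atlas) {
  rows <- lapply(masks, function(m) {
    rv <- regional_volumes(m, atlas)
    c(rv$volumes_ml, total_wmh = rv$total_ml)
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(subject_id = vapply(masks, function(m) m$subject_id, ""),
             out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Cube-root transform of lesion volumes
#'
#' `v^(1/3)`, the standard variance-stabilising transform for the strongly
#' right-skewed distribution of WMH volumes, applied before regression.
#'
#' @param volumes nonnegative numeric vector (NA passed through).
#' @return transformed vector; strictly increasing, 0 maps to 0.
#' @examples cube_root_transform(c(0, 0.027, 8))
#' @export
cube_root_transform <- function(volumes) {
  if (any(volumes < 0, na.rm = TRUE))
    stop("volumes must be nonnegative", call. = FALSE)
  volumes^(1 / 3)
}

#' Standardize values against a reference sample
#'
#' `(x - mean(ref)) / sd(ref)`. A reference with zero (or undefined) standard
#' deviation is degenerate and raises an error of class `wmh_degenerate`;
#' callers such as [run_association_suite()] catch it and skip the affected
#' ROI with a warning.
#'
#' @param x values to standardize.
#' @param reference reference sample defining mean and SD (default `x`
#'   itself); NAs ignored.
#' @return standardized values, mean 0 and SD 1 over the reference sample.
#' @export
zscore <- function(x, reference = x) {
  m <- mean(reference, na.rm = TRUE)
  s <- stats::sd(reference, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    degenerate_error("degenerate reference sample: zero standard deviation")
  (x - m) / s
}
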