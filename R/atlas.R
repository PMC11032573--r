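#' White-matter label atlas
#'
#' Bundle a 3D integer label grid with its voxel size and a label table.
#' Labels follow the convention of tract atlases such as ICBM-DTI-81: each
#' raw label is a left, right or midline structure, and bilateral structures
#' are merged into a single region of interest (ROI) for analysis (see
#' [merge_bilateral()]).
#'
#' @param labels 3D integer array; 0 is background, positive values are raw
#'   atlas labels.
#' @param voxel_size_mm numeric length 3 (or scalar, recycled), voxel edge
#'   lengths in millimetres.
#' @param label_table data.frame with columns `raw_id`, `name`, `laterality`
#'   (one of `"left"`, `"right"`, `"midline"`), and optionally `merged_id`,
#'   `merged_name` (added by [merge_bilateral()] if absent) plus any extra
#'   columns (e.g. a `zone` tag), which are preserved.
#'
#' @return An object of class `label_atlas`: a list with elements `labels`,
#'   `voxel_size_mm`, `label_table`.
#' @examples
#' tab <- data.frame(raw_id = 1:3,
#'                   name = c("external capsule", "external capsule", "genu"),
#'                   laterality = c("left", "right", "midline"))
#' arr <- array(0L, c(4, 4, 4)); arr[1, 1, 1] <- 1L; arr[4, 1, 1] <- 2L
#' atl <- label_atlas(arr, 1, tab)
#' atl$label_table$merged_name
#' @export
label_atlas <- function(labels, voxel_size_mm, label_table) {
  stopifnot(length(dim(labels)) == 3L)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be positive", call. = FALSE)
  label_table <- validate_label_table(label_table)
  if (!("merged_id" %in% names(label_table)))
    label_table <- merge_bilateral(label_table)
  pos <- sort(unique(as.integer(labels[labels > 0])))
  missing <- setdiff(pos, label_table$raw_id)
  if (length(missing))
    stop("label grid contains values absent from the label table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(labels = labels,
                 voxel_size_mm = voxel_size_mm,
                 label_table = label_table),
            class = "label_atlas")
}

validate_label_table <- function(tab) {
  req <- c("raw_id", "name", "laterality")
  if (!all(req %in% names(tab)))
    stop("label table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  tab$raw_id <- as.integer(tab$raw_id)
  if (anyDuplicated(tab$raw_id))
    stop("duplicated raw_id in label table", call. = FALSE)
  if (any(tab$raw_id < 1)) stop("raw_id must be positive", call. = FALSE)
  bad <- setdiff(unique(tab$laterality), c("left", "right", "midline"))
  if (length(bad))
    stop("laterality must be left/right/midline; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab
}

#' Merge bilateral atlas labels into analysis ROIs
#'
#' Left/right labels sharing a stem `name` are collapsed into one merged ROI;
#' midline labels map to their own ROI. Applied to the 50-label ICBM-DTI-81
#' white-matter atlas (22 bilateral pairs + 6 midline structures) this yields
#' the 28 merged ROIs used throughout the analysis.
#'
#' @param label_table data.frame with `raw_id`, `name`, `laterality`.
#' @return The same table with `merged_id` (1..K, in order of first
#'   appearance by `raw_id`) and `merged_name` columns filled in.
#' @examples
#' tab <- data.frame(raw_id = 1:3,
#'                   name = c("tapetum", "tapetum", "fornix"),
#'                   laterality = c("left", "right", "midline"))
#' merge_bilateral(tab)
#' @export
merge_bilateral <- function(label_table) {
  tab <- validate_label_table(label_table)
  tab <- tab[order(tab$raw_id), , drop = FALSE]
  lat <- tab$laterality
  # every lateralised stem must come as a complete left/right pair
  for (stem in unique(tab$name[lat != "midline"])) {
    l <- sum(lat == "left" & tab$name == stem)
    r <- sum(lat == "right" & tab$name == stem)
    if (l != 1L || r != 1L)
      stop(sprintf("bilateral stem '%s' has %d left and %d right entries; expected one of each",
                   stem, l, r), call. = FALSE)
  }
  if (anyDuplicated(tab$name[lat == "midline"]))
    stop("duplicated midline label name", call. = FALSE)
  if (length(intersect(tab$name[lat == "midline"], tab$name[lat != "midline"])))
    stop("a name cannot be both midline and lateralised", call. = FALSE)
  key <- tab$name
  merged_names <- unique(key)            # order of first appearance by raw_id
  tab$merged_id <- match(key, merged_names)
  tab$merged_name <- key
  rownames(tab) <- NULL
  tab
}

#' Number of merged ROIs in an atlas
#' @param x a `label_atlas` or label table with `merged_id`.
#' @return integer count of merged ROIs.
#' @export
n_rois <- function(x) {
  tab <- if (inherits(x, "label_atlas")) x$label_table else x
  length(unique(tab$merged_id))
}

#' Names of merged ROIs, in merged-id order
#' @inheritParams n_rois
#' @return character vector of merged ROI names.
#' @export
roi_names <- function(x) {
  tab <- if (inherits(x, "label_atlas")) x$label_table else x
  tab <- tab[!duplicated(tab$merged_id), ]
  tab$merged_name[order(tab$merged_id)]
}

#' @exportS3Method base::print
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s voxels @ %s mm, %d raw labels -> %d merged ROIs\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              nrow(x$label_table), n_rois(x)))
  invisible(x)
}

#' Read / write a label atlas (NIfTI grid + TSV label table)
#'
#' The TSV has columns `raw_id`, `name`, `laterality`, `merged_id`,
#' `merged_name` and any extra columns such as `zone`.
#'
#' @param nifti_path path to the label NIfTI (gzip-compressed accepted).
#' @param table_path path to the label-table TSV.
#' @return `read_label_atlas()` returns a `label_atlas`.
#' @export
read_label_atlas <- function(nifti_path, table_path) {
  g <- read_nifti_grid(nifti_path)
  tab <- utils::read.delim(table_path, sep = "\t", stringsAsFactors = FALSE)
  label_atlas(array(as.integer(round(g$data)), dim(g$data)),
              g$voxel_size_mm, tab)
}

#' @rdname read_label_atlas
#' @param atlas a `label_atlas`.
#' @export
write_label_atlas <- function(atlas, nifti_path, table_path) {
  write_nifti_grid(atlas$labels, atlas$voxel_size_mm, nifti_path,
                   datatype = "int16")
  utils::write.table(atlas$label_table, table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(nifti_path, table_path))
}
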