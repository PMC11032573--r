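# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# grids must be identical across atlas, WM map and masks; no resampling here
check_same_grid <- function(dim_a, vox_a, dim_b, vox_b, what_a = "input",
                            what_b = "input") {
  if (!identical(as.integer(dim_a), as.integer(dim_b)))
    stop(sprintf("grid shape mismatch between %s (%s) and %s (%s)",
                 what_a, paste(dim_a, collapse = "x"),
                 what_b, paste(dim_b, collapse = "x")), call. = FALSE)
  if (max(abs(as.numeric(vox_a) - as.numeric(vox_b))) > 1e-6)
    stop(sprintf("voxel size mismatch between %s (%s mm) and %s (%s mm)",
                 what_a, paste(vox_a, collapse = "x"),
                 what_b, paste(vox_b, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

degenerate_error <- function(msg) {
  stop(errorCondition(msg, class = c("wmh_degenerate", "error", "condition")))
}

# md5 of a character vector, via a temp file (tools::md5sum is file-based)
md5_of_text <- function(lines) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}

assert_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# NIfTI writer that preserves an isotropic-mm voxel grid
write_nifti_grid <- function(arr, voxel_size_mm, path, datatype = "auto") {
  dm <- dim(arr)
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, dm, 1L, 1L, 1L, 1L),
    pixdim = c(-1, voxel_size_mm, 0, 0, 0, 0)))
  img <- RNifti::asNifti(arr, reference = hdr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  list(data = unclass(as.array(img)), voxel_size_mm = RNifti::pixdim(img)[1:3])
}
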