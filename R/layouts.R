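#' Synthetic ROI layouts
#'
#' A layout places each raw atlas label as an axis-aligned block of voxels
#' inside the simulation grid. Bilateral pairs occupy mirror-symmetric
#' blocks about the mid-sagittal voxel plane; midline structures straddle
#' it. Every ROI carries a `zone` tag (`anterior`, `posterior`,
#' `infratentorial`, `other`) used by the simulator to impose spatially
#' structured covariate effects (e.g. vascular risk loading anterior zones
#' and amyloid status loading posterior zones).
#'
#' `default_roi_layout()` is a compact 10-label layout (4 bilateral pairs +
#' 2 midline = 6 merged ROIs) on a 24 x 28 x 20 grid. `icbm_like_layout()`
#' is a synthetic stand-in with the merge structure of the ICBM-DTI-81
#' white-matter atlas: 50 labels (22 bilateral pairs + 6 midline) merging to
#' 28 ROIs, on a 24 x 46 x 46 grid.
#'
#' @return data.frame with columns `name`, `laterality`, `zone`,
#'   `x0,x1,y0,y1,z0,z1` (inclusive voxel bounds) and attribute
#'   `grid_shape`.
#' @export
default_roi_layout <- function() {
  blk <- function(name, lat, zone, x, y, z)
    data.frame(name = name, laterality = lat, zone = zone,
               x0 = x[1], x1 = x[2], y0 = y[1], y1 = y[2],
               z0 = z[1], z1 = z[2], stringsAsFactors = FALSE)
  pair <- function(name, zone, xl, y, z) {
    rbind(blk(name, "left", zone, xl, y, z),
          blk(name, "right", zone, c(25 - xl[2], 25 - xl[1]), y, z))
  }
  layout <- rbind(
    pair("anterior corona radiata", "anterior", c(2, 9), c(20, 27), c(11, 18)),
    pair("superior corona radiata", "anterior", c(2, 9), c(11, 18), c(11, 18)),
    pair("posterior thalamic radiation", "posterior", c(2, 9), c(2, 9), c(11, 18)),
    pair("external capsule", "other", c(2, 9), c(11, 18), c(2, 9)),
    blk("splenium of corpus callosum", "midline", "posterior",
        c(10, 15), c(2, 9), c(11, 18)),
    blk("middle cerebellar peduncle", "midline", "infratentorial",
        c(10, 15), c(11, 18), c(2, 9)))
  structure(layout, grid_shape = c(24L, 28L, 20L))
}

#' @rdname default_roi_layout
#' @export
icbm_like_layout <- function() {
  nx <- 24L
  midline_names <- c("middle cerebellar peduncle", "pontine crossing tract",
                     "genu of corpus callosum", "body of corpus callosum",
                     "splenium of corpus callosum", "fornix")
  midline_zones <- c("infratentorial", "infratentorial", "anterior", "other",
                     "posterior", "other")
  paired <- c(
    "corticospinal tract" = "infratentorial",
    "medial lemniscus" = "infratentorial",
    "inferior cerebellar peduncle" = "infratentorial",
    "superior cerebellar peduncle" = "infratentorial",
    "cerebral peduncle" = "other",
    "anterior limb of internal capsule" = "anterior",
    "posterior limb of internal capsule" = "other",
    "retrolenticular part of internal capsule" = "posterior",
    "anterior corona radiata" = "anterior",
    "superior corona radiata" = "anterior",
    "posterior corona radiata" = "posterior",
    "posterior thalamic radiation" = "posterior",
    "sagittal stratum" = "posterior",
    "external capsule" = "anterior",
    "cingulum (cingulate gyrus)" = "other",
    "cingulum (hippocampus)" = "other",
    "fornix (cres) / stria terminalis" = "other",
    "superior longitudinal fasciculus" = "other",
    "superior fronto-occipital fasciculus" = "anterior",
    "inferior fronto-occipital fasciculus" = "other",
    "uncinate fasciculus" = "other",
    "tapetum" = "posterior")
  # 5 x 5 lattice of 8-voxel slots (1-voxel gaps) in (y, z)
  slots <- expand.grid(y0 = c(2L, 11L, 20L, 29L, 38L),
                       z0 = c(2L, 11L, 20L, 29L, 38L))
  rows <- vector("list", 50L)
  k <- 0L
  for (i in seq_along(paired)) {
    y <- c(slots$y0[i], slots$y0[i] + 7L); z <- c(slots$z0[i], slots$z0[i] + 7L)
    for (lat in c("left", "right")) {
      x <- if (lat == "left") c(2L, 9L) else c(nx + 1L - 9L, nx + 1L - 2L)
      k <- k + 1L
      rows[[k]] <- data.frame(name = names(paired)[i], laterality = lat,
                              zone = unname(paired[i]), x0 = x[1], x1 = x[2],
                              y0 = y[1], y1 = y[2], z0 = z[1], z1 = z[2],
                              stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(midline_names)) {
    y <- c(slots$y0[i], slots$y0[i] + 7L); z <- c(slots$z0[i], slots$z0[i] + 7L)
    k <- k + 1L
    rows[[k]] <- data.frame(name = midline_names[i], laterality = "midline",
                            zone = midline_zones[i], x0 = 10L, x1 = 15L,
                            y0 = y[1], y1 = y[2], z0 = z[1], z1 = z[2],
                            stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), grid_shape = c(nx, 46L, 46L))
}

# validates bounds, pairwise disjointness (naming the offending pair) and
# mirror symmetry of bilateral pairs about the mid-sagittal voxel plane
validate_roi_layout <- function(layout, grid_shape) {
  req <- c("name", "laterality", "zone", "x0", "x1", "y0", "y1", "z0", "z1")
  if (is.null(layout) || !nrow(layout))
    stop("roi_layout must be non-empty", call. = FALSE)
  miss <- setdiff(req, names(layout))
  if (length(miss))
    stop("roi_layout missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_zone <- setdiff(unique(layout$zone),
                      c("anterior", "posterior", "infratentorial", "other"))
  if (length(bad_zone))
    stop("unknown zone tag: ", paste(bad_zone, collapse = ", "), call. = FALSE)
  lab <- paste(layout$name, layout$laterality)
  for (i in seq_len(nrow(layout))) {
    b <- layout[i, ]
    if (b$x0 > b$x1 || b$y0 > b$y1 || b$z0 > b$z1 ||
        b$x0 < 1 || b$y0 < 1 || b$z0 < 1 ||
        b$x1 > grid_shape[1] || b$y1 > grid_shape[2] || b$z1 > grid_shape[3])
      stop(sprintf("block '%s' lies outside the %s grid", lab[i],
                   paste(grid_shape, collapse = "x")), call. = FALSE)
  }
  if (nrow(layout) > 1L) {
    for (i in seq_len(nrow(layout) - 1L)) for (j in seq(i + 1L, nrow(layout))) {
      a <- layout[i, ]; b <- layout[j, ]
      if (a$x0 <= b$x1 && b$x0 <= a$x1 && a$y0 <= b$y1 && b$y0 <= a$y1 &&
          a$z0 <= b$z1 && b$z0 <= a$z1)
        stop(sprintf("overlapping ROI blocks: '%s' and '%s'", lab[i], lab[j]),
             call. = FALSE)
    }
  }
  # mirror symmetry: x -> grid_shape[1] + 1 - x maps left block onto right
  for (stem in unique(layout$name[layout$laterality != "midline"])) {
    l <- layout[layout$name == stem & layout$laterality == "left", ]
    r <- layout[layout$name == stem & layout$laterality == "right", ]
    if (nrow(l) != 1L || nrow(r) != 1L)
      stop(sprintf("bilateral stem '%s' must have exactly one left and one right block",
                   stem), call. = FALSE)
    mirrored <- c(grid_shape[1] + 1L - l$x1, grid_shape[1] + 1L - l$x0)
    if (!identical(as.integer(c(r$x0, r$x1)), as.integer(mirrored)) ||
        !identical(as.integer(c(l$y0, l$y1, l$z0, l$z1)),
                   as.integer(c(r$y0, r$y1, r$z0, r$z1))))
      stop(sprintf("blocks of bilateral pair '%s' are not mirror-symmetric",
                   stem), call. = FALSE)
  }
  invisible(layout)
}
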