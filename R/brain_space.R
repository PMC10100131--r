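#' Reference space for all voxelwise analyses
#'
#' A `brain_space` bundles everything the pipeline needs to know about the
#' common grid that lesion masks and maps live on: grid dimensions, voxel
#' size, world origin, a binary brain mask, an integer-labelled parcellation
#' (0 = background, 1..R regions), region centroids in mm, and a ventricle
#' mask used as the subventricular-zone (SVZ) proxy.
#'
#' World coordinates follow the convention `mm = origin + index0 * voxel_size`
#' with 0-based voxel indices; distances are always in mm and volumes in cm^3.
#'
#' @param dims Integer triple, voxels per axis.
#' @param voxel_size Numeric triple, mm per voxel along each axis.
#' @param origin Numeric triple, world mm coordinate of voxel (0,0,0).
#' @param brain_mask Logical 3-D array of dimension `dims`.
#' @param parcellation Integer 3-D array of dimension `dims`; 0 outside the
#'   brain mask, labels `1..R` inside.
#' @param region_centroids `R x 3` numeric matrix of region centroids (mm).
#' @param ventricle_mask Logical 3-D array, subset of `brain_mask`.
#' @return An object of class `brain_space`.
#' @seealso [make_brain_space()] for a synthetic constructor.
#' @export
brain_space <- function(dims, voxel_size, origin, brain_mask, parcellation,
                        region_centroids, ventricle_mask) {
  space <- structure(
    list(
      dims = as.integer(dims),
      voxel_size = as.numeric(voxel_size),
      origin = as.numeric(origin),
      brain_mask = brain_mask,
      parcellation = parcellation,
      region_centroids = region_centroids,
      ventricle_mask = ventricle_mask
    ),
    class = "brain_space"
  )
  validate_brain_space(space)
  space
}

#' Validate the invariants of a brain space
#'
#' Checks that the parcellation is nonzero only inside the brain mask, that
#' the ventricle mask is contained in the brain mask, that all region labels
#' `1..R` are present, and that centroids are finite and inside the grid's
#' world bounding box.
#'
#' @param space A [brain_space()].
#' @return `space`, invisibly; errors on any violation.
#' @export
validate_brain_space <- function(space) {
  stopifnot(inherits(space, "brain_space"))
  d <- space$dims
  if (length(d) != 3L || any(d < 1L)) stop("dims must be a positive triple")
  if (length(space$voxel_size) != 3L || any(space$voxel_size <= 0)) {
    stop("voxel_size must be a positive mm triple")
  }
  for (fld in c("brain_mask", "parcellation", "ventricle_mask")) {
    if (!identical(dim(space[[fld]]), d)) {
      stop(sprintf("%s does not match dims", fld))
    }
  }
  if (any(space$parcellation[!space$brain_mask] != 0L)) {
    stop("parcellation has nonzero labels outside brain_mask")
  }
  if (any(space$ventricle_mask & !space$brain_mask)) {
    stop("ventricle_mask extends outside brain_mask")
  }
  labs <- space$parcellation[space$brain_mask]
  R <- nrow(space$region_centroids)
  present <- sort(unique(labs[labs > 0L]))
  if (!identical(as.integer(present), seq_len(R))) {
    stop("parcellation labels must be exactly 1..R with all labels present")
  }
  cen <- space$region_centroids
  if (!all(is.finite(cen))) stop("region centroids must be finite")
  lo <- space$origin
  hi <- space$origin + (d - 1) * space$voxel_size
  if (any(t(cen) < lo - 1e-9) || any(t(cen) > hi + 1e-9)) {
    stop("region centroids fall outside the grid bounding box")
  }
  invisible(space)
}

#' Number of parcellation regions in a space
#' @param space A [brain_space()].
#' @return Integer count of regions.
#' @export
n_regions <- function(space) nrow(space$region_centroids)

#' Volume of one voxel in cm^3
#' @param space A [brain_space()].
#' @return Scalar voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(space) prod(space$voxel_size) / 1000

# Internal: world mm coordinates of every voxel, as an (nx*ny*nz) x 3 matrix
# in R's column-major array order.
voxel_grid_mm <- function(space) {
  d <- space$dims
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  sweep(sweep(idx, 2L, space$voxel_size, `*`), 2L, space$origin, `+`)
}

# Internal: world mm coordinates of the voxels where mask is TRUE.
mask_coords_mm <- function(mask, space) {
  idx <- arrayInd(which(mask), space$dims) - 1L
  sweep(sweep(idx, 2L, space$voxel_size, `*`), 2L, space$origin, `+`)
}

#' @export
print.brain_space <- function(x, ...) {
  cat(sprintf(
    "<brain_space> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm, %d regions\n",
    x$dims[1], x$dims[2], x$dims[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], n_regions(x)
  ))
  cat(sprintf(
    "  brain: %d voxels (%.1f cm^3); ventricles: %d voxels\n",
    sum(x$brain_mask), sum(x$brain_mask) * voxel_volume_cm3(x),
    sum(x$ventricle_mask)
  ))
  invisible(x)
}
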