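#' 3-D intensity volumes with anisotropic voxel spacing
#'
#' A `voxel_grid` holds a 3-D scalar intensity array together with its
#' voxel spacing (mm per axis) and the world coordinate of the *centre* of
#' voxel index `(0, 0, 0)` (0-based). The voxel-to-world map is
#' `world = origin + index * spacing` componentwise; all millimetre
#' coordinates used by the detection functions are world coordinates under
#' this convention. The default spacing is the anisotropic acquisition grid
#' of a typical coronal T1 protocol, 0.575 x 0.575 x 0.8 mm, on which
#' spherical markers acquire their characteristic slightly oval
#' partial-volume appearance.
#'
#' @param intensities 3-D numeric array.
#' @param spacing numeric length-3, mm per axis, all positive.
#' @param origin numeric length-3, world mm of the centre of voxel
#'   `(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, spacing = c(0.575, 0.575, 0.8),
                       origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L,
            all(spacing > 0), all(is.finite(origin)))
  structure(list(intensities = intensities, spacing = spacing,
                 origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_grid: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm; intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# 0-based voxel indices (n x 3) -> world mm (n x 3)
voxel_to_world <- function(grid, idx0) {
  sweep(sweep(idx0, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

# world mm (n x 3) -> fractional 0-based voxel indices
world_to_voxel <- function(grid, world) {
  sweep(sweep(world, 2L, grid$origin, "-"), 2L, grid$spacing, "/")
}

#' Read and write voxel grids as NIfTI-1
#'
#' Volumes are stored with a diagonal sform encoding the spacing and the
#' world origin of voxel `(0, 0, 0)`; reading recovers spacing from the
#' sform diagonal and origin from its offset column. Axis orientation is
#' taken as stored (no RAS reorientation is attempted), which is sufficient
#' for volumes this package writes itself.
#'
#' @param grid a [voxel_grid()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `voxel_grid`; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$intensities)
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  spacing <- abs(diag(m)[1:3])
  origin <- m[1:3, 4]
  voxel_grid(array(as.numeric(img), dim = dim(img)),
             spacing = spacing, origin = origin)
}
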