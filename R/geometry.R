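#' Acquisition geometry of an axial image stack
#'
#' Describes the in-plane field of view, in-plane matrix, number of axial
#' slices and slice thickness of a CHESS fat/water acquisition, and owns all
#' voxel-size arithmetic.
#'
#' @param fov_mm numeric(2), in-plane field of view in mm (x, y).
#' @param matrix integer(2), in-plane matrix size (nx, ny).
#' @param n_slices number of axial slices.
#' @param slice_thickness_mm slice thickness in mm.
#'
#' @return An object of class `acq_geometry`.
#' @examples
#' g <- acq_geometry()            # the printed small-animal protocol
#' voxel_volume(g)                # 0.0078125 mm^3
#' @export
acq_geometry <- function(fov_mm = c(16, 16), matrix = c(128L, 128L),
                         n_slices = 50L, slice_thickness_mm = 0.5) {
  if (length(fov_mm) != 2L || any(!is.finite(fov_mm)) || any(fov_mm <= 0))
    stopf("'fov_mm' must be two positive extents in mm")
  if (length(matrix) != 2L || any(!is.finite(matrix)) || any(matrix < 1) ||
      any(matrix != round(matrix)))
    stopf("'matrix' must be two positive integer counts")
  check_scalar_number(n_slices, "n_slices", min = 0, strict = TRUE)
  if (n_slices != round(n_slices)) stopf("'n_slices' must be an integer count")
  check_scalar_number(slice_thickness_mm, "slice_thickness_mm", min = 0, strict = TRUE)
  structure(
    list(fov_mm = as.numeric(fov_mm), matrix = as.integer(matrix),
         n_slices = as.integer(n_slices),
         slice_thickness_mm = as.numeric(slice_thickness_mm)),
    class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  d <- voxel_dims(x)
  cat(sprintf("Acquisition geometry: %g x %g mm FOV, %d x %d matrix, %d slices x %g mm\n",
              x$fov_mm[1], x$fov_mm[2], x$matrix[1], x$matrix[2],
              x$n_slices, x$slice_thickness_mm))
  cat(sprintf("  voxel: %g x %g x %g mm (%g mm^3)\n", d[1], d[2], d[3], voxel_volume(x)))
  invisible(x)
}

#' Voxel edge lengths in mm
#'
#' @param geometry an [acq_geometry()].
#' @return numeric(3): (dx, dy, dz) in mm.
#' @export
voxel_dims <- function(geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  c(geometry$fov_mm[1] / geometry$matrix[1],
    geometry$fov_mm[2] / geometry$matrix[2],
    geometry$slice_thickness_mm)
}

#' Voxel volume in mm^3
#'
#' The product of the in-plane voxel edges (FOV divided by matrix,
#' componentwise) and the slice thickness. For the 16 x 16 mm FOV, 128 x 128
#' matrix, 0.5 mm slice protocol this is 7.8125e-3 mm^3, i.e. 7.81 on the
#' 1e-3 mm^3 scale.
#'
#' @inheritParams voxel_dims
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(geometry) prod(voxel_dims(geometry))

# Expected array dimensions (slices, rows, columns) for this geometry.
stack_dim <- function(geometry)
  c(geometry$n_slices, geometry$matrix[2], geometry$matrix[1])

# Voxel-centre coordinates (mm), origin at the FOV/slab centre.
# Returns list(x[nx], y[ny], z[n_slices]).
voxel_grid <- function(geometry) {
  d <- voxel_dims(geometry)
  nx <- geometry$matrix[1]; ny <- geometry$matrix[2]; ns <- geometry$n_slices
  list(x = -geometry$fov_mm[1] / 2 + (seq_len(nx) - 0.5) * d[1],
       y = -geometry$fov_mm[2] / 2 + (seq_len(ny) - 0.5) * d[2],
       z = -ns * d[3] / 2 + (seq_len(ns) - 0.5) * d[3])
}

# Coordinates of every voxel, in array layout order (slice fastest).
# Returns list(x, y, z) vectors of length prod(stack_dim(geometry)).
voxel_coords <- function(geometry) {
  g <- voxel_grid(geometry)
  ns <- geometry$n_slices; ny <- geometry$matrix[2]; nx <- geometry$matrix[1]
  list(x = rep(g$x, each = ns * ny),
       y = rep(rep(g$y, each = ns), times = nx),
       z = rep(g$z, times = ny * nx))
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}
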