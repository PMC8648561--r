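#' Three-dimensional scalar volume
#'
#' The basic container of the package: a 3D numeric array on an isotropic
#' voxel grid with physical metadata. Data are stored `[x, y, z]`
#' (column-major, so `data[, , k]` is the axial slice `k`; `z` is the
#' tomographic rotation axis). The physical coordinate of the centre of voxel
#' `(i, j, k)` (1-based) is `origin + voxel_size * (i - 1, j - 1, k - 1)`,
#' in micrometres.
#'
#' @param data numeric 3D array (or a matrix, promoted to a single slice).
#' @param voxel_size isotropic voxel edge length in micrometres (> 0).
#' @param origin physical coordinate (µm) of the centre of voxel (1,1,1).
#' @param dtype_tag storage tag, `"float32"` or `"uint16"`. With `"uint16"`
#'   the array still holds numeric values; `scale` maps stored integers
#'   `s` to physical values `offset + slope * s`.
#' @param scale numeric `c(offset, slope)`; only meaningful for `uint16`.
#'
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size, origin = c(0, 0, 0),
                     dtype_tag = c("float32", "uint16"),
                     scale = c(0, 1)) {
  dtype_tag <- match.arg(dtype_tag)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("every dimension must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)", call. = FALSE)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  if (dtype_tag == "uint16") {
    if (length(scale) != 2L || scale[2] <= 0)
      stop("uint16 volumes need scale = c(offset, slope) with slope > 0",
           call. = FALSE)
  }
  structure(
    list(data = data, voxel_size = voxel_size, origin = as.numeric(origin),
         dtype_tag = dtype_tag, scale = as.numeric(scale)),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %.4g um/voxel [%s]\n",
              d[1], d[2], d[3], x$voxel_size, x$dtype_tag))
  cat(sprintf("  origin (um): %.4g %.4g %.4g;  range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Physical values of a volume
#'
#' For `uint16` volumes applies the stored linear scale; for `float32`
#' volumes returns the data unchanged.
#'
#' @param vol a [volume3d()].
#' @return numeric 3D array of physical values.
#' @export
physical_values <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  if (vol$dtype_tag == "uint16")
    vol$scale[1] + vol$scale[2] * vol$data
  else vol$data
}

#' Voxel-centre coordinate grids
#'
#' @param vol a [volume3d()].
#' @return list of numeric vectors `x`, `y`, `z` (µm, voxel centres).
#' @export
voxel_axes <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + vol$voxel_size * (seq_len(d[1]) - 1),
       y = vol$origin[2] + vol$voxel_size * (seq_len(d[2]) - 1),
       z = vol$origin[3] + vol$voxel_size * (seq_len(d[3]) - 1))
}

#' Cylindrical region of interest (virtual biopsy geometry)
#'
#' A finite cylinder defined by a base point on its axis, a unit axis
#' direction, a radius and a length, all in micrometres. Used both for
#' virtual-biopsy counting and for masking reconstructed volumes.
#'
#' @param axis_point 3-vector (µm), base point of the axis.
#' @param axis_direction 3-vector; normalised internally, must be non-zero.
#' @param radius cylinder radius (µm, > 0).
#' @param length cylinder length (µm, > 0).
#' @return an object of class `cylinder_roi`.
#' @export
cylinder_roi <- function(axis_point, axis_direction, radius, length) {
  if (radius <= 0 || length <= 0)
    stop("radius and length must be positive", call. = FALSE)
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm < 1e-12) stop("axis_direction must be non-zero", call. = FALSE)
  structure(list(axis_point = as.numeric(axis_point),
                 axis_direction = as.numeric(axis_direction) / nrm,
                 radius = radius, length = length),
            class = "cylinder_roi")
}

#' Cylinder volume, pi r^2 L
#' @param roi a [cylinder_roi()].
#' @return volume in µm^3.
#' @export
cylinder_volume <- function(roi) pi * roi$radius^2 * roi$length

#' Rasterise a cylindrical ROI onto a volume grid
#'
#' Membership is evaluated at voxel centres and is inclusive at the boundary:
#' a voxel is inside iff its radial distance from the axis is `<= radius` and
#' its axial coordinate lies in `[0, length]`.
#'
#' @param vol a [volume3d()] providing the grid.
#' @param roi a [cylinder_roi()].
#' @return a logical-valued [volume3d()] mask on the same grid. If the ROI
#'   does not intersect the volume the mask is empty, with a warning.
#' @export
cylinder_mask <- function(vol, roi) {
  ax <- voxel_axes(vol)
  d <- dim(vol$data)
  # coordinates relative to the axis base point
  px <- ax$x - roi$axis_point[1]
  py <- ax$y - roi$axis_point[2]
  pz <- ax$z - roi$axis_point[3]
  u <- roi$axis_direction
  # axial coordinate t = p . u  (separable over the three index axes)
  tx <- px * u[1]; ty <- py * u[2]; tz <- pz * u[3]
  t3 <- outer(outer(tx, ty, "+"), tz, "+")
  # squared distance from base point
  r2 <- outer(outer(px^2, py^2, "+"), pz^2, "+")
  rad2 <- r2 - t3^2
  mask <- (t3 >= 0) & (t3 <= roi$length) & (rad2 <= roi$radius^2 + 1e-9)
  if (!any(mask)) warning("cylinder ROI does not intersect the volume")
  out <- volume3d(array(mask, d), vol$voxel_size, vol$origin)
  out
}
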