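#' Regular 3D voxel lattice
#'
#' A `voxel_grid` describes the geometry shared by structure masks and
#' dose grids: integer dimensions, positive spacing in mm, and the world
#' position (mm) of the centre of voxel `(1,1,1)`. The axis convention is
#' x: patient-right to patient-left, y: anterior to posterior,
#' z: caudal to cranial, so the "cranial border" of a structure is its
#' maximum occupied z coordinate.
#'
#' @param dims integer vector of length 3 `(nx, ny, nz)`, all >= 1.
#' @param spacing numeric vector of length 3, voxel spacing in mm, all > 0.
#' @param origin numeric vector of length 3, world coordinate (mm) of the
#'   centre of the first voxel. Defaults to `c(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(10, 10, 5), spacing = c(1, 1, 3))
#' index_to_world(g, cbind(1, 1, 1))
#' @export
voxel_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive lengths in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite world coordinates in mm")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$dims[1], x$dims[2], x$dims[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

grid_equal <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "objects") {
  if (!grid_equal(a, b))
    stop(sprintf("%s are not on the same voxel grid (%s vs %s); resample first",
                 what, format(a), format(b)))
  invisible(TRUE)
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 1-based (R convention); the centre of voxel
#' `(i, j, k)` sits at `origin + (c(i, j, k) - 1) * spacing`.
#' `world_to_index()` returns fractional (continuous) indices;
#' round them to address voxels.
#'
#' @param grid a [voxel_grid].
#' @param idx numeric matrix with 3 columns of voxel indices.
#' @param xyz numeric matrix with 3 columns of world coordinates in mm.
#' @return A numeric matrix with 3 columns.
#' @export
index_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, grid$spacing, `*`), 2L, grid$origin, `+`)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(sweep(xyz, 2L, grid$origin, `-`), 2L, grid$spacing, `/`) + 1
}

#' Physical volume of one voxel in mm^3
#' @param grid a [voxel_grid].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' World coordinates of all voxel centres along one axis
#' @param grid a [voxel_grid].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of length `dims[axis]`.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}
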