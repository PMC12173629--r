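#' Rasterize slice-wise planar contours into a structure mask
#'
#' Contours are closed planar polygons in world mm, each lying on a
#' constant-z plane that must coincide with a grid slice (within half a
#' slice spacing). A voxel is occupied iff its centre lies inside an odd
#' number of the polygons on its slice (even-odd rule), so holes and
#' islands are represented by nesting, as in RT structure-set converters.
#'
#' @param contours list of contours; each contour is a list (or an Nx3
#'   matrix) with a numeric `vertices` Nx2 matrix of (x, y) mm and a
#'   scalar `z` in mm. An Nx3 matrix is interpreted as xyz vertices on a
#'   constant-z plane.
#' @param grid a [voxel_grid].
#' @param label structure label for the resulting mask.
#' @return A [structure_mask]. An empty contour list yields an empty mask.
#' @export
rasterize_polygons <- function(contours, grid, label = "structure") {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- array(FALSE, grid$dims)
  xs <- axis_coords(grid, 1L)
  ys <- axis_coords(grid, 2L)
  zs <- axis_coords(grid, 3L)
  for (ct in contours) {
    if (is.matrix(ct)) {
      if (ncol(ct) != 3L) stop("matrix contour must have 3 columns (x, y, z)")
      zvals <- unique(ct[, 3])
      if (length(zvals) != 1L)
        stop("contour vertices are not coplanar on a constant-z plane")
      ct <- list(vertices = ct[, 1:2, drop = FALSE], z = zvals)
    }
    v <- as.matrix(ct$vertices)
    if (nrow(v) < 3L) stop("a contour needs at least 3 vertices")
    # drop an explicitly repeated closing vertex
    if (all(abs(v[1, ] - v[nrow(v), ]) < 1e-9)) v <- v[-nrow(v), , drop = FALSE]
    k <- which.min(abs(zs - ct$z))
    if (abs(zs[k] - ct$z) > grid$spacing[3] / 2 + 1e-9)
      stop(sprintf("contour plane z = %.3f mm does not align with any grid slice (nearest slice at %.3f mm, spacing %.3f mm)",
                   ct$z, zs[k], grid$spacing[3]))
    occ[, , k] <- xor(occ[, , k], point_in_polygon_grid(xs, ys, v))
  }
  structure_mask(label, grid, occ)
}

# Even-odd (crossing-number) containment of all (xs[i], ys[j]) grid points
# in one polygon; returns a logical matrix length(xs) x length(ys).
point_in_polygon_grid <- function(xs, ys, vertices) {
  n <- nrow(vertices)
  inside <- matrix(FALSE, length(xs), length(ys))
  px <- vertices[, 1]; py <- vertices[, 2]
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]
    x2 <- px[if (e == n) 1L else e + 1L]; y2 <- py[if (e == n) 1L else e + 1L]
    if (y1 == y2) next  # horizontal edges never cross a horizontal ray
    # rows of voxel-centre y strictly between the edge's y-range
    cross_y <- which((ys >= min(y1, y2)) & (ys < max(y1, y2)))
    if (!length(cross_y)) next
    x_at <- x1 + (ys[cross_y] - y1) / (y2 - y1) * (x2 - x1)
    for (jj in seq_along(cross_y)) {
      hit <- xs < x_at[jj]
      inside[hit, cross_y[jj]] <- !inside[hit, cross_y[jj]]
    }
  }
  inside
}

#' Read slice-wise contours from a plain-text file
#'
#' The contour exchange format is a JSON or YAML document: a list of
#' structures, each with a `label` and a list of `contours`, each contour
#' holding `z` (mm) and `vertices` (Nx2 array of x, y in mm). This is the
#' package's text-based entry path for polygon delineations exported from
#' a planning system.
#'
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @param grid a [voxel_grid] to rasterize onto.
#' @return A named list of [structure_mask] objects, one per structure.
#' @export
read_contours <- function(path, grid) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  structs <- if (!is.null(doc$structures)) doc$structures else doc
  out <- list()
  for (s in structs) {
    cts <- lapply(s$contours, function(ct) {
      list(vertices = matrix(unlist(ct$vertices), ncol = 2L, byrow = TRUE),
           z = as.numeric(ct$z))
    })
    out[[s$label]] <- rasterize_polygons(cts, grid, label = s$label)
  }
  out
}
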