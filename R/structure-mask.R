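#' Binary structure mask on a voxel grid
#'
#' A `structure_mask` records one observer's delineation of one named
#' structure (target or organ at risk) as a boolean occupancy field over
#' a [voxel_grid].
#'
#' @param label structure name, e.g. `"CTV-breast"`.
#' @param grid a [voxel_grid].
#' @param occupancy logical array with dimensions `grid$dims`, or `NULL`
#'   for an empty mask.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(label, grid, occupancy = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(occupancy))
    occupancy <- array(FALSE, grid$dims)
  if (!is.logical(occupancy)) {
    storage.mode(occupancy) <- "logical"
  }
  occupancy[is.na(occupancy)] <- FALSE
  if (!identical(dim(occupancy), as.integer(grid$dims)))
    stop(sprintf("occupancy dimensions (%s) do not match grid dims (%s)",
                 paste(dim(occupancy), collapse = "x"),
                 paste(grid$dims, collapse = "x")))
  structure(list(label = as.character(label), grid = grid,
                 occupancy = occupancy),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d occupied voxels (%.2f cc) on %s\n",
              x$label, sum(x$occupancy), volume_cc(x), format(x$grid)))
  invisible(x)
}

is_empty_mask <- function(mask) !any(mask$occupancy)

#' Structure volume in cubic centimetres
#'
#' Occupied-voxel count times the physical voxel volume. This is the
#' whole-voxel volume definition used throughout the package; no
#' partial-volume weighting is applied.
#'
#' @param mask a [structure_mask].
#' @return Volume in cc.
#' @examples
#' g <- voxel_grid(c(10, 10, 10), spacing = c(2, 2, 2))
#' occ <- array(FALSE, g$dims); occ[1:5, 1:5, 1:5] <- TRUE
#' volume_cc(structure_mask("box", g, occ))  # 125 voxels * 8 mm^3 = 1 cc
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * voxel_volume_mm3(mask$grid) / 1000
}

#' Voxelwise union of structure masks
#'
#' Used to group structures for joint analysis, e.g. pooling axillary
#' node levels I-IV with the interpectoral nodes into one nodal target.
#'
#' @param masks list of [structure_mask] objects sharing one grid.
#' @param label label for the combined structure.
#' @return A [structure_mask].
#' @export
union_masks <- function(masks, label = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  for (m in masks) stopifnot(inherits(m, "structure_mask"))
  for (m in masks[-1]) stopifnot_same_grid(masks[[1]]$grid, m$grid, "masks")
  occ <- masks[[1]]$occupancy
  for (m in masks[-1]) occ <- occ | m$occupancy
  if (is.null(label))
    label <- paste(vapply(masks, `[[`, "", "label"), collapse = "+")
  structure_mask(label, masks[[1]]$grid, occ)
}

#' Voxelwise intersection of two masks
#' @param a,b [structure_mask] objects on one grid.
#' @param label label for the result.
#' @return A [structure_mask].
#' @export
intersect_masks <- function(a, b, label = a$label) {
  stopifnot_same_grid(a$grid, b$grid, "masks")
  structure_mask(label, a$grid, a$occupancy & b$occupancy)
}

#' Voxelwise set difference a AND NOT b
#' @inheritParams intersect_masks
#' @return A [structure_mask].
#' @export
subtract_masks <- function(a, b, label = a$label) {
  stopifnot_same_grid(a$grid, b$grid, "masks")
  structure_mask(label, a$grid, a$occupancy & !b$occupancy)
}

#' Isotropic margin expansion (e.g. CTV to PTV)
#'
#' A voxel belongs to the expanded mask iff the Euclidean distance from
#' its centre to the nearest occupied input voxel centre is at most
#' `margin_mm`. Distances honour anisotropic spacing and are exact
#' (computed by a Euclidean distance transform). The result is always a
#' superset of the input, and expansion is monotone in the margin. The
#' expansion is purely geometric: it is not cropped at the body surface.
#' Apply [intersect_masks()] with the body mask afterwards if a
#' skin-cropped planning volume is wanted.
#'
#' @param mask a [structure_mask].
#' @param margin_mm nonnegative margin in mm (5 mm is the conventional
#'   CTV-to-PTV margin used here).
#' @param label label for the expanded structure; defaults to the input
#'   label.
#' @return A [structure_mask].
#' @export
expand_mask <- function(mask, margin_mm, label = mask$label) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L ||
      is.na(margin_mm) || margin_mm < 0)
    stop("`margin_mm` must be a single nonnegative length in mm")
  if (margin_mm == 0 || is_empty_mask(mask))
    return(structure_mask(label, mask$grid, mask$occupancy))
  d2 <- .edt_squared(mask$occupancy, mask$grid$dims, mask$grid$spacing)
  occ <- array(d2 <= margin_mm^2, mask$grid$dims)
  structure_mask(label, mask$grid, occ)
}

#' Border extents of a structure in world coordinates
#'
#' Extreme world coordinates of occupied voxel centres: cranial = maximum
#' z, caudal = minimum z. The medial/lateral assignment of the x extremes
#' depends on laterality: for a left-sided structure the lateral border is
#' the maximum x (patient-left) and the medial border the minimum x;
#' mirrored for right-sided structures.
#'
#' @param mask a non-empty [structure_mask].
#' @param laterality `"left"` or `"right"`.
#' @return A `border_extents` object: list with `cranial_mm`, `caudal_mm`,
#'   `medial_mm`, `lateral_mm`, `anterior_mm`, `posterior_mm`.
#' @export
border_extents <- function(mask, laterality = c("left", "right")) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(mask, "structure_mask"))
  if (is_empty_mask(mask))
    stop(sprintf("structure '%s' is empty: border extents are undefined",
                 mask$label))
  occ_any <- function(axis) {
    which(apply(mask$occupancy, axis, any))
  }
  xs <- axis_coords(mask$grid, 1L)[occ_any(1L)]
  ys <- axis_coords(mask$grid, 2L)[occ_any(2L)]
  zs <- axis_coords(mask$grid, 3L)[occ_any(3L)]
  ext <- list(cranial_mm = max(zs), caudal_mm = min(zs),
              anterior_mm = min(ys), posterior_mm = max(ys))
  if (laterality == "left") {
    ext$lateral_mm <- max(xs); ext$medial_mm <- min(xs)
  } else {
    ext$lateral_mm <- min(xs); ext$medial_mm <- max(xs)
  }
  structure(ext, class = "border_extents", label = mask$label)
}

#' @export
print.border_extents <- function(x, ...) {
  cat(sprintf("<border_extents> '%s': cranial %.1f, caudal %.1f, medial %.1f, lateral %.1f mm\n",
              attr(x, "label"), x$cranial_mm, x$caudal_mm, x$medial_mm,
              x$lateral_mm))
  invisible(x)
}

#' Maximum pairwise border differences across observers
#'
#' For each requested border, the largest absolute difference in that
#' border's world coordinate between any two observers delineating the
#' structure, reported in cm (the unit conventionally used for border
#' discrepancies).
#'
#' @param sets list of [structure_set] objects.
#' @param label structure label to compare.
#' @param borders character vector among
#'   `c("cranial", "caudal", "medial", "lateral")`.
#' @param laterality passed to [border_extents()].
#' @return data.frame with columns `border` and `max_difference_cm`.
#' @export
border_difference_table <- function(sets, label,
                                    borders = c("cranial", "caudal",
                                                "medial", "lateral"),
                                    laterality = "left") {
  borders <- match.arg(borders, several.ok = TRUE)
  ext <- list()
  for (s in sets) {
    if (!label %in% names(s$masks)) {
      warning(sprintf("observer '%s' has no structure '%s'; skipped",
                      s$observer_id, label))
      next
    }
    ext[[s$observer_id]] <- border_extents(s$masks[[label]], laterality)
  }
  if (length(ext) < 2L)
    stop(sprintf("need at least 2 observers with structure '%s'", label))
  out <- data.frame(border = borders,
                    max_difference_cm = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(borders)) {
    v <- vapply(ext, function(e) e[[paste0(borders[i], "_mm")]], 0)
    out$max_difference_cm[i] <- (max(v) - min(v)) / 10
  }
  out
}

#' Resample a mask to a reference grid (nearest neighbour)
#'
#' Binary masks from different observers must live on one reference grid
#' before comparison. Each target voxel takes the value of the source
#' voxel whose centre is nearest to the target voxel centre; target
#' voxels outside the source extent are unoccupied.
#'
#' @param mask a [structure_mask].
#' @param target a [voxel_grid].
#' @return A [structure_mask] on `target`.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "structure_mask"), inherits(target, "voxel_grid"))
  if (grid_equal(mask$grid, target)) return(mask)
  src <- mask$grid
  ijk <- lapply(1:3, function(a) {
    i <- round((axis_coords(target, a) - src$origin[a]) / src$spacing[a]) + 1
    i[i < 1L | i > src$dims[a]] <- NA_integer_
    as.integer(i)
  })
  occ <- array(FALSE, target$dims)
  ok1 <- !is.na(ijk[[1]]); ok2 <- !is.na(ijk[[2]]); ok3 <- !is.na(ijk[[3]])
  occ[ok1, ok2, ok3] <- mask$occupancy[ijk[[1]][ok1], ijk[[2]][ok2],
                                       ijk[[3]][ok3]]
  structure_mask(mask$label, target, occ)
}
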