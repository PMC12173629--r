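# Fixtures built in code and independent brute-force oracles.

make_grid <- function(dims, spacing = c(1, 1, 1), origin = NULL) {
  if (is.null(origin)) origin <- -(dims - 1) * spacing / 2
  voxel_grid(dims, spacing, origin)
}

sphere_mask <- function(grid, center, radius, label = "sphere") {
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
  zs <- axis_coords(grid, 3)
  occ <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
               (zs - center[3])^2, `+`) <= radius^2
  structure_mask(label, grid, occ)
}

box_mask <- function(grid, lo_idx, hi_idx, label = "box") {
  occ <- array(FALSE, grid$dims)
  occ[lo_idx[1]:hi_idx[1], lo_idx[2]:hi_idx[2], lo_idx[3]:hi_idx[3]] <- TRUE
  structure_mask(label, grid, occ)
}

# Random connected-ish blob: union of 1-3 random spheres inside the grid.
random_blob <- function(grid, seed, label = "blob") {
  set.seed(seed)
  ext <- (grid$dims - 1) * grid$spacing
  occ <- array(FALSE, grid$dims)
  for (i in seq_len(sample(1:3, 1))) {
    ctr <- grid$origin + ext * runif(3, 0.25, 0.75)
    r <- runif(1, 0.12, 0.3) * min(ext)
    occ <- occ | sphere_mask(grid, ctr, r)$occupancy
  }
  if (!any(occ)) occ[ceiling(grid$dims / 2)[1],
                     ceiling(grid$dims / 2)[2],
                     ceiling(grid$dims / 2)[3]] <- TRUE
  structure_mask(label, grid, occ)
}

# O(n^2) brute-force surface dice: all pairwise face-centre distances.
bf_surface_dice <- function(maskA, maskB, tolerance_mm) {
  sa <- extract_surface(maskA)
  sb <- extract_surface(maskB)
  d2 <- outer(rowSums(sa$position^2), rowSums(sb$position^2), `+`) -
    2 * sa$position %*% t(sb$position)
  d2[d2 < 0] <- 0
  tol2 <- tolerance_mm^2 + 1e-9
  near_a <- apply(d2, 1, min) <= tol2
  near_b <- apply(d2, 2, min) <= tol2
  (sum(sa$area_mm2[near_a]) + sum(sb$area_mm2[near_b])) /
    (sa$total_area_mm2 + sb$total_area_mm2)
}

# Brute-force even-odd point-in-polygon (independent of the package's
# vectorized implementation).
bf_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Random nonnegative dose field on a grid.
random_dose <- function(grid, seed, prescription_gy = 40.05) {
  set.seed(seed)
  dose_grid(grid, array(runif(prod(grid$dims), 0, 1.1 * prescription_gy),
                        grid$dims),
            prescription_gy = prescription_gy)
}

# Trilinear sampling of a 3D array at world points (test-side oracle).
trilinear_at <- function(arr, grid, pts) {
  cont <- sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`) + 1
  lo <- pmin(pmax(floor(cont), 1),
             matrix(rep(grid$dims - 1L, each = nrow(cont)), ncol = 3))
  fr <- cont - lo
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
      (if (cy) fr[, 2] else 1 - fr[, 2]) *
      (if (cz) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * arr[cbind(lo[, 1] + cx, lo[, 2] + cy, lo[, 3] + cz)]
  }
  acc
}

# Small phantom spec for pipeline tests: same anatomy scaled down by
# coarsening the grid keeps runtimes short.
small_phantom <- function() phantom_spec(spacing_mm = c(4, 4, 4),
                                         dims = c(84, 60, 70))
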