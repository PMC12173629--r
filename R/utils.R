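# Internal numerical helpers shared by the synthetic-data generators.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Separable 3D Gaussian smoothing with physical kernel scale sd_mm,
# normalized weights, replicate padding at the edges.
gaussian_smooth_3d <- function(arr, sd_mm, spacing) {
  if (sd_mm <= 0) return(arr)
  for (axis in 1:3) {
    r <- max(1L, ceiling(3 * sd_mm / spacing[axis]))
    k <- stats::dnorm((-r:r) * spacing[axis], sd = sd_mm)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, axis)
  }
  arr
}

# 1D convolution along one array axis with replicate edge padding.
convolve_axis <- function(arr, kernel, axis) {
  array(.convolve_axis3d(as.numeric(arr), dim(arr), kernel, axis - 1L),
        dim(arr))
}

# Shift a 3D array by an integer voxel offset; vacated entries are
# `fill` (or the edge value when replicate_edge = TRUE).
shift_array <- function(arr, shift, fill = 0, replicate_edge = FALSE) {
  d <- dim(arr)
  idx <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - shift[a]
    if (replicate_edge) pmin(pmax(i, 1L), d[a]) else i
  })
  if (replicate_edge)
    return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  out <- array(fill, d)
  src <- lapply(1:3, function(a) idx[[a]][idx[[a]] >= 1L & idx[[a]] <= d[a]])
  dst <- lapply(1:3, function(a) which(idx[[a]] >= 1L & idx[[a]] <= d[a]))
  if (all(lengths(src) > 0L))
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Signed Euclidean distance (mm) from each voxel centre to the mask
# boundary: negative inside the structure, positive outside.
signed_distance <- function(mask) {
  occ <- mask$occupancy
  d2_in <- .edt_squared(occ, mask$grid$dims, mask$grid$spacing)
  d2_out <- .edt_squared(!occ, mask$grid$dims, mask$grid$spacing)
  sd <- sqrt(d2_in)
  sd[occ] <- -sqrt(d2_out[occ])
  array(sd, mask$grid$dims)
}
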