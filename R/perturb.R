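#' Observer boundary-noise specification
#'
#' Describes one simulated observer's deviation from the reference
#' delineation: boundaries are displaced by a smooth, spatially
#' correlated random field with standard deviation `sigma_mm` and
#' correlation length `correlation_mm`. The smoothness mimics how
#' clinicians differ — coherent over/under-inclusion of regions, never
#' voxel-level speckle.
#'
#' @param sigma_mm nonnegative displacement scale in mm.
#' @param correlation_mm positive smoothness length of the displacement
#'   field in mm (default 10).
#' @param seed integer RNG seed making the observer reproducible.
#' @return An `observer_noise_spec`.
#' @export
observer_noise_spec <- function(sigma_mm, correlation_mm = 10, seed = 1L) {
  if (!is.numeric(sigma_mm) || sigma_mm < 0)
    stop("`sigma_mm` must be >= 0")
  if (!is.numeric(correlation_mm) || correlation_mm <= 0)
    stop("`correlation_mm` must be > 0")
  structure(list(sigma_mm = as.numeric(sigma_mm),
                 correlation_mm = as.numeric(correlation_mm),
                 seed = as.integer(seed)),
            class = "observer_noise_spec")
}

#' Simulate one observer's delineation of the reference structures
#'
#' Each selected mask is re-thresholded from its signed distance field:
#' a voxel belongs to the perturbed structure iff its signed distance to
#' the reference boundary (negative inside) is at most the value of a
#' smooth zero-mean random field with standard deviation `sigma_mm`.
#' This displaces the boundary locally by approximately the field value,
#' keeps perturbed structures closed and clinically plausible, returns
#' the reference exactly when `sigma_mm = 0`, and is fully reproducible
#' under the spec's seed. One field is drawn per observer and applied to
#' all of that observer's structures, so an observer who reads an
#' anatomical boundary generously does so coherently across adjacent
#' structures.
#'
#' @param reference a [structure_set] (typically from [make_phantom()]).
#' @param noise an [observer_noise_spec].
#' @param observer_id name of the simulated observer.
#' @param labels which structures to perturb (default: all except
#'   `"Body"`, which is patient anatomy, not a delineation).
#' @return A [structure_set] with the same labels as the reference.
#' @export
perturb_observer <- function(reference, noise,
                             observer_id = sprintf("sim-%d", noise$seed),
                             labels = setdiff(set_labels(reference), "Body")) {
  stopifnot(inherits(reference, "structure_set"),
            inherits(noise, "observer_noise_spec"))
  out <- structure_set(observer_id)
  fld <- NULL
  for (lab in set_labels(reference)) {
    m <- reference$masks[[lab]]
    if (!(lab %in% labels) || noise$sigma_mm == 0 || is_empty_mask(m)) {
      out <- add_mask(out, structure_mask(lab, m$grid, m$occupancy))
      next
    }
    if (is.null(fld))
      fld <- random_displacement_field(m$grid, noise$sigma_mm,
                                       noise$correlation_mm, noise$seed)
    occ <- array(signed_distance(m) <= fld, m$grid$dims)
    out <- add_mask(out, structure_mask(lab, m$grid, occ))
  }
  out
}

# Smooth zero-mean Gaussian random field with pointwise sd sigma_mm:
# white noise generated on a grid padded by the kernel radius, smoothed
# at the correlation length, and cropped back, so the field is exactly
# stationary; the rescale factor is the closed-form stationary standard
# deviation of the smoothed process (square root of the summed squared
# 3D kernel weights).
random_displacement_field <- function(grid, sigma_mm, correlation_mm, seed) {
  r <- vapply(1:3, function(axis)
    max(1L, as.integer(ceiling(3 * correlation_mm / grid$spacing[axis]))), 0L)
  pad_dims <- grid$dims + 2L * r
  noise <- with_seed(seed, array(stats::rnorm(prod(pad_dims)), pad_dims))
  fld <- gaussian_smooth_3d(noise, correlation_mm, grid$spacing)
  fld <- fld[r[1] + seq_len(grid$dims[1]),
             r[2] + seq_len(grid$dims[2]),
             r[3] + seq_len(grid$dims[3])]
  sd_stationary <- sqrt(prod(vapply(1:3, function(axis) {
    k <- stats::dnorm((-r[axis]:r[axis]) * grid$spacing[axis],
                      sd = correlation_mm)
    sum((k / sum(k))^2)
  }, 0)))
  fld * (sigma_mm / sd_stationary)
}

#' Generate a cohort of simulated observers
#'
#' Convenience wrapper producing `n` observers with independent seeds
#' derived from a base seed, all at one noise level.
#'
#' @param reference a [structure_set].
#' @param n number of observers.
#' @param sigma_mm boundary noise scale in mm.
#' @param correlation_mm smoothness length in mm.
#' @param seed base seed; observer i uses `seed + i`.
#' @param labels structures to perturb (see [perturb_observer()]).
#' @return List of [structure_set] objects named `obs-01`, `obs-02`, ...
#' @export
simulate_cohort <- function(reference, n, sigma_mm, correlation_mm = 10,
                            seed = 1L,
                            labels = setdiff(set_labels(reference), "Body")) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    perturb_observer(reference,
                     observer_noise_spec(sigma_mm, correlation_mm, seed + i),
                     observer_id = sprintf("obs-%02d", i),
                     labels = labels)
  })
}
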