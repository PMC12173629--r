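#' Simplified dose model for a planning target
#'
#' An idealized stand-in for a planned dose distribution, built from
#' geometry alone: the planning target is expanded by twice the penumbra
#' scale (the "field"), extended along the beam axis to provide flash
#' (tangential fields run laterally-oblique across the chest in the x-y
#' plane; AP-PA fields run anterior-posterior), smoothed with a Gaussian
#' of scale `penumbra_mm`, and scaled to the prescription. A uniform
#' low-dose bath of `bath_fraction` times the prescription is added
#' inside the body, and dose is identically zero outside the body. The
#' model is deterministic and bounded by
#' `prescription * (1 + bath_fraction)`.
#'
#' As `penumbra_mm` approaches 0 the distribution converges to the
#' prescription inside the PTV and zero outside (field margin and flash
#' both scale with the penumbra). It is not a beam-transport
#' calculation; it exists so the dosimetric machinery can be exercised
#' and so geometric changes in the target propagate to organ-at-risk
#' dose the way tangential-field geometry makes them propagate (a
#' target reaching closer to the heart drags the dose cloud with it).
#'
#' @param ptv planning target [structure_mask].
#' @param body body [structure_mask] on the same grid; the PTV is
#'   required to lie inside it (enforced by intersection).
#' @param technique `"tangential"` or `"ap_pa"`.
#' @param penumbra_mm nonnegative dose fall-off scale in mm (default 5).
#' @param bath_fraction scatter bath as a fraction of prescription in
#'   `[0, 1)` (default 0.02).
#' @param prescription_gy,n_fractions prescription (defaults 40.05 Gy in
#'   15 fractions).
#' @param flash_factor beam-axis extension of the field, in multiples of
#'   `penumbra_mm` (default 4).
#' @return A [dose_grid].
#' @export
synthetic_dose <- function(ptv, body,
                           technique = c("tangential", "ap_pa"),
                           penumbra_mm = 5, bath_fraction = 0.02,
                           prescription_gy = 40.05, n_fractions = 15L,
                           flash_factor = 4) {
  technique <- match.arg(technique)
  stopifnot(inherits(ptv, "structure_mask"), inherits(body, "structure_mask"))
  stopifnot_same_grid(ptv$grid, body$grid, "ptv and body")
  if (!is.numeric(penumbra_mm) || penumbra_mm < 0)
    stop("`penumbra_mm` must be >= 0")
  if (!is.numeric(bath_fraction) || bath_fraction < 0 || bath_fraction >= 1)
    stop("`bath_fraction` must lie in [0, 1)")
  g <- ptv$grid
  field <- intersect_masks(ptv, body, label = "field")$occupancy
  if (penumbra_mm > 0)
    field <- expand_mask(structure_mask("field", g, field),
                         2 * penumbra_mm)$occupancy

  # beam-axis flash: OR of copies shifted along the beam direction
  step <- beam_step(technique, g)
  flash_mm <- flash_factor * penumbra_mm
  step_len <- sqrt(sum((step * g$spacing)^2))
  n_steps <- if (penumbra_mm > 0) floor(flash_mm / step_len) else 0L
  if (n_steps > 0) {
    acc <- field
    for (t in seq_len(n_steps)) {
      acc <- acc | shift_array(field, t * step, fill = FALSE)
      acc <- acc | shift_array(field, -t * step, fill = FALSE)
    }
    field <- acc
  }

  profile <- gaussian_smooth_3d(field + 0, penumbra_mm, g$spacing)
  dose <- prescription_gy * profile + bath_fraction * prescription_gy
  dose[!body$occupancy] <- 0
  dose_grid(g, dose, prescription_gy, n_fractions)
}

beam_step <- function(technique, grid) {
  if (technique == "ap_pa") c(0L, 1L, 0L) else c(1L, -1L, 0L)
}

#' Composite locoregional plan
#'
#' Combines a tangential field on the breast (plus internal-mammary)
#' planning target with an AP-PA field on the nodal planning target by
#' taking the voxelwise maximum, mirroring the conventional field
#' arrangement for locoregional breast treatment.
#'
#' @param ptv_tangential PTV for the tangential fields (breast, and
#'   usually the internal-mammary chain).
#' @param ptv_appa PTV for the AP-PA fields (nodal volumes), or `NULL`
#'   for whole-breast treatment only.
#' @param body body [structure_mask].
#' @param ... passed on to [synthetic_dose()].
#' @return A [dose_grid].
#' @export
composite_plan <- function(ptv_tangential, ptv_appa, body, ...) {
  d1 <- synthetic_dose(ptv_tangential, body, technique = "tangential", ...)
  if (is.null(ptv_appa)) return(d1)
  d2 <- synthetic_dose(ptv_appa, body, technique = "ap_pa", ...)
  dose_grid(body$grid, pmax(d1$dose, d2$dose),
            d1$prescription_gy, d1$n_fractions)
}
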