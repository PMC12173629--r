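#' Absolute dose distribution on a voxel grid
#'
#' Holds dose in Gy per voxel together with the prescription it was
#' planned for. All dose metrics in the package use whole-voxel counting
#' over a structure's occupied voxels; no partial-volume weighting is
#' applied, so every metric is exactly reproducible by direct voxel
#' counting.
#'
#' @param grid a [voxel_grid].
#' @param dose numeric array of absolute dose in Gy, dimensions
#'   `grid$dims`, all values >= 0.
#' @param prescription_gy prescribed total dose in Gy (> 0); the
#'   moderately hypofractionated breast schedule of 40.05 Gy is the
#'   package default elsewhere.
#' @param n_fractions positive integer fraction count.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose, prescription_gy, n_fractions = 15L) {
  stopifnot(inherits(grid, "voxel_grid"))
  dose <- array(as.numeric(dose), grid$dims)
  if (anyNA(dose) || any(dose < 0))
    stop("dose must be nonnegative Gy everywhere")
  if (!is.numeric(prescription_gy) || length(prescription_gy) != 1L ||
      prescription_gy <= 0)
    stop("`prescription_gy` must be a single positive dose in Gy")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("`n_fractions` must be a positive integer")
  structure(list(grid = grid, dose = dose,
                 prescription_gy = as.numeric(prescription_gy),
                 n_fractions = n_fractions),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s, prescription %.2f Gy in %d fractions, max %.2f Gy\n",
              format(x$grid), x$prescription_gy, x$n_fractions, max(x$dose)))
  invisible(x)
}

structure_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  stopifnot_same_grid(dose$grid, mask$grid, "dose and mask")
  dose$dose[mask$occupancy]
}

#' Resample a dose grid to a target voxel grid
#'
#' Trilinear interpolation of the dose at the target voxel centres.
#' Structures define the analysis frame, so dose is always resampled to
#' the structure grid, never the reverse. Target voxels outside the
#' source extent receive 0 Gy with a warning; fully disjoint extents are
#' rejected.
#'
#' @param dose a [dose_grid].
#' @param target a [voxel_grid].
#' @return A [dose_grid] on `target`.
#' @export
resample_dose <- function(dose, target) {
  stopifnot(inherits(dose, "dose_grid"), inherits(target, "voxel_grid"))
  if (grid_equal(dose$grid, target)) return(dose)
  src <- dose$grid
  cont <- lapply(1:3, function(a)
    (axis_coords(target, a) - src$origin[a]) / src$spacing[a] + 1)
  inside <- lapply(1:3, function(a)
    cont[[a]] >= 1 - 1e-9 & cont[[a]] <= src$dims[a] + 1e-9)
  if (!any(inside[[1]]) || !any(inside[[2]]) || !any(inside[[3]]))
    stop("dose grid and target grid extents are disjoint")
  if (!all(inside[[1]] & TRUE) || !all(inside[[2]]) || !all(inside[[3]]))
    warning("target grid extends outside the dose grid; outside voxels set to 0 Gy")
  # per-axis floor index and fraction, clamped to the last cell
  lo <- lapply(1:3, function(a) {
    i <- pmin(pmax(floor(cont[[a]]), 1), src$dims[a] - 1L)
    if (src$dims[a] == 1L) i <- rep(1L, length(cont[[a]]))
    as.integer(i)
  })
  fr <- lapply(1:3, function(a) {
    if (src$dims[a] == 1L) rep(0, length(cont[[a]]))
    else cont[[a]] - lo[[a]]
  })
  d <- src$dims
  nxt <- function(a) pmin(lo[[a]] + 1L, d[a])
  hi <- lapply(1:3, nxt)
  arr <- dose$dose
  out <- array(0, target$dims)
  # accumulate the 8 trilinear corners with outer-product weights
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    iz <- if (cz) hi[[3]] else lo[[3]]
    wx <- if (cx) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy) fr[[2]] else 1 - fr[[2]]
    wz <- if (cz) fr[[3]] else 1 - fr[[3]]
    vals <- arr[ix, iy, iz, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + array(vals, target$dims) * w
  }
  mask_in <- outer(outer(inside[[1]], inside[[2]]), inside[[3]])
  out[!mask_in] <- 0
  dose_grid(target, out, dose$prescription_gy, dose$n_fractions)
}

#' Cumulative dose-volume histogram of a structure
#'
#' Cumulative "volume at or above dose" curve over the structure's
#' occupied voxels, sampled at regular dose thresholds. The curve is
#' nonincreasing, starts at 100% of the structure volume at 0 Gy, and is
#' the carrier for Dmean, VxGy and Dx% metrics (point metrics are
#' computed exactly from the voxel doses, not read off the binned
#' curve).
#'
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on the same grid (resample
#'   the dose first if needed).
#' @param bin_gy dose sampling step in Gy (default 0.01).
#' @return A `dvh_curve`: list with `structure`, `volume_cc`,
#'   `dose_gy` (thresholds), `cc` and `percent` (volume at-or-above).
#' @export
compute_dvh <- function(dose, mask, bin_gy = 0.01) {
  if (is_empty_mask(mask))
    stop(sprintf("structure '%s' is empty: DVH is undefined", mask$label))
  if (bin_gy <= 0) stop("`bin_gy` must be positive")
  dv <- structure_doses(dose, mask)
  vox_cc <- voxel_volume_mm3(mask$grid) / 1000
  thresholds <- seq(0, max(dv) + bin_gy, by = bin_gy)
  # at-or-above counts via reversed cumulative histogram of bin indices
  bins <- findInterval(dv, thresholds)  # dv >= thresholds[k] iff bin >= k
  tab <- tabulate(bins, nbins = length(thresholds))
  at_or_above <- rev(cumsum(rev(tab)))
  structure(list(structure = mask$label,
                 volume_cc = length(dv) * vox_cc,
                 dose_gy = thresholds,
                 cc = at_or_above * vox_cc,
                 percent = 100 * at_or_above / length(dv)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> '%s': %.2f cc, %d dose samples up to %.2f Gy\n",
              x$structure, x$volume_cc, length(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' Mean structure dose in Gy
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask].
#' @return Dmean in Gy.
#' @export
d_mean <- function(dose, mask) {
  if (is_empty_mask(mask))
    stop(sprintf("structure '%s' is empty: Dmean is undefined", mask$label))
  mean(structure_doses(dose, mask))
}

#' Volume receiving at least a threshold dose (VxGy / Vx%)
#'
#' The structure volume at or above a dose threshold, as percent of the
#' structure or in absolute cc. The threshold is given in Gy
#' (`threshold_gy`) or as a percentage of the prescription
#' (`threshold_pct`; 105 means 1.05 x prescription, the high-dose
#' "V105%" body metric). The comparison is inclusive (>=); use
#' `strict = TRUE` for a strictly-greater threshold.
#'
#' @param dose a [dose_grid].
#' @param mask a [structure_mask].
#' @param threshold_gy absolute threshold in Gy.
#' @param threshold_pct threshold as % of prescription (exactly one of
#'   the two thresholds must be given).
#' @param output `"percent"` or `"cc"`.
#' @param strict logical; if `TRUE` count voxels strictly above the
#'   threshold.
#' @return The volume metric.
#' @export
v_dose <- function(dose, mask, threshold_gy = NULL, threshold_pct = NULL,
                   output = c("percent", "cc"), strict = FALSE) {
  output <- match.arg(output)
  if (is.null(threshold_gy) == is.null(threshold_pct))
    stop("give exactly one of `threshold_gy` or `threshold_pct`")
  if (!is.null(threshold_pct))
    threshold_gy <- threshold_pct / 100 * dose$prescription_gy
  if (is_empty_mask(mask)) {
    if (output == "percent")
      stop(sprintf("structure '%s' is empty: percent volume is undefined",
                   mask$label))
    return(0)
  }
  dv <- structure_doses(dose, mask)
  n <- if (strict) sum(dv > threshold_gy) else sum(dv >= threshold_gy)
  if (output == "percent") 100 * n / length(dv)
  else n * voxel_volume_mm3(mask$grid) / 1000
}

#' Dose covering a volume fraction, as percent of prescription (Dx%)
#'
#' `D98%` is the minimum dose received by the best-covered 98% of the
#' structure volume: the largest dose d such that at least p% of the
#' structure receives >= d. Computed by exact sorting of the voxel
#' doses (no DVH binning) and reported as a percentage of the
#' prescription dose, the unit used by coverage guidelines.
#'
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask].
#' @param p volume percentile in (0, 100]; default 98.
#' @return Dose as % of prescription.
#' @export
d_percent_coverage <- function(dose, mask, p = 98) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 100)
    stop("`p` must lie in (0, 100]")
  if (is_empty_mask(mask))
    stop(sprintf("structure '%s' is empty: D%% is undefined", mask$label))
  dv <- sort(structure_doses(dose, mask), decreasing = TRUE)
  d <- dv[ceiling(p / 100 * length(dv))]
  100 * d / dose$prescription_gy
}

#' ICRU-50 treated and irradiated volumes
#'
#' Within the body structure: the treated volume receives at least 90%
#' of the prescription and the irradiated volume at least 50%. The
#' treated volume is always a subset of the irradiated volume.
#'
#' @param dose a [dose_grid].
#' @param body non-empty body [structure_mask].
#' @return List with `treated_cc` and `irradiated_cc`.
#' @export
icru_volumes <- function(dose, body) {
  if (is_empty_mask(body)) stop("body structure is empty")
  list(treated_cc = v_dose(dose, body, threshold_pct = 90, output = "cc"),
       irradiated_cc = v_dose(dose, body, threshold_pct = 50, output = "cc"))
}

#' High-dose volume outside the planning target
#'
#' Volume of normal tissue (body minus PTV) receiving strictly more than
#' 90% of the prescription dose — the "irradiated volume outside PTV"
#' used to judge how much of the high-dose region falls outside the
#' intended target. The strict (>) comparison follows the usual
#' definition of this spill metric; set `strict = FALSE` for at-or-above.
#'
#' @param dose a [dose_grid].
#' @param ptv planning target [structure_mask]; intersected with the body
#'   before subtraction so the PTV cannot extend past the patient
#'   outline.
#' @param body body [structure_mask].
#' @param strict logical, default `TRUE` (strictly greater than 90%).
#' @return Volume in cc.
#' @export
irradiated_outside_ptv <- function(dose, ptv, body, strict = TRUE) {
  ptv_in <- intersect_masks(ptv, body)
  outside <- subtract_masks(body, ptv_in, label = "body-outside-ptv")
  if (is_empty_mask(outside)) return(0)
  v_dose(dose, outside, threshold_pct = 90, output = "cc", strict = strict)
}

#' Guideline coverage verdicts from D98%
#'
#' Evaluates target-coverage criteria of the form "D98% of structure S
#' must be at least T percent of the prescription". The comparison is
#' inclusive: achieving exactly the threshold passes. Structures missing
#' from `masks` yield a non-evaluable verdict (`pass = NA`) rather than
#' an error, so a whole criteria table can be applied to partial
#' structure sets.
#'
#' @param dose a [dose_grid].
#' @param masks named list of [structure_mask] objects.
#' @param criteria data.frame with columns `structure` and
#'   `threshold_pct` (and optionally `p`, the volume percentile, default
#'   98). See [swedish_breast_criteria()] for the default set.
#' @return data.frame with columns `structure`, `metric`, `threshold_pct`,
#'   `achieved_pct`, `pass`.
#' @export
coverage_report <- function(dose, masks, criteria = swedish_breast_criteria()) {
  stopifnot(is.data.frame(criteria),
            all(c("structure", "threshold_pct") %in% names(criteria)))
  p <- if ("p" %in% names(criteria)) criteria$p else rep(98, nrow(criteria))
  out <- data.frame(structure = criteria$structure,
                    metric = sprintf("D%g%%", p),
                    threshold_pct = criteria$threshold_pct,
                    achieved_pct = NA_real_,
                    pass = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(criteria))) {
    m <- masks[[criteria$structure[i]]]
    if (is.null(m) || is_empty_mask(m)) next
    ach <- d_percent_coverage(dose, m, p = p[i])
    out$achieved_pct[i] <- ach
    out$pass[i] <- ach >= criteria$threshold_pct[i]
  }
  out
}

#' Default coverage criteria for adjuvant breast radiotherapy
#'
#' The Swedish national guideline thresholds: the breast and nodal
#' clinical targets together must reach D98% >= 95% of prescription,
#' the internal-mammary target D98% >= 90%, and the combined planning
#' targets D98% >= 93%.
#'
#' @return data.frame usable as the `criteria` argument of
#'   [coverage_report()].
#' @export
swedish_breast_criteria <- function() {
  data.frame(structure = c("CTV-breast+CTVN", "CTV-IMN", "PTV-breast+PTVN"),
             threshold_pct = c(95, 90, 93),
             p = c(98, 98, 98),
             stringsAsFactors = FALSE)
}
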