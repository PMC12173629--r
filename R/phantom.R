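#' Specification of the anthropomorphic thorax phantom
#'
#' Parameterizes a synthetic left-sided (by default) breast-radiotherapy
#' patient: an elliptic-cylinder body with breast bulges, a hemi-
#' ellipsoidal breast clinical target on the anterior chest wall, an
#' axillary/supraclavicular nodal cluster (levels I-IV plus the
#' interpectoral nodes), a thin parasternal internal-mammary node tube,
#' and ellipsoid/tube organs at risk (heart, both lungs, contralateral
#' breast, esophagus, thyroid, humeral head). All positions and radii
#' are world mm in the package's axis convention (x right-to-left,
#' y anterior-to-posterior, z caudal-to-cranial), centred on the
#' patient midline. Default sizes put the structure volumes in the
#' range typical of adjuvant breast radiotherapy (breast target of
#' order 850 cc, grouped nodal target of order 100 cc, internal-mammary
#' target of order 5 cc).
#'
#' @param spacing_mm isotropic-by-default voxel spacing (length 1 or 3).
#' @param dims grid dimensions; the default covers a 330 x 240 x 280 mm
#'   thorax section.
#' @param laterality `"left"` or `"right"` (right mirrors every x).
#' @param breast_center,breast_semiaxes geometry of the breast target
#'   hemi-ellipsoid (flat side on the chest-wall plane, bulging
#'   anteriorly).
#' @return A `phantom_spec` list understood by [make_phantom()].
#' @export
phantom_spec <- function(spacing_mm = c(2.5, 2.5, 2.5),
                         dims = c(132L, 96L, 112L),
                         laterality = c("left", "right"),
                         breast_center = c(70, -55, -30),
                         breast_semiaxes = c(85, 60, 80)) {
  laterality <- match.arg(laterality)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  dims <- as.integer(dims)
  origin <- -(dims - 1) * spacing_mm / 2
  spec <- list(
    grid = voxel_grid(dims, spacing_mm, origin),
    laterality = laterality,
    body = list(center_xy = c(0, 0), semiaxes_xy = c(150, 100)),
    breast = list(center = breast_center, semiaxes = breast_semiaxes),
    # skin bulge enclosing each breast so targets stay inside the body
    breast_bulge_mm = 5,
    nodal_levels = list(
      `CTVN-L1` = list(center = c(95, -5, 30), semiaxes = c(22, 20, 25)),
      `CTVN-L2` = list(center = c(75, -10, 55), semiaxes = c(18, 16, 20)),
      `CTVN-L3` = list(center = c(55, -15, 75), semiaxes = c(15, 14, 16)),
      `CTVN-L4` = list(center = c(35, -20, 95), semiaxes = c(13, 12, 14)),
      `CTVN-IP` = list(center = c(80, -30, 40), semiaxes = c(10, 9, 12))),
    imn = list(center_xy = c(18, -80), radius_mm = 4.5, z_range = c(-35, 55)),
    heart = list(center = c(15, 0, -65), semiaxes = c(55, 50, 55)),
    lung_ipsi = list(center = c(80, 15, 10), semiaxes = c(45, 60, 100)),
    lung_contra = list(center = c(-80, 15, 10), semiaxes = c(45, 60, 100)),
    breast_contra = list(center = c(-70, -55, -30), semiaxes = c(60, 45, 55)),
    esophagus = list(center_xy = c(-8, 25), radius_mm = 6,
                     z_range = c(-100, 110)),
    thyroid = list(center = c(0, -35, 100), semiaxes = c(20, 11, 13)),
    humeral_head = list(center = c(140, -5, 95), semiaxes = c(20, 20, 20)))
  class(spec) <- "phantom_spec"
  spec
}

mirror_x <- function(p) { p[1] <- -p[1]; p }

#' Build the phantom structure set
#'
#' Deterministically rasterizes every structure of a [phantom_spec] onto
#' its grid and returns them as one observer ("reference"). The grouped
#' nodal target `CTVN` (union of levels I-IV and the interpectoral
#' nodes) is emitted alongside the individual levels. Structures whose
#' analytic bounding box leaves the grid are rejected, and target
#' structures are checked to lie inside the body.
#'
#' @param spec a [phantom_spec].
#' @param observer_id observer name for the returned set.
#' @return A [structure_set] containing `Body`, `CTV-breast`, `CTVN`
#'   (plus its levels), `CTV-IMN`, and the organs at risk.
#' @export
make_phantom <- function(spec = phantom_spec(), observer_id = "reference") {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  co <- grid_coordinate_arrays(g)
  flip <- spec$laterality == "right"
  fx <- function(center) if (flip) mirror_x(center) else center

  ell <- function(center, semi) {
    center <- fx(center)
    check_bbox(g, center - semi, center + semi)
    ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
      ((co$z - center[3]) / semi[3])^2 <= 1
  }
  hemi <- function(center, semi) {
    # anterior half only: the flat face lies on the chest-wall plane
    center <- fx(center)
    check_bbox(g, center - c(semi[1], semi[2], semi[3]),
               center + c(semi[1], 0, semi[3]))
    (((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
       ((co$z - center[3]) / semi[3])^2 <= 1) & (co$y <= center[2])
  }
  tube <- function(center_xy, r, z_range) {
    center_xy <- if (flip) c(-center_xy[1], center_xy[2]) else center_xy
    check_bbox(g, c(center_xy - r, z_range[1]), c(center_xy + r, z_range[2]))
    ((co$x - center_xy[1])^2 + (co$y - center_xy[2])^2 <= r^2) &
      co$z >= z_range[1] & co$z <= z_range[2]
  }

  b <- spec$body
  body_occ <- ((co$x - b$center_xy[1]) / b$semiaxes_xy[1])^2 +
    ((co$y - b$center_xy[2]) / b$semiaxes_xy[2])^2 <= 1
  body_occ <- body_occ |
    hemi(spec$breast$center, spec$breast$semiaxes + spec$breast_bulge_mm) |
    hemi(spec$breast_contra$center,
         spec$breast_contra$semiaxes + spec$breast_bulge_mm)

  masks <- list()
  add <- function(label, occ) structure_mask(label, g, occ)
  masks$Body <- add("Body", body_occ)
  masks$`CTV-breast` <- add("CTV-breast", hemi(spec$breast$center,
                                               spec$breast$semiaxes))
  for (nm in names(spec$nodal_levels)) {
    lv <- spec$nodal_levels[[nm]]
    masks[[nm]] <- add(nm, ell(lv$center, lv$semiaxes))
  }
  masks$CTVN <- union_masks(masks[names(spec$nodal_levels)], label = "CTVN")
  masks$`CTV-IMN` <- add("CTV-IMN", tube(spec$imn$center_xy,
                                         spec$imn$radius_mm,
                                         spec$imn$z_range))
  masks$Heart <- add("Heart", ell(spec$heart$center, spec$heart$semiaxes))
  masks$`Lung-ipsilateral` <- add("Lung-ipsilateral",
                                  ell(spec$lung_ipsi$center,
                                      spec$lung_ipsi$semiaxes))
  masks$`Lung-contralateral` <- add("Lung-contralateral",
                                    ell(spec$lung_contra$center,
                                        spec$lung_contra$semiaxes))
  masks$`Breast-contralateral` <- add("Breast-contralateral",
                                      hemi(spec$breast_contra$center,
                                           spec$breast_contra$semiaxes))
  masks$Esophagus <- add("Esophagus", tube(spec$esophagus$center_xy,
                                           spec$esophagus$radius_mm,
                                           spec$esophagus$z_range))
  masks$Thyroid <- add("Thyroid", ell(spec$thyroid$center,
                                      spec$thyroid$semiaxes))
  masks$`Humeral-head` <- add("Humeral-head", ell(spec$humeral_head$center,
                                                  spec$humeral_head$semiaxes))

  for (lab in c("CTV-breast", "CTVN", "CTV-IMN")) {
    if (any(masks[[lab]]$occupancy & !body_occ))
      stop(sprintf("target '%s' extends outside the body; adjust the phantom spec", lab))
  }
  structure_set(observer_id, masks)
}

grid_coordinate_arrays <- function(grid) {
  d <- grid$dims
  list(x = array(axis_coords(grid, 1L), d),
       y = array(rep(axis_coords(grid, 2L), each = d[1]), d),
       z = array(rep(axis_coords(grid, 3L), each = d[1] * d[2]), d))
}

check_bbox <- function(grid, lo, hi) {
  gmin <- grid$origin - grid$spacing / 2
  gmax <- grid$origin + (grid$dims - 1) * grid$spacing + grid$spacing / 2
  if (any(lo < gmin) || any(hi > gmax))
    stop(sprintf("structure bounding box [%s]..[%s] mm leaves the grid extent",
                 paste(round(lo, 1), collapse = ", "),
                 paste(round(hi, 1), collapse = ", ")))
  invisible(TRUE)
}
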