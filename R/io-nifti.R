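#' Read and write structure masks as NIfTI volumes
#'
#' Masks are stored as integer volumes (1 = occupied). Geometry (spacing
#' and the world position of the first voxel centre) travels in the NIfTI
#' sform as an axis-aligned affine; volumes whose affine is rotated or
#' axis-flipped are rejected rather than silently reinterpreted.
#'
#' @param mask a [structure_mask].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_mask_volume()` returns `path` invisibly;
#'   `read_mask_volume()` returns a [structure_mask].
#' @export
write_mask_volume <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  write_nifti_volume(array(as.integer(mask$occupancy), mask$grid$dims),
                     mask$grid, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask_volume
#' @param label structure label for the mask read back (file names carry
#'   no label).
#' @param threshold if `NULL` (default), the volume must be binary (all
#'   values 0 or 1); supply a numeric threshold to binarize a non-binary
#'   volume explicitly (occupied iff value >= threshold).
#' @export
read_mask_volume <- function(path, label = "structure", threshold = NULL) {
  v <- read_nifti_volume(path)
  vals <- as.vector(v$data)
  if (is.null(threshold)) {
    if (!all(vals %in% c(0, 1)))
      stop(sprintf("'%s' is not a binary volume; pass `threshold` to binarize explicitly", path))
    occ <- array(vals == 1, v$grid$dims)
  } else {
    occ <- array(vals >= threshold, v$grid$dims)
  }
  structure_mask(label, v$grid, occ)
}

#' Write a dose grid as a NIfTI volume in Gy
#' @param dose a [dose_grid].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_dose_volume <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  write_nifti_volume(dose$dose, dose$grid, path, datatype = "double")
  invisible(path)
}

#' @rdname write_dose_volume
#' @param prescription_gy,n_fractions prescription metadata to attach on
#'   read (NIfTI carries no prescription).
#' @export
read_dose_volume <- function(path, prescription_gy, n_fractions = 15L) {
  v <- read_nifti_volume(path)
  dose_grid(v$grid, v$data, prescription_gy = prescription_gy,
            n_fractions = n_fractions)
}

#' Write a consensus agreement map as a floating-point NIfTI volume
#' @param consensus a `consensus_structure` (see [mean_structure()]).
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_agreement_volume <- function(consensus, path) {
  stopifnot(inherits(consensus, "consensus_structure"))
  write_nifti_volume(consensus$agreement, consensus$grid, path,
                     datatype = "double")
  invisible(path)
}

write_nifti_volume <- function(data, grid, path, datatype = "double") {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 3L)
    stop(sprintf("'%s' is not a 3D volume (dims: %s)", path,
                 paste(dims, collapse = "x")))
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(sp)) > 1e-4 * max(sp)))
    stop(sprintf("'%s' has a rotated or flipped affine; only axis-aligned volumes in the package's x/y/z convention are supported", path))
  grid <- voxel_grid(dims, sp, origin = xf[1:3, 4])
  list(data = array(as.numeric(img), dims), grid = grid)
}
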