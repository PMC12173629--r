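#' Labelled collection of one observer's structure masks
#'
#' All masks in a set share one voxel grid; the shared-grid requirement
#' is enforced on insertion. The observer id names the delineating
#' clinic, model, or the synthetic reference.
#'
#' @param observer_id observer name.
#' @param masks optional named list of [structure_mask] objects, or an
#'   unnamed list (labels are taken from the masks).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(observer_id, masks = list()) {
  s <- structure(list(observer_id = as.character(observer_id),
                      grid = NULL, masks = list()),
                 class = "structure_set")
  for (m in masks) s <- add_mask(s, m)
  s
}

#' Insert a mask into a structure set
#' @param set a [structure_set].
#' @param mask a [structure_mask]; its label must not already be present
#'   and its grid must match the set's grid.
#' @return The updated [structure_set].
#' @export
add_mask <- function(set, mask) {
  stopifnot(inherits(set, "structure_set"), inherits(mask, "structure_mask"))
  if (mask$label %in% names(set$masks))
    stop(sprintf("duplicate structure label '%s' in set '%s'",
                 mask$label, set$observer_id))
  if (is.null(set$grid)) {
    set$grid <- mask$grid
  } else {
    stopifnot_same_grid(set$grid, mask$grid,
                        sprintf("set '%s' and mask '%s'",
                                set$observer_id, mask$label))
  }
  set$masks[[mask$label]] <- mask
  set
}

#' Retrieve a mask by label
#' @param set a [structure_set].
#' @param label structure label.
#' @return The [structure_mask], or an error if absent.
#' @export
get_mask <- function(set, label) {
  m <- set$masks[[label]]
  if (is.null(m))
    stop(sprintf("observer '%s' has no structure '%s'",
                 set$observer_id, label))
  m
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> observer '%s', %d structures on %s\n",
              x$observer_id, length(x$masks),
              if (is.null(x$grid)) "<no grid>" else format(x$grid)))
  for (m in x$masks)
    cat(sprintf("  %-22s %8.2f cc\n", m$label, volume_cc(m)))
  invisible(x)
}

#' Structure labels present in a set
#' @param set a [structure_set].
#' @return Character vector of labels.
#' @export
set_labels <- function(set) names(set$masks)
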