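#' Consensus ("mean") structure from multiple observers
#'
#' The consensus is built from the per-voxel mean of the observers'
#' binary masks: each voxel's agreement is the fraction of observers
#' occupying it, and the consensus mask contains exactly the voxels with
#' agreement >= 0.5. The threshold is inclusive, so with an even number
#' of observers a voxel claimed by exactly half of them belongs to the
#' consensus; the consensus therefore always contains the intersection
#' of the inputs and is contained in their union, and is invariant to
#' observer ordering.
#'
#' @param masks list of [structure_mask] objects on one grid, one per
#'   observer.
#' @param label label for the consensus mask; defaults to the first
#'   input's label.
#' @return A `consensus_structure`: list with `agreement` (numeric array
#'   of per-voxel fractions), `mask` (the thresholded [structure_mask]),
#'   `n_observers`, and `grid`.
#' @examples
#' g <- voxel_grid(c(5, 5, 1), spacing = c(1, 1, 1))
#' a <- array(FALSE, g$dims); a[1:3, , 1] <- TRUE
#' b <- array(FALSE, g$dims); b[2:4, , 1] <- TRUE
#' cs <- mean_structure(list(structure_mask("s", g, a),
#'                           structure_mask("s", g, b)))
#' volume_cc(cs$mask)  # every voxel claimed by either observer reaches 0.5
#' @export
mean_structure <- function(masks, label = NULL) {
  if (!is.list(masks) || length(masks) < 1L)
    stop("need at least one observer mask")
  for (m in masks) stopifnot(inherits(m, "structure_mask"))
  for (m in masks[-1]) stopifnot_same_grid(masks[[1]]$grid, m$grid, "masks")
  grid <- masks[[1]]$grid
  n <- length(masks)
  votes <- array(0L, grid$dims)
  for (m in masks) votes <- votes + m$occupancy
  agreement <- votes / n
  if (is.null(label)) label <- masks[[1]]$label
  structure(list(agreement = agreement,
                 mask = structure_mask(label, grid, agreement >= 0.5),
                 n_observers = n,
                 grid = grid),
            class = "consensus_structure")
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat(sprintf("<consensus_structure> '%s' from %d observers: %.2f cc at agreement >= 0.5\n",
              x$mask$label, x$n_observers, volume_cc(x$mask)))
  invisible(x)
}

#' Histogram of voxel counts per agreement level
#'
#' Diagnostic for observer variability: how many voxels are claimed by
#' each possible fraction of observers. Levels are the attainable
#' fractions `k / n_observers`; the zero level counts background voxels.
#'
#' @param consensus a `consensus_structure`.
#' @return data.frame with columns `agreement` (fraction), `n_observers_in`
#'   (the count k), and `n_voxels`.
#' @export
agreement_histogram <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_structure"))
  n <- consensus$n_observers
  votes <- round(consensus$agreement * n)
  counts <- tabulate(as.vector(votes) + 1L, nbins = n + 1L)
  data.frame(agreement = (0:n) / n,
             n_observers_in = 0:n,
             n_voxels = counts)
}
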