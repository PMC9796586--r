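#' Tissue masks for the three internal reference tissues
#'
#' Bundles gray-matter, white-matter and CSF masks (binary or probabilistic,
#' e.g. segmentation posterior maps) defined on a common voxel grid.
#'
#' @param gm,wm,csf 3D arrays on the same grid; logical masks or
#'   probabilities in `[0, 1]`.
#' @return An object of class `"tissue_masks"`: a named list of the three
#'   arrays.
#' @export
tissue_masks <- function(gm, wm, csf) {
  check_same_grid(gm, wm, "gm/wm masks")
  check_same_grid(gm, csf, "gm/csf masks")
  for (m in list(gm, wm, csf))
    if (length(dim(m)) != 3) stop("masks must be 3D volumes")
  structure(list(gm = gm, wm = wm, csf = csf), class = "tissue_masks")
}

#' Hard per-tissue masks from probabilistic segmentations
#'
#' Converts probabilistic tissue maps to mutually exclusive binary masks by
#' voxelwise argmax, keeping only voxels whose winning probability reaches
#' `floor` (default 0.5).  Already-binary masks pass through unchanged (up to
#' overlap resolution by argmax).
#'
#' @param masks a [tissue_masks()] object.
#' @param floor minimum winning probability for a voxel to be assigned.
#' @return A `"tissue_masks"` object of logical arrays.
#' @export
hard_masks <- function(masks, floor = 0.5) {
  stopifnot(inherits(masks, "tissue_masks"))
  p <- vapply(masks, as.numeric, numeric(length(masks$gm)))
  win <- max.col(p, ties.method = "first")
  top <- p[cbind(seq_len(nrow(p)), win)]
  keep <- top >= floor
  d <- dim(masks$gm)
  out <- lapply(1:3, function(i) array(keep & win == i, d))
  tissue_masks(out[[1]], out[[2]], out[[3]])
}

#' Brain mask from the union of reference tissue masks
#'
#' Skull-stripping mask built from the GM/WM/CSF segmentations: the union of
#' the three (hard) masks, followed by one binary dilation, morphological
#' hole filling, and one binary erosion (a closing).  The result always
#' contains the original union.
#'
#' @param masks a [tissue_masks()] object (probabilistic maps are hardened
#'   with [hard_masks()] first).
#' @return A logical 3D array.
#' @export
build_brain_mask <- function(masks) {
  hm <- hard_masks(masks)
  u <- hm$gm | hm$wm | hm$csf
  if (!any(u)) stop("empty tissue mask union: no brain voxels")
  erode3(fill_holes3(dilate3(u)))
}
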