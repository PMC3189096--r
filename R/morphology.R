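# Binary morphology on logical matrices. Out-of-image pixels count as
# background, so erosion shrinks objects touching the border.

#' Binary erosion
#'
#' @param mask logical matrix.
#' @param radius structuring-element radius in pixels.
#' @param element `"disk"` (radius-1 disk is the 3x3 cross) or `"square"`.
#' @return eroded logical matrix.
#' @export
binary_erode <- function(mask, radius = 1, element = c("disk", "square")) {
  mask <- assert_mask(mask)
  off <- element_offsets(radius, element)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off$dr[i], off$dc[i], fill = FALSE)
  out
}

#' Binary dilation
#'
#' @inheritParams binary_erode
#' @return dilated logical matrix.
#' @export
binary_dilate <- function(mask, radius = 1, element = c("disk", "square")) {
  mask <- assert_mask(mask)
  off <- element_offsets(radius, element)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dr[i], off$dc[i], fill = FALSE)
  out
}

#' Fill enclosed holes
#'
#' Background components (4-connectivity) not reachable from the image
#' border are holes and become foreground.
#'
#' @param mask logical matrix.
#' @return hole-free logical matrix.
#' @export
fill_holes <- function(mask) {
  mask <- assert_mask(mask)
  lab <- label_components_cpp(!mask, 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

#' Morphological refinement of the preliminary tumor mask
#'
#' Erodes the mask to detach residual neighboring tissue, keeps the largest
#' connected component (discarding the detached residue, which a bare
#' opening would reattach), dilates by the same element to restore the
#' margin, and fills enclosed holes so a heterogeneous tumor comes out
#' solid. With `radius = 0` only hole filling is performed.
#'
#' @param mask logical matrix, non-empty.
#' @param radius structuring-element radius (default 1).
#' @param element `"disk"` or `"square"`.
#' @param connectivity connectivity for the largest-component step.
#' @return refined logical matrix: connected (for a connected input) and
#'   hole-free, contained in the `radius`-dilation of the input.
#' @export
refine_mask <- function(mask, radius = 1, element = c("disk", "square"),
                        connectivity = 8) {
  mask <- assert_mask(mask)
  element <- match.arg(element)
  if (!any(mask)) stop("cannot refine an empty mask", call. = FALSE)
  if (radius > 0) {
    eroded <- binary_erode(mask, radius, element)
    if (!any(eroded))
      stop(sprintf("erosion with radius %d annihilated the mask; retry with a smaller radius or 0",
                   radius), call. = FALSE)
    core <- largest_connected_component(eroded, connectivity)
    mask <- binary_dilate(core, radius, element)
  }
  fill_holes(mask)
}
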