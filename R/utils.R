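# Internal validators and small matrix helpers shared across the package.

# A slice is an integer-valued matrix with entries in [0, 255].
assert_slice <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x > 255) || any(x != round(x)))
    stop(sprintf("`%s` must contain integers in [0, 255]", name), call. = FALSE)
  invisible(x)
}

assert_pair <- function(t1, t2) {
  assert_slice(t1, "t1")
  assert_slice(t2, "t2")
  if (!identical(dim(t1), dim(t2)))
    stop(sprintf("T1 and T2 slices must have identical dimensions (got %dx%d vs %dx%d); co-register the pair first",
                 nrow(t1), ncol(t1), nrow(t2), ncol(t2)), call. = FALSE)
  invisible(NULL)
}

assert_mask <- function(x, name = deparse(substitute(x))) {
  if (is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))) {
    x <- matrix(as.logical(x), nrow(x), ncol(x))
  }
  if (!is.matrix(x) || !is.logical(x) || anyNA(x))
    stop(sprintf("`%s` must be a logical (binary) matrix", name), call. = FALSE)
  x
}

assert_connectivity <- function(connectivity) {
  if (!(length(connectivity) == 1L && connectivity %in% c(4, 8)))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  as.integer(connectivity)
}

# out[r, c] = m[r - dr, c - dc], vacated cells filled with `fill`
shift_mask <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(r_dst) < 1L || length(c_dst) < 1L) return(out)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

# Offsets (dr, dc) of a structuring element; disk of radius 1 is the 3x3 cross.
element_offsets <- function(radius, element = c("disk", "square")) {
  element <- match.arg(element)
  if (radius < 0 || radius != round(radius))
    stop("`radius` must be a non-negative integer", call. = FALSE)
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  if (element == "disk") d <- d[d$dr^2 + d$dc^2 <= radius^2, , drop = FALSE]
  d
}

# Tight bounding box of a mask: list(h, w, rmin, rmax, cmin, cmax)
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  list(rmin = min(idx[, 1L]), rmax = max(idx[, 1L]),
       cmin = min(idx[, 2L]), cmax = max(idx[, 2L]),
       h = max(idx[, 1L]) - min(idx[, 1L]) + 1L,
       w = max(idx[, 2L]) - min(idx[, 2L]) + 1L)
}
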