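#' Joint T1/T2 intensity histogram
#'
#' Counts, for every ordered pair of 8-bit intensities (a, b), the number of
#' pixels whose T1 value is a and whose T2 value is b, over a co-registered
#' slice pair. The result is the 256x256 joint histogram that the fuzzy
#' c-means stage partitions.
#'
#' @param t1,t2 integer matrices of identical dimensions, values in 0..255.
#' @return an object of class `intensity_hist2d`: a list with `counts`
#'   (256x256 integer matrix; `counts[a + 1, b + 1]` is the number of pixels
#'   with T1 = a, T2 = b) and `n` (total pixel count).
#' @examples
#' h <- build_intensity_histogram(matrix(10L, 4, 4), matrix(20L, 4, 4))
#' h$counts[11, 21]  # 16
#' @export
build_intensity_histogram <- function(t1, t2) {
  assert_pair(t1, t2)
  idx <- as.integer(t1) * 256L + as.integer(t2) + 1L
  counts <- matrix(tabulate(idx, nbins = 256L * 256L), 256L, 256L, byrow = TRUE)
  structure(list(counts = counts, n = length(t1)), class = "intensity_hist2d")
}

#' @export
print.intensity_hist2d <- function(x, ...) {
  cat(sprintf("Joint T1/T2 intensity histogram: %d pixels in %d occupied of %d bins\n",
              x$n, sum(x$counts > 0), length(x$counts)))
  invisible(x)
}
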