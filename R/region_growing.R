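#' Connected components of a binary mask
#'
#' Labels the connected components of a mask under 4- or 8-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of component labels (0 = background), with the
#'   number of components in `attr(, "n_components")`.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- assert_mask(mask)
  label_components_cpp(mask, assert_connectivity(connectivity))
}

#' Largest connected component
#'
#' Returns the single connected component of a mask with the most pixels;
#' this is the seed the region-growing stage starts from. Ties are broken
#' by the first label in column-major scan order.
#'
#' @inheritParams label_components
#' @return logical matrix containing exactly one connected component.
#' @export
largest_connected_component <- function(mask, connectivity = 8) {
  mask <- assert_mask(mask)
  if (!any(mask))
    stop("mask is empty: cluster has no pixels to seed from", call. = FALSE)
  lab <- label_components_cpp(mask, assert_connectivity(connectivity))
  sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n_components"))
  lab == which.max(sizes)
}

#' Grow a region from a seed under the mean +/- k SD merge rule
#'
#' Computes the T1 and T2 mean and standard deviation of the seed region
#' once, then iteratively merges every pixel adjacent to the region whose T1
#' AND T2 intensities both lie within `k_sd` standard deviations of the
#' respective seed mean, until no qualifying neighbor remains. Seed
#' statistics are frozen: they are never recomputed from the growing region,
#' so the acceptance predicate is static and the fixpoint is the union of
#' the connected components of (seed OR eligible pixels) that touch the
#' seed, which is how the fixpoint is computed.
#'
#' @param seed_mask logical matrix, the (connected) seed region.
#' @param t1,t2 the slice pair.
#' @param connectivity 4 or 8 (default 8).
#' @param k_sd half-width of the acceptance interval in seed SDs (default 2).
#' @param within optional logical matrix restricting growth candidates (for
#'   example the cluster's own defuzzified mask); by default any image pixel
#'   may be merged.
#' @param update_stats number of additional rounds in which the mean and SD
#'   are recomputed from the current grown region and growth is repeated
#'   (as in confidence-connected region growing). The default 0 keeps the
#'   seed statistics frozen throughout. A seed that is a truncated sample
#'   of its tissue's intensity distribution underestimates the tissue SD;
#'   a bounded number of recompute rounds lets the acceptance interval
#'   relax toward the tissue's true spread while termination stays
#'   guaranteed.
#' @param cluster_id optional integer carried through to the result.
#' @return an object of class `candidate_region`: `cluster_id`, `seed_mask`,
#'   `grown_mask`, `t1_mean`, `t2_mean`, `t1_sd`, `t2_sd` (sample SDs; a
#'   single-pixel seed has SD 0) and `area`.
#' @export
grow_region <- function(seed_mask, t1, t2, connectivity = 8, k_sd = 2,
                        within = NULL, update_stats = 0,
                        cluster_id = NA_integer_) {
  seed_mask <- assert_mask(seed_mask)
  assert_pair(t1, t2)
  if (!identical(dim(seed_mask), dim(t1)))
    stop("`seed_mask` and slices must share dimensions", call. = FALSE)
  if (!any(seed_mask)) stop("seed region is empty", call. = FALSE)
  connectivity <- assert_connectivity(connectivity)
  if (!is.null(within)) within <- assert_mask(within)

  region <- seed_mask
  for (round in seq_len(1L + update_stats)) {
    v1 <- t1[region]; v2 <- t2[region]
    mu1 <- mean(v1); mu2 <- mean(v2)
    s1 <- if (length(v1) > 1L) sd(v1) else 0
    s2 <- if (length(v2) > 1L) sd(v2) else 0

    eligible <- t1 >= mu1 - k_sd * s1 & t1 <= mu1 + k_sd * s1 &
                t2 >= mu2 - k_sd * s2 & t2 <= mu2 + k_sd * s2
    if (!is.null(within)) eligible <- eligible & within

    lab <- label_components_cpp(seed_mask | eligible, connectivity)
    grown <- matrix(lab %in% unique(lab[seed_mask]), nrow(t1), ncol(t1))
    if (identical(grown, region) && round > 1L) break
    region <- grown
  }

  structure(list(cluster_id = as.integer(cluster_id),
                 seed_mask = seed_mask, grown_mask = grown,
                 t1_mean = mu1, t2_mean = mu2, t1_sd = s1, t2_sd = s2,
                 area = sum(grown)),
            class = "candidate_region")
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf("Candidate region %s: seed %d px -> grown %d px; seed T1 %.1f +/- %.1f, T2 %.1f +/- %.1f\n",
              ifelse(is.na(x$cluster_id), "?", x$cluster_id),
              sum(x$seed_mask), x$area, x$t1_mean, x$t1_sd, x$t2_mean, x$t2_sd))
  invisible(x)
}
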