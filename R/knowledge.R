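# Knowledge-based candidate selection: four rules applied in order to the
# grown candidate regions -- (a) bounding box, (b) laterality, (c) solidity,
# (d) area -- followed by a logical-OR merge. Each filter returns the
# survivors plus audit-trace rows; menseg() assembles the full KBTrace.

trace_rows <- function(candidates, stage, kept, detail = NA_character_) {
  if (length(candidates) == 0L)
    return(data.frame(cluster_id = integer(0), stage = character(0),
                      decision = character(0), detail = character(0)))
  data.frame(cluster_id = vapply(candidates, `[[`, integer(1), "cluster_id"),
             stage = stage,
             decision = ifelse(kept, "kept", "eliminated"),
             detail = detail,
             stringsAsFactors = FALSE)
}

#' Bounding-box size rule
#'
#' A tumor seldom exceeds half the extent of the brain, so any candidate
#' whose tight bounding box is larger than half the height and half the
#' width of the brain's bounding box is eliminated. The conjunctive reading
#' (taller than half AND wider than half) is the default; `rule = "or"`
#' eliminates when either dimension exceeds half, for sensitivity analysis.
#'
#' @param candidates list of `candidate_region` objects.
#' @param brain_mask logical matrix delimiting the brain/head (for phantoms,
#'   pixels with nonzero intensity).
#' @param rule `"and"` (default) or `"or"`.
#' @return list with `kept` (surviving candidates) and `trace` (one row per
#'   input candidate).
#' @export
bounding_box_filter <- function(candidates, brain_mask, rule = c("and", "or")) {
  rule <- match.arg(rule)
  brain_mask <- assert_mask(brain_mask)
  if (!any(brain_mask)) stop("brain mask is empty", call. = FALSE)
  if (length(candidates) == 0L)
    return(list(kept = list(), trace = trace_rows(list(), "bounding_box", logical(0))))
  bb <- mask_bbox(brain_mask)
  keep <- logical(length(candidates))
  detail <- character(length(candidates))
  for (i in seq_along(candidates)) {
    cb <- mask_bbox(candidates[[i]]$grown_mask)
    too_tall <- cb$h > bb$h / 2
    too_wide <- cb$w > bb$w / 2
    keep[i] <- if (rule == "and") !(too_tall && too_wide) else !(too_tall || too_wide)
    detail[i] <- sprintf("box %dx%d vs brain %dx%d", cb$h, cb$w, bb$h, bb$w)
  }
  list(kept = candidates[keep],
       trace = trace_rows(candidates, "bounding_box", keep, detail))
}

#' Bilateral-histogram laterality analysis
#'
#' Decides whether the tumor sits in the left hemisphere, the right
#' hemisphere or at the midline, from the T2 slice alone. Intensity
#' histograms of the left and right image halves are built over bins at or
#' above `noise_floor` (tumors are bright on T2, so dim pixels are noise
#' here) and compared by Pearson correlation. A correlation above
#' `threshold` means the halves are symmetric and the tumor, if any, sits at
#' the midline; otherwise the intensity bin where the absolute histogram
#' difference is largest serves as the reference point, and the side with
#' the higher count at that bin is the tumor side.
#'
#' With an odd image width the central pixel column belongs to neither half.
#' If the two half histograms are identical the correlation is reported as
#' exactly 1; if either histogram is constant (zero variance) but they
#' differ, the correlation is reported as 0.
#'
#' @param t2 integer matrix, the T2-weighted slice.
#' @param noise_floor minimum intensity included in the histograms.
#' @param threshold correlation above which the verdict is `"midline"`.
#' @return an object of class `laterality_result`: `verdict` (`"left"`,
#'   `"right"` or `"midline"`), `correlation`, `reference_bin` (intensity of
#'   the maximal histogram difference) and the two histograms.
#' @export
laterality_analysis <- function(t2, noise_floor = 50, threshold = 0.95) {
  assert_slice(t2, "t2")
  w <- ncol(t2)
  half <- w %/% 2L
  lh <- t2[, seq_len(half), drop = FALSE]
  rh <- t2[, (w - half + 1L):w, drop = FALSE]
  bins <- noise_floor:255
  count_hist <- function(v) {
    v <- v[v >= noise_floor]
    tabulate(v - noise_floor + 1L, nbins = length(bins))
  }
  hl <- count_hist(lh); hr <- count_hist(rh)
  if (sum(hl) + sum(hr) == 0L)
    stop(sprintf("no pixel reaches the noise floor (%d): empty laterality histograms",
                 noise_floor), call. = FALSE)
  correlation <- if (identical(hl, hr)) 1
    else if (sd(hl) == 0 || sd(hr) == 0) 0
    else cor(hl, hr)
  ref <- which.max(abs(hl - hr))
  verdict <- if (correlation > threshold) "midline"
    else if (hl[ref] > hr[ref]) "left" else "right"
  structure(list(verdict = verdict, correlation = correlation,
                 reference_bin = bins[ref], left_hist = hl, right_hist = hr,
                 noise_floor = noise_floor, threshold = threshold),
            class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("Laterality: %s (correlation %.4f vs threshold %.2f; reference bin %d)\n",
              x$verdict, x$correlation, x$threshold, x$reference_bin))
  invisible(x)
}

#' Hemisphere side rule
#'
#' With a lateral verdict, eliminates every candidate whose pixel majority
#' (fraction > 0.5) lies strictly on the non-tumor side of the midline; with
#' a midline verdict all candidates survive. The midline is the central
#' pixel column: for even width the left half is the first w/2 columns; for
#' odd width the central column counts toward neither side.
#'
#' @param candidates list of `candidate_region` objects.
#' @param laterality a `laterality_result`.
#' @param width image width in pixels (defines the midline).
#' @return list with `kept` and `trace`, as [bounding_box_filter()].
#' @export
side_filter <- function(candidates, laterality, width) {
  if (!inherits(laterality, "laterality_result"))
    stop("`laterality` must come from laterality_analysis()", call. = FALSE)
  half <- width %/% 2L
  if (laterality$verdict == "midline" || length(candidates) == 0L)
    return(list(kept = candidates,
                trace = trace_rows(candidates, "side",
                                   rep(TRUE, length(candidates)),
                                   "midline verdict: all kept")))
  keep <- logical(length(candidates))
  detail <- character(length(candidates))
  for (i in seq_along(candidates)) {
    cols <- which(candidates[[i]]$grown_mask, arr.ind = TRUE)[, 2L]
    off_frac <- if (laterality$verdict == "left")
      mean(cols >= width - half + 1L) else mean(cols <= half)
    keep[i] <- off_frac <= 0.5
    detail[i] <- sprintf("%.2f of pixels on non-tumor side", off_frac)
  }
  list(kept = candidates[keep], trace = trace_rows(candidates, "side", keep, detail))
}

#' Solidity of a binary region
#'
#' Solidity = region area / area of the smallest convex polygon covering the
#' region, both measured in pixels: the hull area is the count of pixel
#' centers inside (or on) the convex hull of the region's pixel centers.
#' Compact blobs score near 1; ragged or branched regions score low. A
#' region whose pixels are collinear is its own hull and scores 1.
#'
#' @param mask logical matrix, non-empty.
#' @return solidity in (0, 1].
#' @export
solidity <- function(mask) {
  mask <- assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("solidity of an empty region is undefined", call. = FALSE)
  if (n <= 2L) return(1)
  x <- as.numeric(idx[, 2L]); y <- as.numeric(idx[, 1L])
  h <- chull(x, y)
  if (length(h) <= 2L) return(1)  # collinear pixel set
  hx <- x[h]; hy <- y[h]
  k <- length(h)
  # orientation via the shoelace signed area
  nxt <- c(seq_len(k)[-1L], 1L)
  s <- sign(sum(hx * hy[nxt] - hx[nxt] * hy))
  gx <- rep(min(x):max(x), each = length(min(y):max(y)))
  gy <- rep(min(y):max(y), times = length(min(x):max(x)))
  inside <- rep(TRUE, length(gx))
  for (e in seq_len(k)) {
    cr <- (hx[nxt[e]] - hx[e]) * (gy - hy[e]) - (hy[nxt[e]] - hy[e]) * (gx - hx[e])
    inside <- inside & (s * cr >= -1e-9)
  }
  n / sum(inside)
}

#' Split values into a high and a low group by agglomerative clustering
#'
#' Agglomerative hierarchical clustering (complete linkage on absolute
#' differences, via [stats::hclust()]) merges the values bottom-up until two
#' clusters remain; the indices of the cluster with the higher (or lower)
#' mean are returned. A relative criterion like this needs no training data
#' and no absolute threshold. Complete linkage is used because it minimizes
#' the within-cluster range and therefore yields balanced high/low groups,
#' whereas average linkage tends to isolate a single extreme value and
#' discard everything else. A single value is trivially kept; if all values
#' are identical no meaningful split exists and every index is returned
#' (fail-open). A tie between cluster means is resolved in favor of the
#' cluster containing the lowest index.
#'
#' @param values numeric vector (length >= 1).
#' @param keep `"higher"` or `"lower"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return integer indices of the kept values.
#' @export
hierarchical_split <- function(values, keep = c("higher", "lower"),
                               linkage = "complete") {
  keep <- match.arg(keep)
  if (length(values) == 0L) stop("no values to split", call. = FALSE)
  if (length(values) == 1L) return(1L)
  if (diff(range(values)) == 0) return(seq_along(values))
  grp <- cutree(hclust(dist(values), method = linkage), k = 2)
  m1 <- mean(values[grp == 1]); m2 <- mean(values[grp == 2])
  target <- if (m1 == m2) grp[1L]
    else if (keep == "higher") which.max(c(m1, m2)) else which.min(c(m1, m2))
  which(grp == target)
}

split_filter <- function(candidates, feature, stage, keep = "higher") {
  if (length(candidates) == 0L)
    return(list(kept = list(), trace = trace_rows(list(), stage, logical(0))))
  vals <- vapply(candidates, feature, numeric(1))
  kept_idx <- hierarchical_split(vals, keep = keep)
  keepv <- seq_along(candidates) %in% kept_idx
  list(kept = candidates[keepv],
       trace = trace_rows(candidates, stage, keepv, sprintf("%s = %.4g", stage, vals)))
}

#' Solidity rule
#'
#' Splits the candidates into high- and low-solidity groups by
#' [hierarchical_split()] and keeps the high group: tumors are compact,
#' normal-tissue remnants ragged.
#'
#' @param candidates list of `candidate_region` objects.
#' @return list with `kept` and `trace`.
#' @export
solidity_filter <- function(candidates) {
  split_filter(candidates, function(cand) solidity(cand$grown_mask), "solidity")
}

#' Area rule
#'
#' Splits the candidates into large- and small-area groups by
#' [hierarchical_split()] and keeps the large group, eliminating small noise
#' remnants.
#'
#' @param candidates list of `candidate_region` objects.
#' @return list with `kept` and `trace`.
#' @export
area_filter <- function(candidates) {
  split_filter(candidates, function(cand) as.numeric(cand$area), "area")
}

#' Merge selected candidates into the preliminary tumor mask
#'
#' Pixelwise logical OR of the grown masks of the surviving candidates. In
#' semi-supervised use, `manual_ids` names the cluster ids a human selected,
#' replacing the automatic solidity/area selection.
#'
#' @param candidates list of `candidate_region` objects (the survivors, or
#'   the pool the manual ids refer to).
#' @param manual_ids optional integer cluster ids to merge instead.
#' @return logical matrix, the preliminary tumor mask.
#' @export
merge_selected <- function(candidates, manual_ids = NULL) {
  if (!is.null(manual_ids)) {
    ids <- vapply(candidates, `[[`, integer(1), "cluster_id")
    missing <- setdiff(manual_ids, ids)
    if (length(missing) > 0L)
      stop(sprintf("manual selection refers to unknown candidate id(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    candidates <- candidates[ids %in% manual_ids]
  }
  if (length(candidates) == 0L)
    stop("no candidate to merge: pipeline found no tumor", call. = FALSE)
  out <- candidates[[1L]]$grown_mask
  for (cand in candidates[-1L]) out <- out | cand$grown_mask
  out
}
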