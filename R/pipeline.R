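#' Pipeline settings
#'
#' Collects every tunable of the segmentation pipeline with its default.
#'
#' @param clusters number of FCM clusters (over-segmentation; default 32).
#' @param fuzzifier FCM fuzzifier exponent m (> 1).
#' @param eps FCM convergence tolerance on the absolute objective change.
#' @param max_iter FCM iteration cap.
#' @param seed integer seed for the FCM initialization; fixing it makes the
#'   whole pipeline deterministic.
#' @param connectivity 4 or 8, for component labeling and region growing.
#' @param k_sd region-growing acceptance half-width in seed SDs (default 2).
#' @param update_stats rounds of region-statistics recomputation during
#'   growth (see [grow_region()]); the pipeline default 2 lets fragmented
#'   seeds consolidate into their full tissue region.
#' @param region_growing set `FALSE` to pass the raw defuzzified cluster
#'   masks to the knowledge-based stage (ablation).
#' @param grow_within_cluster restrict growth candidates to the cluster's
#'   own defuzzified mask instead of the whole image.
#' @param noise_floor minimum T2 intensity entering the laterality
#'   histograms.
#' @param laterality_threshold correlation above which the verdict is
#'   midline.
#' @param bbox_rule `"and"` (default) or `"or"`, see
#'   [bounding_box_filter()].
#' @param brain_threshold intensity above which a pixel (on either channel)
#'   counts as head/brain for the bounding-box rule; 0 suits images whose
#'   background is exactly zero.
#' @param morph_radius structuring-element radius of the morphological
#'   refinement; 0 disables opening (holes are still filled).
#' @param morph_element `"disk"` or `"square"`.
#' @return an object of class `menseg_config`.
#' @export
menseg_config <- function(clusters = 32, fuzzifier = 2, eps = 1e-5,
                          max_iter = 300, seed = NULL, connectivity = 8,
                          k_sd = 2, update_stats = 2, region_growing = TRUE,
                          grow_within_cluster = FALSE, noise_floor = 50,
                          laterality_threshold = 0.95,
                          bbox_rule = "and", brain_threshold = 0,
                          morph_radius = 1, morph_element = "disk") {
  cfg <- as.list(environment())
  structure(cfg, class = "menseg_config")
}

#' @export
print.menseg_config <- function(x, ...) {
  cat("menseg pipeline settings:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k,
                                  if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  invisible(x)
}

#' Segment a meningioma from a co-registered T1/T2 slice pair
#'
#' Runs the full pipeline: joint T1/T2 intensity histogram, fuzzy c-means
#' partition into `clusters` groups, defuzzification, seeded region growing
#' of every non-empty group (largest connected component seed, mean +/- k SD
#' merge rule), knowledge-based candidate selection (bounding box,
#' laterality, solidity, area), logical-OR merge and morphological
#' refinement. If a ground-truth mask is supplied the result carries
#' PM/CR evaluation metrics.
#'
#' Inputs may be integer matrices (0..255) or file paths readable by
#' [read_slice()]. The run is deterministic for a fixed `config$seed`.
#'
#' @param t1,t2 co-registered 8-bit slices (matrices or file paths).
#' @param gt optional ground-truth tumor mask (logical matrix or PNG path).
#' @param config a [menseg_config()].
#' @param manual_select optional integer cluster ids: the semi-supervised
#'   pathway, replacing the automatic solidity/area selection with a human
#'   choice among the candidates surviving the bounding-box and side rules.
#' @return an object of class `menseg`: `status` (`"tumor_found"` or
#'   `"no_tumor_found"`), `mask` (final tumor mask), `preliminary_mask`,
#'   `candidates`, `kb_trace` (one row per candidate per rule),
#'   `features` (per-candidate feature table), `laterality`, `partition`,
#'   `metrics` (if `gt` given), `config`.
#' @examples
#' ph <- generate_phantom(phantom_spec(tumor_position = "left", seed = 11))
#' fit <- menseg(ph$t1, ph$t2, gt = ph$tumor_mask,
#'               config = menseg_config(seed = 11))
#' print(fit)
#' @export
menseg <- function(t1, t2, gt = NULL, config = menseg_config(),
                   manual_select = NULL) {
  if (is.character(t1)) t1 <- read_slice(t1)
  if (is.character(t2)) t2 <- read_slice(t2)
  if (is.character(gt)) gt <- read_mask(gt)
  assert_pair(t1, t2)
  if (!inherits(config, "menseg_config"))
    stop("`config` must come from menseg_config()", call. = FALSE)

  hist <- build_intensity_histogram(t1, t2)
  part <- fcm_cluster(hist, c = config$clusters, m = config$fuzzifier,
                      eps = config$eps, max_iter = config$max_iter,
                      seed = config$seed)
  masks <- defuzzify(part, hist, t1, t2)

  # one candidate per non-empty cluster
  candidates <- list()
  empty_trace <- data.frame(cluster_id = integer(0), stage = character(0),
                            decision = character(0), detail = character(0))
  trace <- empty_trace
  for (i in seq_len(masks$c)) {
    cm <- cluster_mask(masks, i)
    if (!any(cm)) {
      trace <- rbind(trace, data.frame(cluster_id = i, stage = "defuzzify",
                                       decision = "eliminated",
                                       detail = "empty cluster"))
      next
    }
    seed <- largest_connected_component(cm, config$connectivity)
    cand <- if (config$region_growing) {
      grow_region(seed, t1, t2, connectivity = config$connectivity,
                  k_sd = config$k_sd, update_stats = config$update_stats,
                  within = if (config$grow_within_cluster) cm else NULL,
                  cluster_id = i)
    } else {
      # ablation: the raw defuzzified mask goes forward unchanged
      structure(list(cluster_id = i, seed_mask = seed, grown_mask = cm,
                     t1_mean = mean(t1[seed]), t2_mean = mean(t2[seed]),
                     t1_sd = if (sum(seed) > 1) sd(t1[seed]) else 0,
                     t2_sd = if (sum(seed) > 1) sd(t2[seed]) else 0,
                     area = sum(cm)),
                class = "candidate_region")
    }
    candidates <- c(candidates, list(cand))
  }

  brain_mask <- t1 > config$brain_threshold | t2 > config$brain_threshold
  lat <- laterality_analysis(t2, noise_floor = config$noise_floor,
                             threshold = config$laterality_threshold)

  st_a <- bounding_box_filter(candidates, brain_mask, rule = config$bbox_rule)
  st_b <- side_filter(st_a$kept, lat, width = ncol(t1))
  if (is.null(manual_select)) {
    st_c <- solidity_filter(st_b$kept)
    st_d <- area_filter(st_c$kept)
    selected <- st_d$kept
    trace <- rbind(trace, st_a$trace, st_b$trace, st_c$trace, st_d$trace)
  } else {
    ids <- vapply(st_b$kept, `[[`, integer(1), "cluster_id")
    merge_selected(st_b$kept, manual_select)  # validates the ids
    keep <- ids %in% manual_select
    selected <- st_b$kept[keep]
    trace <- rbind(trace, st_a$trace, st_b$trace,
                   trace_rows(st_b$kept, "manual_select", keep))
  }

  h <- nrow(t1); w <- ncol(t1)
  if (length(selected) == 0L) {
    status <- "no_tumor_found"
    prelim <- final <- matrix(FALSE, h, w)
  } else {
    status <- "tumor_found"
    prelim <- merge_selected(selected)
    final <- tryCatch(
      refine_mask(prelim, radius = config$morph_radius,
                  element = config$morph_element,
                  connectivity = config$connectivity),
      error = function(e) refine_mask(prelim, radius = 0))
  }

  features <- data.frame(
    cluster_id = vapply(candidates, `[[`, integer(1), "cluster_id"),
    seed_area = vapply(candidates, function(x) sum(x$seed_mask), numeric(1)),
    area = vapply(candidates, `[[`, numeric(1), "area"),
    t1_mean = vapply(candidates, `[[`, numeric(1), "t1_mean"),
    t2_mean = vapply(candidates, `[[`, numeric(1), "t2_mean"))

  metrics <- NULL
  if (!is.null(gt)) {
    cc <- confusion(final, assert_mask(gt))
    metrics <- c(pm_cr(cc)[c("pm", "cr")], unclass(cc))
  }

  structure(list(status = status, mask = final, preliminary_mask = prelim,
                 candidates = candidates, kb_trace = trace,
                 features = features, laterality = lat, partition = part,
                 metrics = metrics, config = config, t1 = t1, t2 = t2),
            class = "menseg")
}

#' Terminal knowledge-based status of every candidate
#'
#' @param x a `menseg` result.
#' @return data.frame with one row per candidate cluster: its last recorded
#'   stage and decision.
#' @export
kb_status <- function(x) {
  stopifnot(inherits(x, "menseg"))
  tr <- x$kb_trace
  out <- do.call(rbind, lapply(split(tr, tr$cluster_id), function(d) d[nrow(d), ]))
  rownames(out) <- NULL
  out[order(out$cluster_id), ]
}

#' @export
print.menseg <- function(x, ...) {
  cat(sprintf("menseg segmentation: %s\n", x$status))
  cat(sprintf("  %d candidate groups from %d clusters; laterality %s (r = %.3f)\n",
              length(x$candidates), x$config$clusters,
              x$laterality$verdict, x$laterality$correlation))
  cat(sprintf("  final mask: %d px\n", sum(x$mask)))
  if (!is.null(x$metrics))
    cat(sprintf("  vs ground truth: PM = %.2f%%, CR = %.2f\n",
                x$metrics$pm, x$metrics$cr))
  invisible(x)
}

#' @export
summary.menseg <- function(object, ...) {
  print(object)
  tr <- object$kb_trace
  cat("\nKnowledge-based cascade:\n")
  for (stage in unique(tr$stage)) {
    d <- tr[tr$stage == stage, ]
    cat(sprintf("  %-14s %2d in -> %2d kept\n", stage, nrow(d),
                sum(d$decision == "kept")))
  }
  st <- kb_status(object)
  surv <- st$cluster_id[st$decision == "kept"]
  cat(sprintf("  selected cluster id(s): %s\n",
              if (length(surv)) paste(surv, collapse = ", ") else "none"))
  invisible(object)
}

#' Plot a segmentation result
#'
#' Shows the T1 slice, the T2 slice, and the T2 slice with the final mask
#' boundary overlaid.
#'
#' @param x a `menseg` result.
#' @param ... ignored.
#' @export
plot.menseg <- function(x, ...) {
  show <- function(img, main) {
    image(t(img[nrow(img):1, , drop = FALSE]), col = gray(0:255 / 255),
          axes = FALSE, main = main, useRaster = TRUE)
  }
  op <- par(mfrow = c(1, 3), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(par(op))
  show(x$t1, "T1")
  show(x$t2, "T2")
  boundary <- x$mask & !binary_erode(x$mask, 1)
  overlay <- x$t2
  overlay[boundary] <- 255
  show(overlay, sprintf("T2 + mask (%s)", x$status))
  invisible(x)
}
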