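#' Pixel-level confusion counts between a system and a ground-truth mask
#'
#' @param sys_mask logical matrix: the system's tumor mask.
#' @param gt_mask logical matrix: the expert ground-truth tumor mask.
#' @return an object of class `confusion_counts` with `tp`, `fp`, `fn`,
#'   `tn` and `gt` (= tp + fn, the ground-truth tumor area).
#' @export
confusion <- function(sys_mask, gt_mask) {
  sys_mask <- assert_mask(sys_mask)
  gt_mask <- assert_mask(gt_mask)
  if (!identical(dim(sys_mask), dim(gt_mask)))
    stop(sprintf("mask dimensions differ: %dx%d vs %dx%d",
                 nrow(sys_mask), ncol(sys_mask), nrow(gt_mask), ncol(gt_mask)),
         call. = FALSE)
  tp <- sum(sys_mask & gt_mask)
  fp <- sum(sys_mask & !gt_mask)
  fn <- sum(!sys_mask & gt_mask)
  tn <- sum(!sys_mask & !gt_mask)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, gt = tp + fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: GT %d | TP %d FP %d FN %d TN %d\n",
              x$gt, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Percent match and correspondence ratio
#'
#' PM = 100 * TP / GT measures how much of the ground-truth tumor the system
#' recovered; CR = (TP - 0.5 * FP) / GT additionally penalizes false
#' positives and goes negative when they dominate. Values are computed at
#' full precision; round only when reporting.
#'
#' @param counts a `confusion_counts` object, or a list/data.frame row with
#'   fields `tp`, `fp` and `gt`.
#' @return an object of class `seg_metrics` with `pm` (percent) and `cr`.
#' @examples
#' m <- pm_cr(list(tp = 4118, fp = 195, gt = 4271))
#' round(m$pm, 2); round(m$cr, 2)  # 96.42, 0.94
#' @export
pm_cr <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; gt <- counts$gt
  if (is.null(gt) && !is.null(counts$fn)) gt <- tp + counts$fn
  if (gt <= 0)
    stop("PM and CR are undefined for an empty ground truth (GT = 0)", call. = FALSE)
  structure(list(pm = 100 * tp / gt, cr = (tp - 0.5 * fp) / gt),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("PM = %.2f%%, CR = %.2f\n", x$pm, x$cr))
  invisible(x)
}

#' Summarize per-case segmentation metrics
#'
#' Arithmetic mean and sample (n - 1) standard deviation of PM and CR over a
#' set of cases, optionally excluding some case ids. With a single included
#' case the SD is reported as 0 and flagged.
#'
#' @param metrics a list of `seg_metrics`, or a data.frame with columns `pm`
#'   and `cr` (and optionally `case`).
#' @param exclude_ids case ids (matching the `case` column, or positions) to
#'   exclude.
#' @return a list with `pm_mean`, `pm_sd`, `cr_mean`, `cr_sd`, `n` and
#'   `sd_defined`.
#' @export
summarize_cases <- function(metrics, exclude_ids = NULL) {
  if (is.data.frame(metrics)) {
    df <- metrics
    if (is.null(df$case)) df$case <- seq_len(nrow(df))
  } else {
    df <- data.frame(case = seq_along(metrics),
                     pm = vapply(metrics, `[[`, numeric(1), "pm"),
                     cr = vapply(metrics, `[[`, numeric(1), "cr"))
  }
  df <- df[!(df$case %in% exclude_ids), , drop = FALSE]
  if (nrow(df) == 0L) stop("no cases left after exclusion", call. = FALSE)
  one <- nrow(df) == 1L
  list(pm_mean = mean(df$pm), pm_sd = if (one) 0 else sd(df$pm),
       cr_mean = mean(df$cr), cr_sd = if (one) 0 else sd(df$cr),
       n = nrow(df), sd_defined = !one)
}

#' Paired t-test between two per-case metric series
#'
#' Two-sided paired t-test (via [stats::t.test()]) comparing, for example,
#' automatic against semi-supervised PM values case by case. Constant
#' differences have zero variance and no defined t statistic, so they raise
#' an error rather than returning a misleading p-value.
#'
#' @param values_a,values_b numeric vectors of equal length (>= 2).
#' @return a list with `t`, `df` and `p_value`.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired series must have equal length", call. = FALSE)
  if (length(values_a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  if (sd(d) == 0)
    stop("differences have zero variance: paired t statistic undefined", call. = FALSE)
  ht <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Recompute PM/CR for a table of printed confusion counts
#'
#' Takes a per-case table of pixel counts (columns `case`, `gt`, `tp`, `fp`,
#' and optionally `fn`, `tn`, `sys`) and recomputes PM and CR for every row
#' at full precision.
#'
#' @param counts a data.frame, or the path of a CSV file holding one.
#' @return the input data.frame with numeric `pm` and `cr` columns appended.
#' @export
recompute_metrics_table <- function(counts) {
  if (is.character(counts)) counts <- read.csv(counts)
  need <- c("case", "gt", "tp", "fp")
  if (!all(need %in% names(counts)))
    stop("counts table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  met <- lapply(seq_len(nrow(counts)), function(i) pm_cr(counts[i, ]))
  counts$pm <- vapply(met, `[[`, numeric(1), "pm")
  counts$cr <- vapply(met, `[[`, numeric(1), "cr")
  counts
}

#' Published per-case confusion counts
#'
#' Path of the CSV bundled with the package holding the 29-case per-case
#' pixel counts (GT, SYS, TP, FP, FN, TN) of the original meningioma study,
#' together with the PM/CR values as printed there (2 decimals), for use
#' with [recompute_metrics_table()] and [summarize_cases()].
#'
#' @return a file path.
#' @export
study_counts_path <- function() {
  system.file("extdata", "table1_counts.csv", package = "menseg", mustWork = TRUE)
}
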