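#' Fuzzy c-means partition of the joint intensity histogram
#'
#' Runs fuzzy c-means over the occupied bins of a joint T1/T2 intensity
#' histogram, with each bin weighted by its pixel count. This is
#' mathematically equivalent to running FCM over the full per-pixel data
#' list (pixels sharing a bin share memberships at every iteration) at a
#' fraction of the cost. Memberships are initialized uniformly at random and
#' row-normalized; each iteration updates the membership-weighted cluster
#' centers, then the memberships, then evaluates the objective
#' \deqn{J = \sum_k w_k \sum_i u_{ik}^m \|x_k - v_i\|^2,} stopping when the
#' absolute change in J falls to `eps` or at `max_iter`.
#'
#' @param hist an `intensity_hist2d` from [build_intensity_histogram()].
#' @param c number of clusters (default 32: over-segmentation so the tumor
#'   separates into its own group or groups).
#' @param m fuzzifier exponent (> 1) regulating membership softness.
#' @param eps convergence tolerance on the absolute objective change.
#' @param max_iter iteration cap.
#' @param seed optional integer seed for the random initialization.
#' @param nstart number of random restarts (default 1). With more than one
#'   start, each restart runs `explore_iter` iterations and the
#'   lowest-objective one is continued to convergence.
#' @param explore_iter exploration iterations per restart before the best
#'   restart is selected.
#' @param u_init optional initial membership matrix (occupied bins x c, rows
#'   summing to 1), overriding the random initialization; implies a single
#'   start.
#' @return an object of class `fcm_partition`: `c`, `m`, `eps`,
#'   `memberships` (occupied bins x c), `centers` (c x 2 in (T1, T2)
#'   intensity units), `bins` (occupied-bin coordinates and counts),
#'   `objective_trace`, `iter`.
#' @export
fcm_cluster <- function(hist, c = 32, m = 2, eps = 1e-5, max_iter = 300,
                        seed = NULL, nstart = 1, explore_iter = 60,
                        u_init = NULL) {
  if (!inherits(hist, "intensity_hist2d"))
    stop("`hist` must come from build_intensity_histogram()", call. = FALSE)
  if (c < 1 || c != round(c)) stop("`c` must be a positive integer", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must exceed 1", call. = FALSE)

  occ <- which(hist$counts > 0, arr.ind = TRUE)
  B <- nrow(occ)
  if (B < c)
    stop(sprintf("histogram has %d occupied bins, fewer than c = %d clusters", B, c),
         call. = FALSE)
  X <- cbind(t1 = occ[, 1] - 1, t2 = occ[, 2] - 1)
  w <- hist$counts[occ]

  w <- as.numeric(w)
  if (is.null(u_init)) {
    if (!is.null(seed)) set.seed(seed)
    nstart <- max(1L, as.integer(nstart))
    explore <- min(as.integer(explore_iter), as.integer(max_iter))
    starts <- vector("list", nstart)
    for (k in seq_len(nstart)) {
      u0 <- matrix(runif(B * c), B, c)
      starts[[k]] <- fcm_core(X, w, u0 / rowSums(u0), m, eps, explore)
    }
    objs <- vapply(starts, function(f) tail(f$objective_trace, 1), numeric(1))
    best <- starts[[which.min(objs)]]
    if (best$iter < explore || explore >= max_iter) {
      fit <- best  # already converged during exploration
    } else {
      fit <- fcm_core(X, w, best$u, m, eps, as.integer(max_iter) - explore)
      fit$objective_trace <- c(best$objective_trace, fit$objective_trace)
      fit$iter <- fit$iter + best$iter
    }
  } else {
    if (!is.matrix(u_init) || nrow(u_init) != B || ncol(u_init) != c)
      stop(sprintf("`u_init` must be %d x %d", B, c), call. = FALSE)
    fit <- fcm_core(X, w, u_init / rowSums(u_init), m, eps, as.integer(max_iter))
  }
  structure(list(c = as.integer(c), m = m, eps = eps,
                 memberships = fit$u,
                 centers = matrix(fit$centers, ncol = 2,
                                  dimnames = list(NULL, c("t1", "t2"))),
                 bins = data.frame(t1 = X[, 1], t2 = X[, 2], count = w),
                 objective_trace = fit$objective_trace,
                 iter = fit$iter),
            class = "fcm_partition")
}

#' @export
print.fcm_partition <- function(x, ...) {
  tr <- x$objective_trace
  cat(sprintf("Fuzzy c-means partition: c = %d, m = %g, %d bins, %d iterations (J = %.4g)\n",
              x$c, x$m, nrow(x$bins), x$iter, tr[length(tr)]))
  invisible(x)
}

#' Defuzzify a fuzzy partition into per-cluster binary images
#'
#' Assigns every occupied histogram bin to its cluster of maximal membership
#' (ties broken by the lowest cluster index) and maps the assignment back to
#' pixels, producing c binary masks that partition the slice.
#'
#' @param partition an `fcm_partition` computed on `hist`.
#' @param hist the `intensity_hist2d` the partition was computed on.
#' @param t1,t2 the slice pair `hist` was built from.
#' @return an object of class `cluster_masks`: a list with `assignment`
#'   (integer matrix of cluster indices, same shape as the slices) and `c`.
#'   Use [cluster_mask()] to extract one binary mask.
#' @export
defuzzify <- function(partition, hist, t1, t2) {
  if (!inherits(partition, "fcm_partition"))
    stop("`partition` must come from fcm_cluster()", call. = FALSE)
  assert_pair(t1, t2)
  if (length(t1) != hist$n)
    stop("`hist` was not built from this slice pair", call. = FALSE)
  hard <- max.col(partition$memberships, ties.method = "first")
  # bin index (1..65536) -> cluster, then look pixels up by their bin
  bin_cluster <- integer(256L * 256L)
  bin_cluster[partition$bins$t1 * 256L + partition$bins$t2 + 1L] <- hard
  assignment <- matrix(bin_cluster[as.integer(t1) * 256L + as.integer(t2) + 1L],
                       nrow(t1), ncol(t1))
  structure(list(assignment = assignment, c = partition$c),
            class = "cluster_masks")
}

#' Extract one cluster's binary mask
#'
#' @param masks a `cluster_masks` object from [defuzzify()].
#' @param i cluster index in `1..c`.
#' @return a logical matrix; may be empty if the cluster lost every bin.
#' @export
cluster_mask <- function(masks, i) {
  if (i < 1 || i > masks$c) stop("cluster index out of range", call. = FALSE)
  masks$assignment == i
}

#' @export
print.cluster_masks <- function(x, ...) {
  areas <- tabulate(x$assignment, nbins = x$c)
  cat(sprintf("Defuzzified partition: %d clusters over %d pixels (%d non-empty)\n",
              x$c, length(x$assignment), sum(areas > 0)))
  invisible(x)
}
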