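# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops and textbook definitions only.

# Reference FCM: alternating center/membership updates over a plain data
# list (rows of X, optional weights), same update order as the textbook
# algorithm: centers from memberships, memberships from distances, objective
# after both. Returns the converged objective, centers and trace.
ref_fcm <- function(X, U, m = 2, eps = 1e-9, max_iter = 100, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(X))
  U <- U / rowSums(U)
  n <- nrow(X); cc <- ncol(U)
  trace <- numeric(0)
  J_prev <- Inf
  V <- NULL
  for (it in seq_len(max_iter)) {
    Um <- U^m * w
    V <- t(vapply(seq_len(cc), function(i)
      colSums(X * Um[, i]) / sum(Um[, i]), numeric(ncol(X))))
    D2 <- matrix(0, n, cc)
    for (i in seq_len(cc)) D2[, i] <- rowSums((X - matrix(V[i, ], n, ncol(X), byrow = TRUE))^2)
    Unew <- matrix(0, n, cc)
    for (k in seq_len(n)) {
      z <- which(D2[k, ] < 1e-12)
      if (length(z) > 0) Unew[k, z] <- 1 / length(z)
      else {
        inv <- (1 / D2[k, ])^(1 / (m - 1))
        Unew[k, ] <- inv / sum(inv)
      }
    }
    U <- Unew
    J <- sum(w * rowSums(U^m * D2))
    trace <- c(trace, J)
    if (abs(J_prev - J) <= eps) break
    J_prev <- J
  }
  list(J = trace[length(trace)], centers = V, trace = trace, u = U)
}

# Exhaustive stack-based flood fill labelling (4- or 8-connectivity).
flood_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Breadth-first region growing oracle: literal queue implementation of the
# frozen-statistics merge rule (both channels within mean +/- k * SD of the
# original seed region).
bfs_grow <- function(seed, t1, t2, connectivity = 8, k_sd = 2) {
  mu1 <- mean(t1[seed]); mu2 <- mean(t2[seed])
  s1 <- if (sum(seed) > 1) sd(t1[seed]) else 0
  s2 <- if (sum(seed) > 1) sd(t2[seed]) else 0
  in_range <- function(r, c)
    t1[r, c] >= mu1 - k_sd * s1 && t1[r, c] <= mu1 + k_sd * s1 &&
    t2[r, c] >= mu2 - k_sd * s2 && t2[r, c] <= mu2 + k_sd * s2
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  region <- seed
  queue <- which(seed, arr.ind = TRUE)
  nr <- nrow(t1); nc <- ncol(t1)
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!region[rr, cc] && in_range(rr, cc)) {
        region[rr, cc] <- TRUE
        queue <- rbind(queue, c(rr, cc))
      }
    }
  }
  region
}

# Naive agglomerative 2-clustering of scalars: repeatedly merge the two
# clusters at smallest linkage distance until exactly two remain. Returns a
# group id per value.
brute_agglom2 <- function(values, linkage = "complete") {
  clusters <- as.list(seq_along(values))
  dist_fun <- switch(linkage,
    complete = function(a, b) max(abs(outer(values[a], values[b], "-"))),
    average  = function(a, b) mean(abs(outer(values[a], values[b], "-"))),
    single   = function(a, b) min(abs(outer(values[a], values[b], "-"))))
  while (length(clusters) > 2) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      d <- dist_fun(clusters[[i]], clusters[[j]])
      if (d < bd) { bd <- d; best <- c(j, i) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  grp <- integer(length(values))
  for (g in seq_along(clusters)) grp[clusters[[g]]] <- g
  grp
}

# Pixelwise structuring-element morphology (min/max over the element).
se_offsets <- function(radius, element = "disk") {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  if (element == "disk") d <- d[d$dr^2 + d$dc^2 <= radius^2, ]
  d
}

erode_ref <- function(mask, radius = 1, element = "disk") {
  off <- se_offsets(radius, element)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    keep <- TRUE
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      v <- if (rr < 1 || rr > nr || cc < 1 || cc > nc) FALSE else mask[rr, cc]
      if (!v) { keep <- FALSE; break }
    }
    out[r, c] <- keep
  }
  out
}

dilate_ref <- function(mask, radius = 1, element = "disk") {
  off <- se_offsets(radius, element)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    hit <- FALSE
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      v <- if (rr < 1 || rr > nr || cc < 1 || cc > nc) FALSE else mask[rr, cc]
      if (v) { hit <- TRUE; break }
    }
    out[r, c] <- hit
  }
  out
}

fill_ref <- function(mask) {
  lab <- flood_components(!mask, 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  mask | (lab > 0 & !(lab %in% border))
}

# number of enclosed background components (holes)
count_holes <- function(mask) {
  lab <- flood_components(!mask, 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(unique(lab[lab > 0]), border))
}

# Two-sided p-value of a t statistic by numeric integration of the t
# density written from its closed form (independent of pt()).
t_pvalue_ref <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

# random binary mask with at least one foreground pixel
random_mask <- function(nr, nc, p = 0.4) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

random_slice <- function(nr, nc, max_val = 255) {
  matrix(sample(0:max_val, nr * nc, replace = TRUE), nr, nc)
}
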