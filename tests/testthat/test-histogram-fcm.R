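test_that("the joint histogram counts pixels by their (T1, T2) intensity pair", {
  z <- matrix(0L, 10, 10)
  h <- build_intensity_histogram(z, z)
  expect_equal(h$counts[1, 1], 100)
  expect_equal(sum(h$counts), 100)

  a <- matrix(10L, 1, 1); b <- matrix(20L, 1, 1)
  h2 <- build_intensity_histogram(a, b)
  expect_equal(h2$counts[11, 21], 1)
  expect_equal(sum(h2$counts), 1)

  set.seed(1)
  t1 <- random_slice(13, 9); t2 <- random_slice(13, 9)
  h3 <- build_intensity_histogram(t1, t2)
  expect_equal(sum(h3$counts), 13 * 9)
  expect_equal(h3$counts[t1[5, 5] + 1, t2[5, 5] + 1] > 0, TRUE)

  expect_error(build_intensity_histogram(matrix(0L, 3, 3), matrix(0L, 4, 3)),
               "identical dimensions")
})

test_that("a single cluster takes all membership and the weighted mean center", {
  set.seed(2)
  t1 <- random_slice(8, 8, 50); t2 <- random_slice(8, 8, 50)
  h <- build_intensity_histogram(t1, t2)
  p <- fcm_cluster(h, c = 1, seed = 2)
  expect_true(all(p$memberships == 1))
  expect_equal(p$centers[1, "t1"], mean(t1), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(p$centers[1, "t2"], mean(t2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two tight intensity clouds are resolved at their locations", {
  set.seed(3)
  n <- 100
  lo <- sample(19:21, 2 * n, replace = TRUE)
  hi <- sample(199:201, 2 * n, replace = TRUE)
  t1 <- matrix(c(lo[1:n], hi[1:n]), 10, 20)
  t2 <- matrix(c(lo[n + 1:n], hi[n + 1:n]), 10, 20)
  h <- build_intensity_histogram(t1, t2)
  p <- fcm_cluster(h, c = 2, m = 2, seed = 3)
  centers <- p$centers[order(p$centers[, 1]), ]
  expect_lt(max(abs(centers[1, ] - c(20, 20))), 1)
  expect_lt(max(abs(centers[2, ] - c(200, 200))), 1)

  # independent brute-force iteration from the same start agrees
  occ <- which(h$counts > 0, arr.ind = TRUE)
  set.seed(3)
  u0 <- matrix(runif(nrow(occ) * 2), nrow(occ), 2)
  p2 <- fcm_cluster(h, c = 2, u_init = u0)
  ref <- ref_fcm(cbind(occ[, 1] - 1, occ[, 2] - 1), u0, m = 2,
                 eps = 1e-5, max_iter = 300, w = h$counts[occ])
  expect_equal(tail(p2$objective_trace, 1), ref$J, tolerance = 1e-8)
})

test_that("memberships stay normalized and the objective never increases", {
  set.seed(4)
  for (i in 1:5) {
    t1 <- random_slice(12, 12); t2 <- random_slice(12, 12)
    h <- build_intensity_histogram(t1, t2)
    p <- fcm_cluster(h, c = 4, seed = i)
    expect_lt(max(abs(rowSums(p$memberships) - 1)), 1e-9)
    tr <- p$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("bin-weighted clustering equals per-pixel clustering", {
  set.seed(5)
  for (i in 1:6) {
    nr <- sample(6:16, 1); nc <- sample(6:16, 1)
    t1 <- random_slice(nr, nc, 60); t2 <- random_slice(nr, nc, 60)
    h <- build_intensity_histogram(t1, t2)
    occ <- which(h$counts > 0, arr.ind = TRUE)
    cc <- sample(2:4, 1)
    u0 <- matrix(runif(nrow(occ) * cc), nrow(occ), cc)
    u0 <- u0 / rowSums(u0)
    p <- fcm_cluster(h, c = cc, u_init = u0, eps = 1e-9, max_iter = 150)

    # expand bins to the pixel list, replicating each bin's start row
    bin_of <- match(paste(t1, t2), paste(occ[, 1] - 1, occ[, 2] - 1))
    Xpix <- cbind(as.vector(t1), as.vector(t2))
    ref <- ref_fcm(Xpix, u0[bin_of, , drop = FALSE], m = 2,
                   eps = 1e-9, max_iter = 150)
    expect_equal(tail(p$objective_trace, 1), ref$J, tolerance = 1e-6)
    expect_lt(max(abs(p$centers[order(p$centers[, 1]), ] -
                      ref$centers[order(ref$centers[, 1]), ])), 1e-5)
  }
})

test_that("degenerate clustering inputs are rejected", {
  h <- build_intensity_histogram(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_error(fcm_cluster(h, c = 2), "fewer than c")
  expect_error(fcm_cluster(h, c = 0), "positive integer")
  expect_error(fcm_cluster(h, c = 1, m = 1), "exceed 1")
})

test_that("defuzzification partitions the image by maximal membership", {
  set.seed(6)
  t1 <- random_slice(16, 16); t2 <- random_slice(16, 16)
  h <- build_intensity_histogram(t1, t2)
  p1 <- fcm_cluster(h, c = 1, seed = 6)
  m1 <- defuzzify(p1, h, t1, t2)
  expect_true(all(cluster_mask(m1, 1)))

  p <- fcm_cluster(h, c = 5, seed = 6)
  ms <- defuzzify(p, h, t1, t2)
  areas <- vapply(1:5, function(i) sum(cluster_mask(ms, i)), numeric(1))
  expect_equal(sum(areas), length(t1))
  expect_true(all(ms$assignment >= 1 & ms$assignment <= 5))
})

test_that("noiseless quadrants defuzzify onto their exact pixel sets", {
  t1 <- matrix(0L, 16, 16); t2 <- matrix(0L, 16, 16)
  vals <- list(c(30L, 40L), c(30L, 200L), c(200L, 40L), c(220L, 220L))
  quads <- list(1:8, 9:16)
  k <- 0
  truth <- matrix(0L, 16, 16)
  for (qr in 1:2) for (qc in 1:2) {
    k <- k + 1
    t1[quads[[qr]], quads[[qc]]] <- vals[[k]][1]
    t2[quads[[qr]], quads[[qc]]] <- vals[[k]][2]
    truth[quads[[qr]], quads[[qc]]] <- k
  }
  h <- build_intensity_histogram(t1, t2)
  p <- fcm_cluster(h, c = 4, seed = 1)
  ms <- defuzzify(p, h, t1, t2)
  # each cluster mask must coincide with exactly one quadrant
  for (i in 1:4) {
    mask <- cluster_mask(ms, i)
    lab <- unique(truth[mask])
    expect_length(lab, 1)
    expect_identical(mask, truth == lab)
  }
})

test_that("permuting the initialization permutes masks but not the mask set", {
  set.seed(7)
  t1 <- random_slice(12, 12); t2 <- random_slice(12, 12)
  h <- build_intensity_histogram(t1, t2)
  occ <- sum(h$counts > 0)
  u0 <- matrix(runif(occ * 3), occ, 3)
  perm <- c(3, 1, 2)
  pa <- fcm_cluster(h, c = 3, u_init = u0)
  pb <- fcm_cluster(h, c = 3, u_init = u0[, perm])
  ma <- defuzzify(pa, h, t1, t2)
  mb <- defuzzify(pb, h, t1, t2)
  set_a <- lapply(1:3, function(i) cluster_mask(ma, i))
  set_b <- lapply(1:3, function(i) cluster_mask(mb, i))
  for (i in 1:3)
    expect_true(any(vapply(set_b, identical, logical(1), set_a[[i]])))
})
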