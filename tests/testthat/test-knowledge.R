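test_that("oversized bounding boxes are eliminated under the AND rule", {
  brain <- rect_mask(120, 120, 11, 110, 11, 110)  # 100 x 100
  full <- make_cand(rect_mask(120, 120, 11, 110, 11, 110), 1)
  px <- make_cand(rect_mask(120, 120, 60, 60, 60, 60), 2)
  res <- bounding_box_filter(list(full, px), brain)
  expect_equal(vapply(res$kept, `[[`, integer(1), "cluster_id"), 2L)
  expect_equal(res$trace$decision, c("eliminated", "kept"))

  tall <- make_cand(rect_mask(120, 120, 20, 79, 20, 59), 3)   # 60 x 40
  wide <- make_cand(rect_mask(120, 120, 20, 59, 20, 79), 4)   # 40 x 60
  both <- make_cand(rect_mask(120, 120, 20, 79, 20, 79), 5)   # 60 x 60
  and_res <- bounding_box_filter(list(tall, wide, both), brain, rule = "and")
  expect_setequal(vapply(and_res$kept, `[[`, integer(1), "cluster_id"), c(3L, 4L))
  or_res <- bounding_box_filter(list(tall, wide, both), brain, rule = "or")
  expect_length(or_res$kept, 0)

  empty <- bounding_box_filter(list(), brain)
  expect_length(empty$kept, 0)
})

test_that("mirror symmetry yields a midline verdict with correlation exactly 1", {
  set.seed(21)
  half <- matrix(sample(0:255, 40 * 20, replace = TRUE), 40, 20)
  t2 <- cbind(half, half[, 20:1])
  lat <- laterality_analysis(t2)
  expect_equal(lat$correlation, 1)
  expect_equal(lat$verdict, "midline")
})

test_that("a bright one-sided blob drives a lateral verdict", {
  set.seed(22)
  base <- matrix(sample(60:100, 40 * 20, replace = TRUE), 40, 20)
  t2 <- cbind(base, base[, 20:1])
  t2[15:25, 3:9] <- 220L
  lat <- laterality_analysis(t2)
  expect_equal(lat$verdict, "left")
  expect_lt(lat$correlation, 0.95)
  expect_true(lat$reference_bin >= 215 && lat$reference_bin <= 225)

  # reflecting the image swaps the verdict
  lat_r <- laterality_analysis(t2[, ncol(t2):1])
  expect_equal(lat_r$verdict, "right")
  expect_equal(lat_r$correlation, lat$correlation)
})

test_that("a right-sided phantom tumor is lateralized to the right", {
  ph <- generate_phantom(phantom_spec(tumor_position = "right", noise_sd = 5, seed = 3))
  lat <- laterality_analysis(ph$t2)
  expect_equal(lat$verdict, "right")
  mid <- generate_phantom(phantom_spec(tumor_position = "midline", noise_sd = 5, seed = 3))
  expect_equal(laterality_analysis(mid$t2)$verdict, "midline")
})

test_that("laterality needs pixels above the noise floor", {
  expect_error(laterality_analysis(matrix(10L, 8, 8)), "noise floor")
})

test_that("the side rule removes majority-contralateral candidates only", {
  lat_left <- structure(list(verdict = "left", correlation = 0.5,
                             reference_bin = 100, threshold = 0.95),
                        class = "laterality_result")
  lat_mid <- structure(list(verdict = "midline", correlation = 0.99,
                            reference_bin = 100, threshold = 0.95),
                       class = "laterality_result")
  right_c <- make_cand(rect_mask(40, 40, 5, 15, 25, 35), 1)
  straddle <- make_cand(cbind(rect_mask(40, 14, 10, 19, 1, 14),
                              rect_mask(40, 26, 10, 15, 7, 12)), 2)
  # straddle: 140 px in columns 1-14 (left), 36 px in columns 21-26 (right)

  mid_res <- side_filter(list(right_c, straddle), lat_mid, width = 40)
  expect_length(mid_res$kept, 2)

  res <- side_filter(list(right_c, straddle), lat_left, width = 40)
  expect_equal(vapply(res$kept, `[[`, integer(1), "cluster_id"), 2L)
})

test_that("solidity is area over rasterized convex hull area", {
  expect_equal(solidity(rect_mask(30, 30, 5, 20, 8, 25)), 1)

  # L shape: two 10x10 squares sharing a corner
  L <- rect_mask(30, 30, 1, 10, 1, 10) | rect_mask(30, 30, 10, 19, 10, 19)
  idx <- which(L, arr.ind = TRUE)
  skip_if_not_installed("pracma")
  h <- grDevices::chull(idx[, 2], idx[, 1])
  grid <- expand.grid(x = min(idx[, 2]):max(idx[, 2]),
                      y = min(idx[, 1]):max(idx[, 1]))
  inside <- pracma::inpolygon(grid$x, grid$y,
                              idx[h, 2], idx[h, 1], boundary = TRUE)
  expect_equal(solidity(L), sum(L) / sum(inside), tolerance = 1e-9)

  expect_gte(solidity(disk_mask(50, 50, 25, 25, 20)), 0.95)
  expect_error(solidity(matrix(FALSE, 4, 4)), "empty")
})

test_that("the two-group split keeps the higher cluster and fails open on ties", {
  expect_setequal(hierarchical_split(c(0.9, 0.85, 0.2)), c(1L, 2L))
  expect_setequal(hierarchical_split(c(0.5, 0.5)), c(1L, 2L))
  expect_equal(hierarchical_split(0.7), 1L)
  expect_setequal(hierarchical_split(c(0.9, 0.85, 0.2), keep = "lower"), 3L)
  expect_error(hierarchical_split(numeric(0)), "no values")
})

test_that("the two-group split matches brute-force agglomeration", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    vals <- runif(n)
    kept <- hierarchical_split(vals)
    grp <- brute_agglom2(vals, linkage = "complete")
    means <- tapply(vals, grp, mean)
    expect_setequal(kept, which(grp == as.integer(names(which.max(means)))))
  }
})

test_that("solidity and area filters drop the clearly inferior group", {
  sq <- function(id, n) make_cand(rect_mask(80, 80, 1, n, 1, n), id)
  ragged <- make_cand(rect_mask(80, 80, 1, 30, 1, 1) |
                      rect_mask(80, 80, 1, 1, 1, 30), 3)
  res <- solidity_filter(list(sq(1, 20), sq(2, 18), ragged))
  expect_setequal(vapply(res$kept, `[[`, integer(1), "cluster_id"), c(1L, 2L))

  one <- solidity_filter(list(sq(9, 10)))
  expect_length(one$kept, 1)

  equal_areas <- area_filter(list(sq(1, 10), sq(2, 10)))
  expect_length(equal_areas$kept, 2)

  big1 <- make_cand(rect_mask(100, 100, 1, 71, 1, 71), 1)   # 5041 px
  big2 <- make_cand(rect_mask(100, 100, 1, 70, 1, 70), 2)   # 4900 px
  tiny <- make_cand(rect_mask(100, 100, 1, 5, 1, 8), 3)     # 40 px
  ares <- area_filter(list(big1, big2, tiny))
  expect_setequal(vapply(ares$kept, `[[`, integer(1), "cluster_id"), c(1L, 2L))
})

test_that("selected candidates merge by pixelwise OR", {
  a <- make_cand(rect_mask(30, 30, 1, 10, 1, 10), 1)    # 100 px
  b <- make_cand(rect_mask(30, 30, 20, 24, 20, 29), 2)  # 50 px
  expect_identical(merge_selected(list(a)), a$grown_mask)
  expect_equal(sum(merge_selected(list(a, b))), 150)

  o <- make_cand(rect_mask(30, 30, 5, 14, 5, 14), 3)
  merged <- merge_selected(list(a, o))
  expect_equal(sum(merged), 100 + 100 - sum(a$grown_mask & o$grown_mask))

  expect_identical(merge_selected(list(a, b), manual_ids = 2), b$grown_mask)
  expect_error(merge_selected(list(a, b), manual_ids = c(2, 7)), "unknown")
  expect_error(merge_selected(list()), "no candidate")
})

test_that("the knowledge cascade only ever removes pixels and traces every candidate", {
  fx <- lateral_fit()
  fit <- fx$fit
  union_all <- Reduce(`|`, lapply(fit$candidates, `[[`, "grown_mask"))
  expect_false(any(fit$preliminary_mask & !union_all))
  st <- kb_status(fit)
  expect_setequal(st$cluster_id, seq_len(fit$config$clusters))
  expect_equal(nrow(st), fit$config$clusters)
})
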