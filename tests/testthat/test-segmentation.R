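# paint a shaded disk onto an image (independent of the simulator)
paint_disk <- function(img, r0, c0, rad, amp = 150) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    d2 <- (i - r0)^2 + (j - c0)^2
    if (d2 <= rad^2) img[i, j] <- max(img[i, j], amp * (1 - (d2 / rad^2)^2))
  }
  img
}

test_that("well-separated disks are segmented with accurate centroids", {
  img <- matrix(5, 80, 80)
  img <- paint_disk(img, 25, 20, 10)
  img <- paint_disk(img, 55, 58, 10)
  nuc <- segment_nuclei(img, min_area = 30)
  expect_equal(attr(nuc, "n_nuclei"), 2L)
  pos <- which(nuc > 0, arr.ind = TRUE)
  for (ctr in list(c(25, 20), c(55, 58))) {
    lab <- nuc[ctr[1], ctr[2]]
    expect_gt(lab, 0)
    sel <- pos[nuc[pos] == lab, , drop = FALSE]
    expect_lt(max(abs(colMeans(sel) - ctr)), 1)
  }
})

test_that("a blank noise-only image yields zero nuclei", {
  set.seed(42)
  noise <- matrix(pmax(0, rnorm(96 * 96, 20, 8)), 96, 96)
  nuc <- segment_nuclei(noise)
  expect_equal(attr(nuc, "n_nuclei"), 0L)
  expect_true(all(nuc == 0L))
})

test_that("touching nuclei are split along the overlap waist", {
  # centers 1.5 * radius apart: overlapping disks, distinct distance maxima
  rad <- 12
  img <- matrix(5, 70, 70)
  c1 <- c(35, 26); c2 <- c(35, 26 + 1.5 * rad)
  img <- paint_disk(img, c1[1], c1[2], rad)
  img <- paint_disk(img, c2[1], c2[2], rad)
  nuc <- segment_nuclei(img, min_area = 30)
  expect_equal(attr(nuc, "n_nuclei"), 2L)
  # oracle: grow two seeds over the foreground, assigning each pixel to the
  # nearer center; watershed may only disagree near the equidistance waist
  pos <- which(nuc > 0, arr.ind = TRUE)
  d1 <- sqrt((pos[, 1] - c1[1])^2 + (pos[, 2] - c1[2])^2)
  d2 <- sqrt((pos[, 1] - c2[1])^2 + (pos[, 2] - c2[2])^2)
  want <- ifelse(d1 < d2, nuc[c1[1], c1[2]], nuc[c2[1], c2[2]])
  disagree <- nuc[pos] != want
  expect_true(all(abs(d1 - d2)[disagree] <= 2.5))
  expect_lt(mean(disagree), 0.05)
})

test_that("labels are contiguous, connected, and min_area removes debris", {
  sim <- simulate_image(small_scene_config(seed = 5))
  img <- sim$images$DAPI
  img[2:3, 2:3] <- 200   # 4-px debris blob
  nuc <- segment_nuclei(img, min_area = 30)
  n <- attr(nuc, "n_nuclei")
  expect_equal(n, nrow(sim$ground_truth$nuclei))
  expect_identical(sort(unique(as.integer(nuc[nuc > 0]))), seq_len(n))
  # every label 8-connected (one bwlabel component per label)
  for (lab in seq_len(n)) {
    comp <- EBImage::bwlabel(matrix(as.numeric(nuc == lab), nrow(nuc)))
    expect_equal(max(comp), 1)
  }
})

test_that("dilation matches the exhaustive nearest-label oracle", {
  set.seed(9)
  for (trial in 1:8) {
    lab <- matrix(0L, 40, 40)
    n <- sample(2:5, 1)
    ctr <- cbind(sample(8:32, n), sample(8:32, n))
    for (i in seq_len(n)) {
      rad <- sample(2:5, 1)
      px <- which(outer((1:40 - ctr[i, 1])^2, (1:40 - ctr[i, 2])^2, `+`) <= rad^2)
      lab[px] <- i
    }
    lab <- rnaquant:::.relabel(lab)
    for (radius in c(0, 2, 3, 5)) {
      got <- dilate_labels(lab, radius)
      expect_identical(matrix(as.integer(got), 40), oracle_dilate(lab, radius),
                       info = sprintf("trial %d radius %d", trial, radius))
    }
  }
})

test_that("dilation is the identity at radius 0 and grows disk territories exactly", {
  lab <- matrix(0L, 41, 41)
  px <- which(outer((1:41 - 21)^2, (1:41 - 21)^2, `+`) <= 7^2)
  lab[px] <- 1L
  expect_identical(matrix(as.integer(dilate_labels(lab, 0)), 41), lab)
  ter <- dilate_labels(lab, 3)
  # matches the exhaustive per-pixel distance oracle exactly, and the ideal
  # disk of radius r + 3 up to discretization of the Euclidean metric
  expect_identical(matrix(as.integer(ter), 41), oracle_dilate(lab, 3))
  ideal <- sum(outer((1:41 - 21)^2, (1:41 - 21)^2, `+`) <= 10^2)
  expect_lt(abs(sum(ter == 1) - ideal) / ideal, 0.1)
  expect_error(dilate_labels(lab, -1), "non-negative")
})

test_that("close nuclei partition the gap without overlap and keep all labels", {
  # two disks 4 px apart at closest approach, dilated by 3
  lab <- matrix(0L, 40, 60)
  px1 <- which(outer((1:40 - 20)^2, (1:60 - 15)^2, `+`) <= 8^2)
  px2 <- which(outer((1:40 - 20)^2, (1:60 - 35)^2, `+`) <= 8^2)
  lab[px1] <- 1L; lab[px2] <- 2L
  ter <- dilate_labels(lab, 3)
  expect_identical(matrix(as.integer(ter), 40), oracle_dilate(lab, 3))
  expect_setequal(unique(as.integer(ter[ter > 0])), 1:2)
  # nucleus pixels unchanged, territories are supersets
  expect_true(all(ter[lab > 0] == lab[lab > 0]))
  # monotone in radius
  areas <- vapply(0:4, function(r) sum(dilate_labels(lab, r) > 0), 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("separability flags fused blobs but passes spaced nuclei", {
  sim <- simulate_image(small_scene_config(seed = 2))
  nuc <- segment_nuclei(sim$images$DAPI)
  chk <- separability_check(nuc)
  expect_true(chk$separable)
  expect_equal(chk$fused_fraction, 0)

  # one giant blob holding ~30% of foreground, ceiling below its area
  lab <- matrix(0L, 60, 60)
  lab[1:20, 1:20] <- 1L                      # 400 px blob
  k <- 2L
  for (i in seq(30, 55, by = 9)) for (j in seq(5, 50, by = 9)) {
    if (k > 13L) break
    lab[i:(i + 4), j:(j + 4)] <- k; k <- k + 1L
  }
  chk2 <- separability_check(lab, area_ceiling = 100)
  expect_false(chk2$separable)
  expect_gt(chk2$fused_fraction, 0.25)
})

test_that("a too-dense regime is flagged not separable at a calibrated ceiling", {
  # nuclei packed far closer than their diameter: watershed cannot recover
  # individual cells (the dense-habenula regime)
  cfg <- simulation_config(width = 192, height = 192, n_nuclei = 200,
                           nucleus_radius_mean = 10, nucleus_radius_sd = 1,
                           min_center_spacing = 4,
                           channels = list(channel_spec("p")), seed = 31)
  sim <- simulate_image(cfg)
  nuc <- segment_nuclei(sim$images$DAPI)
  expected_area <- pi * 10^2
  chk <- separability_check(nuc, area_ceiling = 3 * expected_area)
  expect_false(chk$separable)
})
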