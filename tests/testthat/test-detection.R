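test_that("gaussian filter preserves constants, mass, and sigma = 0 is identity", {
  const <- matrix(7, 15, 23)
  expect_equal(gaussian_filter(const, 1), const)
  expect_identical(gaussian_filter(const, 0), const)

  # interior impulse: center value = central kernel weight, mass preserved
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  sm <- gaussian_filter(img, 1)
  r <- ceiling(4)
  w <- dnorm(-r:r, sd = 1); w <- w / sum(w)
  expect_equal(sm[21, 21], w[r + 1]^2, tolerance = 1e-12)
  expect_lt(abs(sum(sm) - 1), 1e-6)

  expect_error(gaussian_filter(img, -1), "non-negative")
})

test_that("isolated peaks, saddles and constant images follow the tolerance rule", {
  # single bright spot over flat background: one focus at the planted pixel
  img <- matrix(10, 31, 31)
  img[16, 12] <- 200
  f <- find_maxima(img, tolerance = 50)
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$row, f$col), c(16, 12))

  # constant image: no foci at any tolerance
  expect_equal(nrow(find_maxima(matrix(3, 20, 20), tolerance = 1)), 0L)

  # tolerance above the total relief: nothing detected
  expect_equal(nrow(find_maxima(img, tolerance = 500)), 0L)

  # two peaks joined by a ridge with a known saddle depth
  x <- matrix(0, 11, 31)
  ridge <- c(seq(0, 100, length.out = 11), seq(95, 60, length.out = 5),
             seq(64, 80, length.out = 5), rep(0, 10))
  x[6, ] <- ridge[seq_len(31)]
  # saddle between peak 100 (col 11) and peak 80 (col 21) is 60
  f_lo <- find_maxima(x, tolerance = 15)   # 80 - 60 = 20 > 15: both kept
  expect_equal(nrow(f_lo), 2L)
  f_hi <- find_maxima(x, tolerance = 25)   # 20 < 25: lower peak merges
  expect_equal(nrow(f_hi), 1L)
  expect_equal(f_hi$value, 100)
})

test_that("plateaus yield one focus at their rounded centroid", {
  img <- matrix(0, 15, 15)
  img[6:8, 6:9] <- 5            # 3x4 plateau, centroid (7, 7.5) -> (7, 8)
  f <- find_maxima(img, tolerance = 2)
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$row, f$col), c(7, 8))

  # two equal-height plateaus separated by lower ground never merge
  img2 <- matrix(0, 9, 21)
  img2[4:5, 3:4] <- 8; img2[4:5, 16:17] <- 8
  f2 <- find_maxima(img2, tolerance = 3)
  expect_equal(nrow(f2), 2L)
})

test_that("detect_foci composes filtering and extraction and honours borders", {
  img <- matrix(5, 41, 41)
  img[20, 20] <- 300; img[3, 3] <- 300
  composed <- detect_foci(img, tolerance = 20, sigma = 1)
  manual <- find_maxima(gaussian_filter(img, 1), 20)
  expect_equal(as.data.frame(composed), as.data.frame(manual))
  expect_equal(nrow(composed), 2L)
  f <- detect_foci(img, tolerance = 20, sigma = 1, exclude_border = 5)
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$row, f$col), c(20, 20))
})

test_that("a uniform aberration patch contributes no spurious foci", {
  # the flat interior of a bright uniform patch has no prominent maxima: at
  # most its single highest point (the plateau top, which stands above the
  # image floor like any bright object) can appear, never a spray of foci
  cfg <- small_scene_config(seed = 11, n_nuclei = 0, stray_rate = 0)
  cfg$aberration_patches <- list(list(row = 40, col = 40, height = 60,
                                      width = 60, intensity = 400))
  sim <- simulate_image(cfg)
  f <- detect_default(sim$images$probeA, cfg$channels[[1]])
  inside <- f$row >= 40 & f$row <= 99 & f$col >= 40 & f$col <= 99
  expect_lte(sum(inside), 1L)
  # and with tolerance above the patch relief, nothing at all
  f2 <- detect_foci(sim$images$probeA, tolerance = 600, sigma = 1)
  expect_equal(nrow(f2), 0L)
})

test_that("find_maxima matches the flood-search oracle on random images", {
  set.seed(101)
  for (trial in 1:30) {
    img <- matrix(runif(32 * 32, 0, 100), 32, 32)
    if (trial %% 3 == 0) img <- matrix(sample(0:6, 32 * 32, TRUE), 32, 32) # ties
    tol <- sample(c(5, 15, 40), 1)
    got <- find_maxima(img, tol)
    want <- oracle_find_maxima(img, tol)
    got <- data.frame(row = as.numeric(got$row), col = as.numeric(got$col),
                      value = got$value)
    want <- data.frame(row = as.numeric(want$row), col = as.numeric(want$col),
                       value = want$value, row.names = NULL)
    expect_equal(got, want, info = sprintf("trial %d tol %g", trial, tol))
  }
})

test_that("focus count is non-increasing in tolerance", {
  set.seed(7)
  sim <- simulate_image(small_scene_config(seed = 7))
  img <- gaussian_filter(sim$images$probeA, 1)
  tols <- c(5, 15, 30, 60, 120, 400)
  counts <- vapply(tols, function(t) nrow(find_maxima(img, t)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("foci shift with integer translations and scale with intensity", {
  sim <- simulate_image(small_scene_config(seed = 3))
  img <- sim$images$probeA
  f0 <- detect_foci(img, tolerance = 60, sigma = 0)
  # integer shift by (5, 9) with constant padding
  sh <- matrix(min(img), nrow(img), ncol(img))
  sh[6:nrow(img), 10:ncol(img)] <- img[1:(nrow(img) - 5), 1:(ncol(img) - 9)]
  f1 <- detect_foci(sh, tolerance = 60, sigma = 0)
  interior <- f0$row + 5 <= nrow(img) - 8 & f0$col + 9 <= ncol(img) - 8
  shifted <- data.frame(row = f0$row + 5, col = f0$col + 9)[interior, ]
  expect_true(all(do.call(paste, shifted) %in% paste(f1$row, f1$col)))

  # scaling image and tolerance together leaves the foci unchanged
  f2 <- detect_foci(img * 3.5, tolerance = 60 * 3.5, sigma = 0)
  expect_equal(as.data.frame(f0)[c("row", "col")], as.data.frame(f2)[c("row", "col")])
})
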