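test_that("linear stretch maps the window onto [0, 255] with the stated rounding", {
  img <- matrix(c(10, 50, 90, 200), 2, 2)
  expect_equal(linear_stretch(img, 0, 255), img)
  st <- linear_stretch(img, 10, 90)
  expect_equal(st[1, 1], 0)    # at in_low
  expect_equal(st[1, 2], 255)  # at in_high
  expect_equal(st[2, 1], 128)  # round(255 * 40 / 80)
  expect_equal(st[2, 2], 255)  # clipped above in_high
  expect_error(linear_stretch(img, 90, 10), class = "ipsoseg_error_parameter")
  expect_error(linear_stretch(matrix(7, 3, 3)),
               class = "ipsoseg_error_degenerate")
})

test_that("percentile-derived stretch window spans the image", {
  img <- matrix(withr::with_seed(1, sample(30:220, 400, TRUE)), 20, 20)
  st <- linear_stretch(img)
  expect_equal(dim(st), dim(img))
  expect_equal(min(st), 0)
  expect_equal(max(st), 255)
})

test_that("binarization is strict and total", {
  expect_true(all(binarize(matrix(128, 2, 2), 255) == 0))
  expect_true(all(binarize(matrix(128, 2, 2), 100) == 1))
  vals <- matrix(c(100, 128, 200), 1, 3)
  expect_equal(as.vector(binarize(vals, 128)), c(0, 0, 1))
})

test_that("connected labeling matches hand flood-fill and adjacency rules", {
  expect_length(label_connected(matrix(0, 4, 4))$region_areas, 0)
  m <- matrix(0, 5, 5); m[1:2, 1:2] <- 1; m[5, 5] <- 1
  lab <- label_connected(m, 8)
  expect_equal(unname(lab$region_areas), c(4, 1))
  expect_equal(lab$labels[1, 1], 1L)
  expect_equal(lab$labels[5, 5], 2L)
  diagm <- matrix(0, 3, 3); diagm[1, 1] <- 1; diagm[2, 2] <- 1
  expect_length(label_connected(diagm, 8)$region_areas, 1)
  expect_length(label_connected(diagm, 4)$region_areas, 2)
  expect_error(label_connected(m, 6), class = "ipsoseg_error_parameter")
})

test_that("labels are numbered in row-major first-encounter order", {
  m <- matrix(0, 4, 6)
  m[3, 1] <- 1   # later row, first column
  m[1, 5] <- 1   # first row, later column -> must get label 1
  lab <- label_connected(m, 8)
  expect_equal(lab$labels[1, 5], 1L)
  expect_equal(lab$labels[3, 1], 2L)
})

test_that("connected labeling agrees with EBImage on random masks (4-connectivity)", {
  for (seed in c(2, 17)) {
    m <- matrix(withr::with_seed(seed, stats::rbinom(40 * 40, 1, 0.4)), 40, 40)
    mine <- label_connected(m, 4)
    ref <- EBImage::bwlabel(m)
    expect_equal(length(mine$region_areas), max(ref))
    # same partition: each of my labels maps onto exactly one reference label
    cross <- table(mine$labels[m == 1], ref[m == 1])
    expect_true(all(rowSums(cross > 0) == 1))
    expect_true(all(colSums(cross > 0) == 1))
  }
})

test_that("area filter keeps only regions inside the window and is idempotent", {
  m <- matrix(0, 5, 5); m[1:2, 1:2] <- 1; m[5, 5] <- 1
  lab <- label_connected(m, 8)
  expect_equal(area_filter(lab, 1), m)
  kept <- area_filter(lab, 2)
  expect_equal(sum(kept), 4)
  expect_equal(kept[5, 5], 0)
  expect_true(all(area_filter(lab, 99) == 0))
  expect_error(area_filter(lab, 5, 2), class = "ipsoseg_error_parameter")
  # filtering an already-filtered mask with the same bounds changes nothing
  again <- area_filter(label_connected(kept, 8), 2)
  expect_equal(again, kept)
})

test_that("Gaussian smoothing preserves constants, normalization and range", {
  const <- matrix(42, 8, 8)
  expect_equal(gaussian_smooth(const, 1.7), const)
  k <- ipsoseg:::gaussian_kernel_1d(2.3)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  img <- matrix(withr::with_seed(3, sample(0:255, 30 * 30, TRUE)), 30, 30)
  sm <- gaussian_smooth(img, 2)
  expect_true(all(sm >= 0 & sm <= 255))
  expect_equal(dim(sm), dim(img))
  expect_error(gaussian_smooth(img, 0), class = "ipsoseg_error_parameter")
})

test_that("impulse response equals the kernel center weight", {
  sigma <- 1.3
  img <- matrix(0, 21, 21); img[11, 11] <- 255
  k <- ipsoseg:::gaussian_kernel_1d(sigma)
  center <- k[(length(k) + 1) %/% 2]
  sm <- gaussian_smooth(img, sigma)
  expect_equal(sm[11, 11], round_half_away(center^2 * 255))
})
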