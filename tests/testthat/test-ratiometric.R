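test_that("max projection takes the per-pixel maximum over z", {
  st <- array(0, dim = c(1, 1, 3))
  st[1, 1, ] <- c(1, 5, 3)
  expect_equal(max_project(st)[1, 1], 5)
  one <- array(runif(12), dim = c(3, 4, 1))
  expect_equal(max_project(one), one[, , 1])
  set.seed(1)
  st3 <- array(runif(60), dim = c(4, 5, 3))
  want <- pmax(st3[, , 1], st3[, , 2], st3[, , 3])
  expect_equal(max_project(st3), want)
  expect_error(max_project(array(0, dim = c(2, 2, 0))), "z-slice")
})

test_that("red threshold is a boundary-inclusive fraction of the image maximum", {
  img <- matrix(c(200, 30, 29, 0), 2, 2)
  mask <- threshold_red(img, fraction = 0.15)
  expect_true(mask[1, 1])   # the max itself
  expect_true(mask[2, 1])   # exactly at the 15% cutoff (30)
  expect_false(mask[1, 2])  # 29, just below
  expect_true(all(threshold_red(matrix(100, 3, 3))))
  zero <- threshold_red(matrix(0, 2, 2))
  expect_false(any(zero))
  expect_true(attr(zero, "all_zero"))
  expect_error(threshold_red(img, fraction = 1.2), "fraction")
})

test_that("single-pixel removal deletes only size-one components", {
  m <- matrix(FALSE, 6, 6)
  m[3, 3] <- TRUE              # isolated pixel
  m[5:6, 5:6] <- TRUE          # 2x2 block
  out <- remove_single_pixels(m)
  expect_false(out[3, 3])
  expect_true(all(out[5:6, 5:6]))
  expect_equal(sum(out), 4)
  # diagonal pair is one 8-connected component of size 2: retained
  d <- matrix(FALSE, 3, 3)
  d[1, 1] <- d[2, 2] <- TRUE
  expect_equal(remove_single_pixels(d), d)
  empty <- matrix(FALSE, 3, 3)
  expect_equal(remove_single_pixels(empty), empty)
})

test_that("single-pixel removal is idempotent on random masks", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_mask(10, 12, p = runif(1, 0.1, 0.7))
    once <- remove_single_pixels(m)
    expect_identical(remove_single_pixels(once), once)
  }
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(11)
  for (i in 1:100) {
    m <- random_mask(8, 8, p = runif(1, 0.1, 0.8))
    expect_identical(label_objects(m), oracle_label(m))
  }
  # documented fixtures
  two <- matrix(FALSE, 6, 8)
  two[1:2, 1:2] <- TRUE
  two[5:6, 6:7] <- TRUE
  expect_equal(max(label_objects(two)), 2)
  expect_equal(max(label_objects(matrix(TRUE, 5, 5))), 1)
  expect_equal(max(label_objects(matrix(FALSE, 5, 5))), 0)
})

test_that("object measurements report areas, channel means and their ratio", {
  lab <- matrix(0L, 3, 4)
  lab[1, 1:2] <- 1L
  lab[3, 2:4] <- 2L
  g <- matrix(0, 3, 4); r <- matrix(0, 3, 4)
  g[1, 1:2] <- 10; r[1, 1:2] <- 5
  g[3, 2:4] <- c(1, 2, 3); r[3, 2:4] <- c(2, 4, 6)
  m <- measure_objects(lab, g, r, pixel_size = 0.5)
  expect_equal(m$area_px, c(2L, 3L))
  expect_equal(m$area_um2, c(2, 3) * 0.25)
  expect_equal(m$mean_green, c(10, 2))
  expect_equal(m$ratio, c(0.5, 2))
  # zero-green object is retained and flagged, not dropped
  g[1, 1:2] <- 0
  m2 <- measure_objects(lab, g, r)
  expect_true(is.na(m2$ratio[1]))
  expect_false(m2$ratio_defined[1])
  expect_equal(nrow(m2), 2)
  expect_error(measure_objects(lab, g[, 1:3], r), "identical dimensions")
})

test_that("ratio images divide inside the mask and mark undefined pixels", {
  red <- matrix(c(4, 0, 6), 1, 3)
  green <- matrix(c(2, 5, 0), 1, 3)
  mask <- matrix(c(TRUE, TRUE, TRUE), 1, 3)
  rg <- ratio_image(red, green, mask)
  expect_equal(rg[1, 1], 2)
  expect_equal(rg[1, 2], 0)
  expect_true(is.na(rg[1, 3]))        # zero denominator
  gr <- ratio_image(red, green, mask, direction = "green_over_red")
  expect_equal(gr[1, 1], 0.5)
  expect_true(is.na(gr[1, 2]))
  outside <- ratio_image(red, green, matrix(FALSE, 1, 3))
  expect_true(all(is.na(outside)))
})

test_that("saturation is flagged only at the detector ceiling", {
  img <- matrix(c(65535, 100), 1, 2)
  chk <- saturation_check(img, 16)
  expect_true(chk$saturated)
  expect_equal(chk$n_saturated, 1)
  expect_false(saturation_check(matrix(65534, 2, 2), 16)$saturated)
})

test_that("cell-average intensity is the integrated intensity per mask pixel", {
  img <- matrix(c(0, 0, 10, 10), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  expect_equal(cell_average_intensity(img, mask), 5)
  expect_equal(cell_average_intensity(matrix(7, 3, 3), matrix(TRUE, 3, 3)), 7)
  expect_equal(cell_average_intensity(3 * img, mask), 15)  # linearity
  expect_error(cell_average_intensity(img, matrix(FALSE, 2, 2)), "empty")
})

test_that("ratio outputs are exactly invariant to joint channel scaling", {
  set.seed(3)
  g <- matrix(runif(400, 0, 50), 20, 20)
  r <- matrix(runif(400, 0, 80), 20, 20)
  mask <- threshold_red(r)
  mask2 <- threshold_red(r * 8)   # dyadic factor: float-exact
  expect_identical(unclass(mask), unclass(mask2))
  lab <- label_objects(remove_single_pixels(mask))
  m1 <- measure_objects(lab, g, r)
  m2 <- measure_objects(lab, g * 8, r * 8)
  expect_identical(m1$ratio, m2$ratio)
  expect_identical(ratio_image(r, g, mask), ratio_image(r * 8, g * 8, mask))
})
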