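test_that("thresholding handles the documented base cases", {
  z <- threshold_binarize(matrix(0, 8, 8))
  expect_equal(z$n_foreground, 0)
  expect_equal(z$flag, "empty")
  two <- matrix(c(0.1, 0.9), 8, 8)
  m <- threshold_binarize(two, method = "fixed_fraction", fraction = 0.5)
  expect_equal(m$pixels, two == 0.9)
  expect_null(m$flag)
})

test_that("otsu matches an exhaustive threshold search on bimodal images", {
  set.seed(21)
  for (i in 1:10) {
    # values quantised to bin centers so histogram and direct search agree
    n_lo <- 300; n_hi <- 60
    v <- c(pmin(pmax(rnorm(n_lo, 0.2, 0.05), 0), 1),
           pmin(pmax(rnorm(n_hi, 0.8, 0.05), 0), 1))
    v <- (floor(v * 255.999) + 0.5) / 256
    img <- matrix(sample(v), 20, 18)
    img <- img / max(img) * max(v)  # keep scale
    thr_pkg <- otsu_threshold(img)
    thr_ora <- otsu_exhaustive(img)
    fg_pkg <- sum(img >= thr_pkg)
    fg_ora <- sum(img >= thr_ora)
    expect_equal(fg_pkg, fg_ora)
  }
})

test_that("component labeling follows connectivity definitions and the oracle", {
  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(max(label_components(diag2, connectivity = 8)$labels), 1)
  expect_equal(max(label_components(diag2, connectivity = 4)$labels), 2)
  empty <- label_components(matrix(FALSE, 5, 5))
  expect_equal(length(empty$areas), 0)
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(runif(256) < 0.4, 16, 16)
    for (conn in c(4L, 8L)) {
      lab <- label_components(m, conn)$labels
      ora <- label_floodfill(m, conn)
      # identical up to renaming: same partition
      expect_equal(max(lab), max(ora))
      key <- paste(lab, ora)
      expect_equal(length(unique(key[m])), max(ora))
    }
  }
})

test_that("large-component selection keeps the documented components", {
  m <- matrix(FALSE, 40, 120)
  m[20, 5:104] <- TRUE        # 100-px line
  m[5, 1:4] <- TRUE           # small blobs
  m[35, 10:13] <- TRUE
  m[10, 110:112] <- TRUE
  lab <- label_components(m)
  kept <- select_large_components(lab, policy = "largest")
  expect_equal(kept$n_foreground, 100)
  expect_true(all(which(kept$pixels) == which(m & row(m) == 20)))
  # single component unchanged
  one <- matrix(FALSE, 8, 8); one[3:5, 3:5] <- TRUE
  expect_equal(select_large_components(label_components(one))$pixels, one)
  # area_fraction keeps everything above the cut
  af <- select_large_components(lab, policy = "area_fraction", alpha = 0.03)
  expect_equal(af$n_foreground, 100 + 4 + 4 + 3)
  # tie: first label in raster (column-major) order wins
  tie <- matrix(FALSE, 16, 16)
  tie[10:12, 2:5] <- TRUE   # discovered first (smaller column)
  tie[2:4, 9:12] <- TRUE    # same area, later columns
  out <- select_large_components(label_components(tie))
  expect_equal(sum(out$pixels[10:12, 2:5]), 12)
  expect_equal(out$n_foreground, 12)
  # no components -> flagged empty
  none <- select_large_components(label_components(matrix(FALSE, 4, 4)))
  expect_equal(none$flag, "no_components")
})

test_that("the full preprocessing chain recovers simulated needle bands", {
  cfg <- sim_config(image_size = c(96L, 96L), seed = 17L)
  pair <- simulate_pair(cfg, seed = 99L)
  got <- preprocess_pa(pair$pa_image)
  expect_null(got$flag)
  # foreground is inside the true band and excludes every blob pixel
  expect_true(all(pair$pa_mask$pixels[got$pixels]))
  expect_gt(dice_coefficient(got, pair$pa_mask), 0.9)
  # all-zero frame flagged, no error
  ez <- preprocess_pa(matrix(0, 32, 32))
  expect_equal(ez$flag, "empty")
  # line + smaller blobs -> exactly one surviving component
  expect_equal(max(label_components(got$pixels)$labels), 1)
})

test_that("preprocessing never creates pixels and is idempotent", {
  set.seed(41)
  cfg <- sim_config(image_size = c(64L, 64L), seed = 13L)
  for (s in 1:5) {
    pair <- simulate_pair(cfg, seed = s)
    bin <- threshold_binarize(pair$pa_image)
    out <- preprocess_pa(pair$pa_image)
    expect_true(all(bin$pixels[out$pixels]))            # output subset of thresholded
    expect_true(all(pair$pa_image$values[out$pixels] > 0))  # subset of support
    again <- preprocess_pa(out$pixels * 1)
    expect_equal(again$pixels, out$pixels)              # idempotent on own output
  }
})
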