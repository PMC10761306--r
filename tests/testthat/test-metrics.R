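band_mask <- function(H, W, p1, p2, half_width) {
  rows <- matrix(rep(0:(H - 1), W), H, W)
  cols <- matrix(rep(0:(W - 1), each = H), H, W)
  d <- p2 - p1
  t <- pmin(pmax(((rows - p1[1]) * d[1] + (cols - p1[2]) * d[2]) / sum(d^2), 0), 1)
  dist <- sqrt((rows - (p1[1] + t * d[1]))^2 + (cols - (p1[2] + t * d[2]))^2)
  dist <= half_width
}

test_that("needle line estimation is exact for collinear input", {
  diag_mask <- matrix(FALSE, 11, 11)
  diag_mask[cbind(1:11, 1:11)] <- TRUE
  ln <- estimate_needle_line(diag_mask)
  expect_equal(ln$tip, c(10, 10), tolerance = 1e-9)
  expect_equal(ln$base, c(0, 0), tolerance = 1e-9)
  expect_equal(abs(sum(ln$direction * c(1, 1) / sqrt(2))), 1, tolerance = 1e-9)
  # horizontal bar: rows = 5, cols 2..20 (0-based)
  bar <- matrix(FALSE, 10, 25)
  bar[6, 3:21] <- TRUE
  lb <- estimate_needle_line(bar)
  expect_equal(abs(lb$direction), c(0, 1), tolerance = 1e-9)
  expect_equal(sort(c(lb$tip[2], lb$base[2])), c(2, 20), tolerance = 1e-9)
  expect_equal(lb$tip[1], 5, tolerance = 1e-9)
  # degenerate masks yield no line
  expect_null(estimate_needle_line(matrix(FALSE, 4, 4)))
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_null(estimate_needle_line(one))
})

test_that("needle line estimation recovers noisy band directions within 2 deg", {
  set.seed(51)
  worst <- 0
  for (i in 1:100) {
    ang <- runif(1, 5, 85) * pi / 180
    p1 <- c(10 + runif(1, 0, 10), 5 + runif(1, 0, 10))
    len <- runif(1, 40, 60)
    p2 <- p1 + len * c(sin(ang), cos(ang))
    m <- band_mask(80, 80, p1, p2, 1.5)
    ln <- estimate_needle_line(m)
    dtrue <- c(sin(ang), cos(ang))
    dev <- acos(pmin(1, abs(sum(ln$direction * dtrue)))) * 180 / pi
    worst <- max(worst, dev)
  }
  expect_lt(worst, 2)
})

test_that("directed mean distance and MHD match closed forms", {
  A <- rbind(c(0, 0))
  expect_equal(directed_mean_distance(A, A), 0)
  expect_equal(directed_mean_distance(A, rbind(c(3, 4))), 5)
  A2 <- rbind(c(0, 0), c(1, 0))
  B2 <- rbind(c(0, 1))
  expect_equal(directed_mean_distance(A2, B2), (1 + sqrt(2)) / 2)
  expect_equal(mhd(A2, B2), (1 + sqrt(2)) / 2)
  expect_equal(mhd(A2, A2), 0)
  expect_error(directed_mean_distance(A[0, , drop = FALSE], A), "non-empty")
})

test_that("MHD equals the brute-force oracle and is rigid-motion invariant", {
  set.seed(61)
  for (i in 1:30) {
    A <- random_point_set(sample.int(30, 1))
    B <- random_point_set(sample.int(30, 1))
    v <- mhd(A, B)
    expect_equal(v, mhd_bruteforce(A, B), tolerance = 1e-9)
    expect_equal(v, mhd(B, A))
    expect_gte(v, 0)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sh <- runif(2, -5, 5)
    expect_equal(mhd(sweep(A %*% R, 2, sh), sweep(B %*% R, 2, sh)), v,
                 tolerance = 1e-9)
  }
})

test_that("localization success applies both criteria", {
  gt <- band_mask(64, 64, c(10, 10), c(50, 50), 1.5)
  gtm <- needle_mask(gt)
  ln <- estimate_needle_line(gt)
  expect_true(localization_success(gtm, gtm, ln))
  expect_false(localization_success(gtm, needle_mask(matrix(FALSE, 64, 64)), NULL))
  # same shape far from the needle: zero intersection
  far <- band_mask(64, 64, c(10, 50), c(50, 10), 1.5)
  expect_false(localization_success(gtm, needle_mask(far & !gt),
                                    estimate_needle_line(far & !gt)))
  # sufficient overlap but line that misses the ground truth fails criterion 1
  off_line <- needle_line(c(0, 63), c(0, 0))  # top image row
  expect_false(localization_success(gtm, gtm, off_line))
})

test_that("targeting error follows the point-line distance formula", {
  l1 <- needle_line(c(60, 60), c(3, 3))
  expect_equal(targeting_error(l1, l1, c(64, 64)), 0)
  # true line through the center, predicted parallel 7 px away
  ctr <- c(63, 63) / 2
  thr <- needle_line(ctr + c(10, 10), ctr - c(10, 10))
  off <- 7 * c(1, -1) / sqrt(2)
  pred <- needle_line(ctr + c(10, 10) + off, ctr - c(10, 10) + off)
  expect_equal(targeting_error(thr, pred, c(64, 64)), 7, tolerance = 1e-9)
  expect_equal(targeting_error(pred, thr, c(64, 64)), 7, tolerance = 1e-9)
})

test_that("needle length ratio is a plain length quotient", {
  a <- needle_line(c(6, 8), c(0, 0))
  b <- needle_line(c(3, 4), c(0, 0))
  expect_equal(needle_length_ratio(a, a), 1)
  expect_equal(needle_length_ratio(b, a), 0.5)
  expect_equal(needle_length_ratio(a, b), 2)
})

test_that("evaluate_dataset matches an independently scripted computation", {
  gt1 <- band_mask(64, 64, c(12, 8), c(50, 52), 1.5)
  pred1 <- gt1                                         # perfect
  gt2 <- band_mask(64, 64, c(20, 6), c(55, 40), 1.5)
  pred2 <- gt2 & band_mask(64, 64, c(20, 6), c(40, 26), 6)  # partial needle
  gt3 <- band_mask(64, 64, c(8, 40), c(56, 10), 1.5)
  pred3 <- matrix(FALSE, 64, 64)                       # miss
  preds <- lapply(list(pred1, pred2, pred3), needle_mask)
  gts <- lapply(list(gt1, gt2, gt3), needle_mask)
  rep <- evaluate_dataset(preds, gts)
  expect_equal(rep$nlsr, 100 * 2 / 3)
  expect_equal(sum(rep$per_image$success), 2)
  # independent recomputation for the two successes
  exp_mhd <- vapply(1:2, function(i) {
    mhd_bruteforce(which(preds[[i]]$pixels, arr.ind = TRUE) - 1,
                   which(gts[[i]]$pixels, arr.ind = TRUE) - 1)
  }, numeric(1))
  expect_equal(rep$per_image$mhd[1:2], exp_mhd, tolerance = 1e-9)
  expect_equal(rep$summary$mhd[["mean"]], mean(exp_mhd), tolerance = 1e-9)
  expect_equal(rep$summary$mhd[["sd"]], sd(exp_mhd), tolerance = 1e-9)
  expect_true(all(is.na(rep$per_image$mhd[3])))
  expect_equal(rep$per_image$length_ratio[1], 1, tolerance = 1e-9)
  expect_equal(rep$per_image$te[1], 0, tolerance = 1e-9)
  expect_error(evaluate_dataset(preds[1:2], gts), "equal length")
})

test_that("failures are excluded from success-only summaries", {
  gt <- band_mask(48, 48, c(8, 8), c(40, 40), 1.5)
  good <- needle_mask(gt)
  bad <- needle_mask(matrix(FALSE, 48, 48))
  rep <- evaluate_dataset(list(good, bad, good, good), rep(list(needle_mask(gt)), 4))
  expect_equal(rep$nlsr, 75)
  expect_equal(rep$summary$mhd[["mean"]], 0)
  expect_equal(rep$summary$length_ratio[["mean"]], 1)
  expect_equal(rep$summary$te[["mean"]], 0)
  expect_equal(rep$summary$mhd[["sd"]], 0)  # over exactly the 3 successes
})
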