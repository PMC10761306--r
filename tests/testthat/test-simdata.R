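test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(image_size = c(64L, 64L), seed = 3L)
  a <- simulate_pair(cfg, seed = 42L)
  b <- simulate_pair(cfg, seed = 42L)
  expect_identical(a$us_image$values, b$us_image$values)
  expect_identical(a$pa_image$values, b$pa_image$values)
  expect_identical(a$pa_mask$pixels, b$pa_mask$pixels)
  expect_identical(a$true_line$tip, b$true_line$tip)
  c <- simulate_pair(cfg, seed = 43L)
  expect_false(identical(a$us_image$values, c$us_image$values))
})

test_that("the noiseless limit renders a strictly bright needle", {
  cfg <- sim_config(image_size = c(64L, 64L), speckle_scale = 0,
                    needle_dropout = 0, ghost_max = 0L, seed = 9L)
  pair <- simulate_pair(cfg, seed = 4L)
  us <- pair$us_image$values
  expect_true(all(us >= 0 & us <= 1))
  on_needle <- pair$pa_mask$pixels
  expect_true(min(us[on_needle]) > max(us[!on_needle & us > 0], 0))
})

test_that("ground truth is the exact thickness band and ignores US noise", {
  cfg <- sim_config(image_size = c(64L, 64L), seed = 5L)
  pair <- simulate_pair(cfg, seed = 11L)
  pts <- which(pair$pa_mask$pixels, arr.ind = TRUE) - 1
  ln <- pair$true_line
  v <- sweep(pts, 2, ln$base)
  perp <- abs(v[, 1] * ln$direction[2] - v[, 2] * ln$direction[1])
  thick <- cfg$thickness_by_gauge[[as.character(pair$meta$gauge)]]
  expect_lte(max(perp), thick / 2 + 1e-9)
  # mask independent of speckle/ghost settings at the same seed
  cfg2 <- sim_config(image_size = c(64L, 64L), speckle_scale = 0.4,
                     ghost_max = 0L, seed = 5L)
  pair2 <- simulate_pair(cfg2, seed = 11L)
  expect_identical(pair$pa_mask$pixels, pair2$pa_mask$pixels)
})

test_that("needle echo amplitude is non-increasing with insertion angle", {
  amps <- vapply(c(10, 20, 30, 40), function(a) {
    cfg <- sim_config(image_size = c(64L, 64L), angle_range = c(a, a),
                      speckle_scale = 0, seed = 2L)
    simulate_pair(cfg, seed = 8L)$meta$echo_amp
  }, numeric(1))
  expect_true(all(diff(amps) <= 0))
})

test_that("impossible geometry is rejected after bounded retries", {
  cfg <- sim_config(image_size = c(64L, 64L), angle_range = c(60, 60),
                    depth_range = c(0.1, 0.1), length_frac_range = c(0.9, 0.9),
                    seed = 1L)
  expect_error(simulate_pair(cfg), "rejected")
})

test_that("dataset split sizes are floor-based with remainder to train", {
  expect_equal(unname(usneedle:::split_sizes(2600, c(0.8, 0.1, 0.1))),
               c(2080, 260, 260))
  expect_equal(unname(usneedle:::split_sizes(10, c(0.8, 0.1, 0.1))),
               c(8, 1, 1))
  expect_equal(unname(usneedle:::split_sizes(25, c(0.8, 0.1, 0.1))),
               c(21, 2, 2))
  expect_error(simulate_dataset(sim_config(), 20, split = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("datasets and manifests are reproducible and written to disk", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(image_size = c(32L, 32L), margin = 4L, seed = 7L)
  d1 <- simulate_dataset(cfg, 10L, outdir = file.path(outdir, "a"))
  d2 <- simulate_dataset(cfg, 10L, outdir = file.path(outdir, "b"))
  expect_identical(d1$manifest$seed, d2$manifest$seed)
  expect_identical(d1$pairs[[3]]$us_image$values, d2$pairs[[3]]$us_image$values)
  expect_equal(d1$split, rep(c("train", "val", "test"), c(8, 1, 1)))
  man <- read.csv(file.path(outdir, "a", "manifest.csv"))
  expect_equal(nrow(man), 10)
  # images round-trip through PGM within quantisation error
  us <- read_pgm(man$path_us[1])
  expect_equal(us, d1$pairs[[1]]$us_image$values, tolerance = 1e-4)
  mk <- read_pgm(man$path_mask[1])
  expect_identical(mk > 0.5, d1$pairs[[1]]$pa_mask$pixels)
})

test_that("the fixture suite is written with stable checksums", {
  outdir <- withr::local_tempdir()
  sums1 <- make_fixture_suite(file.path(outdir, "f1"))
  sums2 <- make_fixture_suite(file.path(outdir, "f2"))
  expect_equal(sums1$md5, sums2$md5)
  expect_equal(nrow(sums1), 5)
  # fixtures load back and behave as constructed
  blob <- read_pgm(file.path(outdir, "f1", "blob_only_pa.pgm"))
  got <- preprocess_pa(blob)
  expect_true(is.null(got$flag) || nzchar(got$flag))  # valid mask object
  expect_equal(max(label_components(got$pixels)$labels) <= 1, TRUE)
  empty <- read_pgm(file.path(outdir, "f1", "empty.pgm"))
  expect_equal(preprocess_pa(empty)$flag, "empty")
  mask <- read_pgm(file.path(outdir, "f1", "noiseless_mask.pgm")) > 0.5
  expect_gt(sum(mask), 0)
})

test_that("PGM round-trips exactly at both bit depths", {
  m <- matrix(runif(63 * 17), 63, 17)
  p8 <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(m, p8, maxval = 255L)
  expect_equal(read_pgm(p8), m, tolerance = 1 / 255)
  p16 <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(m, p16, maxval = 65535L)
  expect_equal(read_pgm(p16), m, tolerance = 1 / 65535)
  pa <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(m, pa, ascii = TRUE)
  expect_equal(read_pgm(pa), read_pgm(p8))
})
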