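forward_probs <- function(model, x) {
  out <- model$fwd(usneedle:::ag_const(array(x, c(dim(x), 1L, 1L))),
                   train = FALSE)
  list(fused = 1 / (1 + exp(-out$fused$val[, , 1, 1])),
       side = lapply(out$side, function(s) 1 / (1 + exp(-s$val[, , 1, 1]))))
}

test_that("all variants share the input/output shape contract", {
  set.seed(71)
  x <- matrix(runif(32 * 32), 32, 32)
  for (v in c("uiu", "unet", "attention_unet", "r2u")) {
    model <- build_network(network_spec(v, base_channels = 2L))
    out <- forward_probs(model, x)
    expect_equal(dim(out$fused), c(32L, 32L))
    expect_true(all(out$fused > 0 & out$fused < 1))
    if (v == "uiu") {
      expect_length(out$side, 4L)
      for (s in out$side) expect_equal(dim(s), c(32L, 32L))
    } else {
      expect_length(out$side, 0L)
    }
  }
})

test_that("parameter count strictly increases with base_channels", {
  set.seed(72)
  for (v in c("uiu", "unet")) {
    n1 <- count_params(build_network(network_spec(v, base_channels = 4L)))
    n2 <- count_params(build_network(network_spec(v, base_channels = 8L)))
    expect_gt(n2, n1)
  }
})

test_that("incompatible input sizes are rejected with the admissible size", {
  set.seed(73)
  model <- build_network(network_spec("uiu"))
  expect_error(predict_needle(model, matrix(0.5, 6, 6)), "too small")
  ds <- tiny_sim_dataset(n = 12L, size = 40L)   # 40 not a multiple of 16
  expect_error(train_network(model, ds, train_config(iterations = 2)),
               "multiples of 16")
  expect_error(network_spec("uiu", n_scales = 2), ">= 3")
})

test_that("multi-BCE loss matches its closed forms", {
  tgt <- matrix(c(0, 1), 8, 8)
  eps <- 1e-7
  perfect <- pmin(pmax(tgt, eps), 1 - eps)
  expect_lt(multi_bce_loss(list(perfect, perfect), perfect, tgt),
            3 * 1e-6)
  expect_gte(multi_bce_loss(list(), perfect, tgt), 0)
  # single map with no side outputs reduces to plain BCE
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  plain <- -mean(tgt * log(p) + (1 - tgt) * log(1 - p))
  expect_equal(multi_bce_loss(list(), p, tgt), plain)
  # uniform 0.5 predictions: n_outputs * ln 2
  half <- matrix(0.5, 8, 8)
  expect_equal(multi_bce_loss(list(half, half, half), half, tgt), 4 * log(2),
               tolerance = 1e-12)
  expect_error(multi_bce_loss(list(), matrix(0.5, 4, 4), tgt), "mismatch")
})

test_that("training memorizes a single sample and selects the best checkpoint", {
  ds <- tiny_sim_dataset(n = 12L, size = 32L, seed = 6L)
  one <- list(pairs = ds$pairs[c(1, 1)], split = c("train", "val"))
  set.seed(74)
  model <- build_network(network_spec("unet", base_channels = 4L))
  x0 <- usneedle:::stack_batch(list(ds$pairs[[1]]$us_image$values))
  y0 <- usneedle:::stack_batch(list(ds$pairs[[1]]$pa_mask$pixels * 1))
  loss0 <- usneedle:::forward_loss(model, x0, y0, train = FALSE)$loss$val[1]
  ck <- train_network(model, one,
                      train_config(iterations = 60L, batch_size = 1L,
                                   val_every = 20L, loss = "bce", seed = 10L))
  expect_lt(ck$best_val_loss, loss0)
  expect_equal(ck$best_val_loss, min(ck$log$val_loss))
  expect_true(ck$iteration_of_best %in% ck$log$iteration)
  # reloading the checkpoint reproduces the recorded validation loss
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  model2 <- usneedle:::model_from_checkpoint(ck2)
  l2 <- usneedle:::forward_loss(model2, x0, y0, train = FALSE)$loss$val[1]
  expect_equal(l2, ck$best_val_loss, tolerance = 1e-12)
})

test_that("training is deterministic given a seed", {
  ds <- tiny_sim_dataset(n = 12L, size = 32L, seed = 8L)
  run <- function() {
    model <- withr::with_seed(20L, build_network(network_spec("unet", base_channels = 2L)))
    train_network(model, ds, train_config(iterations = 20L, val_every = 10L,
                                          loss = "bce", seed = 21L))
  }
  a <- run()
  b <- run()
  expect_identical(a$log, b$log)
  expect_identical(a$weights, b$weights)
})

test_that("prediction thresholds behave at the extremes and deterministically", {
  ds <- tiny_sim_dataset(n = 12L, size = 32L, seed = 9L)
  set.seed(75)
  model <- build_network(network_spec("uiu", base_channels = 2L))
  img <- ds$pairs[[1]]$us_image
  p0 <- predict_needle(model, img, binarize_threshold = 0)
  expect_true(all(p0$mask$pixels))
  p1 <- predict_needle(model, img, binarize_threshold = 1)
  expect_false(any(p1$mask$pixels))
  pa <- predict_needle(model, img)
  pb <- predict_needle(model, img)
  expect_identical(pa$mask$pixels, pb$mask$pixels)
  expect_equal(dim(pa$prob), c(32L, 32L))
  # non-multiple sizes are padded and cropped back
  odd <- matrix(runif(40 * 48), 40, 48)
  po <- predict_needle(model, odd)
  expect_equal(dim(po$prob), c(40L, 48L))
})

test_that("uiu training demands the multi-BCE loss", {
  ds <- tiny_sim_dataset(n = 12L, size = 32L, seed = 12L)
  set.seed(76)
  model <- build_network(network_spec("uiu", base_channels = 2L))
  expect_error(train_network(model, ds, train_config(iterations = 2L, loss = "bce")),
               "multi_bce")
})
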