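#' Training configuration
#'
#' Defaults follow the reference recipe: AdamW, learning rate 0.001, batch
#' size 2, inputs 256x256, checkpoint at the lowest validation loss. The
#' full-scale recipe prescribes 20000 iterations on a GPU; `iterations` here
#' defaults to a desk-scale count suitable for a single CPU and should be
#' raised for full-scale runs.
#'
#' @param input_size side length of (square) training inputs, pixels.
#' @param learning_rate AdamW step size.
#' @param iterations number of optimisation steps.
#' @param batch_size samples per step.
#' @param loss `"multi_bce"` (sum of BCE over all side outputs plus the fused
#'   output; required for the `uiu` variant) or `"bce"`.
#' @param weight_decay decoupled weight decay coefficient.
#' @param val_every validation-loss evaluation period, in iterations.
#' @param seed integer seed controlling initialisation and batch sampling.
#' @return an object of class `usn_train_config`.
#' @export
train_config <- function(input_size = 256L, learning_rate = 0.001,
                         iterations = 2000L, batch_size = 2L,
                         loss = c("multi_bce", "bce"), weight_decay = 0.01,
                         val_every = 200L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(input_size > 0, learning_rate > 0, iterations > 0, batch_size > 0,
            weight_decay >= 0, val_every > 0)
  structure(list(input_size = as.integer(input_size),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), loss = loss,
                 weight_decay = weight_decay, val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "usn_train_config")
}

#' Multi-output binary cross-entropy
#'
#' Sum, with equal weights, of the pixel-mean binary cross-entropy of every
#' side-output probability map and of the fused map against a binary target.
#' With no side outputs this reduces to plain BCE.
#'
#' @param side_outputs list (possibly empty) of probability arrays in (0,1).
#' @param fused fused probability array.
#' @param target binary array (0/1 or logical) of the same shape.
#' @return scalar loss.
#' @export
multi_bce_loss <- function(side_outputs, fused, target) {
  maps <- c(side_outputs, list(fused))
  if (!is.null(dim(target)) && !identical(dim(target), dim(fused))) {
    stop("prediction/target shape mismatch")
  }
  tgt <- array(as.numeric(target), dim = dim(fused))
  eps <- 1e-7
  sum(vapply(maps, function(p) {
    if (!identical(dim(p), dim(tgt))) stop("prediction/target shape mismatch")
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(tgt * log(p) + (1 - tgt) * log(1 - p))
  }, numeric(1)))
}

# One AdamW step over all parameters carrying a gradient.
adamw_step <- function(params, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, t = 1L) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) {
      p$m <- array(0, dim(p$val))
      p$v <- array(0, dim(p$val))
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$val <- p$val - lr * (mhat / (sqrt(vhat) + eps) + wd * p$val)
    p$grad <- NULL
  }
  invisible(NULL)
}

model_weights <- function(model) lapply(model$params, function(p) p$val)

set_model_weights <- function(model, weights) {
  stopifnot(length(weights) == length(model$params))
  for (i in seq_along(weights)) model$params[[i]]$val <- weights[[i]]
  invisible(model)
}

# Assemble a (H,W,1,B) batch from a list of matrices.
stack_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(imgs)))
  for (i in seq_along(imgs)) out[, , 1L, i] <- imgs[[i]]
  out
}

forward_loss <- function(model, xb, yb, train = TRUE) {
  out <- model$fwd(ag_const(xb), train = train)
  terms <- lapply(c(out$side, list(out$fused)), op_bce_logits, target = yb)
  list(loss = op_sum_scalars(terms), out = out)
}

# Resolve a manifest (data frame with path_us/path_mask/split columns) or an
# in-memory dataset (list with elements us/mask/split) into per-split sample
# lists of list(us = matrix, mask = 0/1 matrix).
resolve_dataset <- function(dataset) {
  if (is.data.frame(dataset)) {
    samples <- lapply(seq_len(nrow(dataset)), function(i) {
      list(us = read_pgm(dataset$path_us[i]),
           mask = read_pgm(dataset$path_mask[i]) > 0.5)
    })
    split <- dataset$split
  } else {
    samples <- lapply(dataset$pairs, function(p) {
      list(us = p$us_image$values, mask = p$pa_mask$pixels)
    })
    split <- dataset$split
  }
  list(train = samples[split == "train"], val = samples[split == "val"],
       test = samples[split == "test"])
}

#' Train a needle-segmentation network
#'
#' Seeded AdamW training with periodic validation; the returned checkpoint
#' carries the weights with the lowest validation loss seen, the full loss
#' log, and echoes of the network spec and training configuration.
#'
#' @param model a `usn_model` from [build_network()].
#' @param dataset manifest data frame (columns `path_us`, `path_mask`,
#'   `split`) or an in-memory dataset from [simulate_dataset()].
#' @param cfg a [train_config()].
#' @param log_file optional CSV path receiving the loss log.
#' @param verbose print progress lines.
#' @return an object of class `usn_checkpoint`.
#' @export
train_network <- function(model, dataset, cfg = train_config(),
                          log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "usn_model"), inherits(cfg, "usn_train_config"))
  ds <- resolve_dataset(dataset)
  if (length(ds$train) == 0L || length(ds$val) == 0L) {
    stop("dataset must provide non-empty train and val splits")
  }
  d1 <- dim(ds$train[[1]]$us)
  check_input_size(model, d1)
  if (model$spec$variant == "uiu" && cfg$loss != "multi_bce") {
    stop("variant 'uiu' requires the multi_bce loss")
  }
  # validation in chunks to bound peak memory
  val_chunks <- split(seq_along(ds$val), ceiling(seq_along(ds$val) / 8))
  val_loss <- function() {
    tot <- 0
    for (ch in val_chunks) {
      xb <- stack_batch(lapply(ds$val[ch], `[[`, "us"))
      yb <- stack_batch(lapply(ds$val[ch], function(s) s$mask * 1))
      tot <- tot + length(ch) * forward_loss(model, xb, yb, train = FALSE)$loss$val[1L]
    }
    tot / length(ds$val)
  }
  log <- data.frame(iteration = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(loss = Inf, iter = NA_integer_, weights = NULL)
  withr::with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      idx <- sample.int(length(ds$train), cfg$batch_size, replace = TRUE)
      xb <- stack_batch(lapply(ds$train[idx], `[[`, "us"))
      yb <- stack_batch(lapply(ds$train[idx], function(s) s$mask * 1))
      fl <- forward_loss(model, xb, yb, train = TRUE)
      if (!is.finite(fl$loss$val[1L])) {
        stop(sprintf("non-finite training loss at iteration %d", it))
      }
      ag_backward(fl$loss)
      adamw_step(model$params, cfg$learning_rate, cfg$weight_decay, t = it)
      if (it %% cfg$val_every == 0L || it == cfg$iterations) {
        vl <- val_loss()
        log <- rbind(log, data.frame(iteration = it,
                                     train_loss = fl$loss$val[1L],
                                     val_loss = vl))
        if (vl < best$loss) {
          best <- list(loss = vl, iter = it, weights = model_weights(model))
        }
        if (verbose) {
          message(sprintf("iter %6d  train %.4f  val %.4f", it,
                          fl$loss$val[1L], vl))
        }
      }
    }
  })
  set_model_weights(model, best$weights)
  if (!is.null(log_file)) utils::write.csv(log, log_file, row.names = FALSE)
  structure(list(spec = model$spec, config = cfg,
                 weights = best$weights,
                 best_val_loss = best$loss, iteration_of_best = best$iter,
                 log = log),
            class = "usn_checkpoint")
}

#' @export
print.usn_checkpoint <- function(x, ...) {
  cat(sprintf("<usn_checkpoint> %s, best val loss %.4f at iteration %d\n",
              x$spec$variant, x$best_val_loss, x$iteration_of_best))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' The checkpoint is one serialized file holding the network spec, training
#' configuration, best weights, and the loss log.
#' @param ckpt a `usn_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "usn_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "usn_checkpoint")) stop("not a usn_checkpoint file")
  ckpt
}

# Rebuild a model carrying a checkpoint's weights. Initialisation randomness
# is irrelevant here because every parameter is overwritten.
model_from_checkpoint <- function(ckpt) {
  model <- withr::with_seed(1L, build_network(ckpt$spec))
  set_model_weights(model, ckpt$weights)
  model
}

# Reflect-pad a matrix up to target size (bottom/right), returning the padded
# matrix; used to reach an admissible network input size.
pad_reflect <- function(m, H, W) {
  d <- dim(m)
  if (d[1] == H && d[2] == W) return(m)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(H)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(W)]
  m[ri, ci, drop = FALSE]
}

#' Predict a needle mask for one ultrasound image
#'
#' Runs the fused output of a trained network on a B-mode image (padded by
#' reflection to the nearest admissible size and cropped back), returning the
#' probability map and its thresholded binary mask.
#'
#' @param ckpt a `usn_checkpoint` or a live `usn_model`.
#' @param us_image a `usn_bscan` or numeric matrix in `[0, 1]`.
#' @param binarize_threshold probability threshold for the mask.
#' @return list with `mask` (a `usn_mask`) and `prob` (matrix in (0,1)).
#' @export
predict_needle <- function(ckpt, us_image, binarize_threshold = 0.5) {
  model <- if (inherits(ckpt, "usn_checkpoint")) {
    model_from_checkpoint(ckpt)
  } else {
    stopifnot(inherits(ckpt, "usn_model"))
    ckpt
  }
  img <- if (inherits(us_image, "usn_bscan")) us_image$values else us_image
  stopifnot(is.matrix(img))
  d <- dim(img)
  Hp <- ceiling(d[1] / model$divisor) * model$divisor
  Wp <- ceiling(d[2] / model$divisor) * model$divisor
  if (Hp > 2 * d[1] || Wp > 2 * d[2]) {
    stop(sprintf("image %dx%d too small for this network (needs >= %d/2 per side)",
                 d[1], d[2], model$divisor))
  }
  xb <- array(pad_reflect(img, Hp, Wp), c(Hp, Wp, 1L, 1L))
  out <- model$fwd(ag_const(xb), train = FALSE)
  prob <- 1 / (1 + exp(-out$fused$val[, , 1L, 1L]))
  prob <- prob[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  list(mask = needle_mask(prob >= binarize_threshold), prob = prob)
}
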