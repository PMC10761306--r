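#' Default pipeline configuration
#'
#' A single nested configuration covering every stage: simulation,
#' PA-ground-truth preprocessing, network spec and training, and metric
#' options. Numeric defaults that the reference recipe prints (learning rate
#' 0.001, batch size 2, 80:10:10 split) are kept; capacity and iteration
#' defaults are desk-scale.
#'
#' @param seed global seed propagated to every stage.
#' @return nested list, ready for [run_pipeline()] (or to serialise as JSON).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(n = 60L, image_size = c(64L, 64L),
                      split = c(0.8, 0.1, 0.1)),
    preprocessing = list(method = "otsu", connectivity = 8L,
                         policy = "largest"),
    network = list(variant = "uiu", n_scales = 4L, inner_depths = c(3L, 2L),
                   base_channels = 8L),
    training = list(learning_rate = 0.001, iterations = 150L, batch_size = 2L,
                    val_every = 50L),
    metrics = list(overlap_threshold = 0.3, pass_tol = 1, point_set = "mask"),
    binarize_threshold = 0.5
  )
}

stage_hash <- function(paths) {
  paths <- paths[file.exists(paths)]
  unname(tools::md5sum(sort(paths)))
}

log_line <- function(run_dir, ...) {
  cat(sprintf(...), "\n", sep = "", file = file.path(run_dir, "pipeline.log"),
      append = TRUE)
}

#' Run the end-to-end pipeline
#'
#' simulate -> PA ground truth -> train -> predict -> evaluate, writing every
#' stage's outputs plus a log with parameters and content hashes into
#' `run_dir`. With `resume = TRUE` a stage whose completion marker exists is
#' skipped. Any stage failure stops with the stage name in the message.
#'
#' @param config nested list as from [default_pipeline_config()] (or a JSON
#'   path readable by [read_config()]); missing entries take defaults.
#' @param run_dir output directory.
#' @param resume skip stages already completed in `run_dir`.
#' @param verbose print stage progress.
#' @return `run_dir`, invisibly; the metrics report is at
#'   `evaluation/report.csv` and returned as attribute `"report"`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), run_dir,
                         resume = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- function(stage) file.path(run_dir, paste0(".done_", stage))
  run_stage <- function(stage, fn) {
    if (resume && file.exists(marker(stage))) {
      if (verbose) message(sprintf("[%s] skipped (resume)", stage))
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    writeLines(format(Sys.time()), marker(stage))
    res
  }

  data_dir <- file.path(run_dir, "data")
  gt_dir <- file.path(run_dir, "ground_truth")
  pred_dir <- file.path(run_dir, "predictions")
  eval_dir <- file.path(run_dir, "evaluation")

  run_stage("simulate", function() {
    scfg <- do.call(sim_config, c(config$simulation[
      intersect(names(config$simulation), names(formals(sim_config)))],
      list(seed = config$seed)))
    ds <- simulate_dataset(scfg, config$simulation$n,
                           split = config$simulation$split, outdir = data_dir)
    log_line(run_dir, "simulate: n=%d size=%dx%d hash=%s", config$simulation$n,
             scfg$image_size[1], scfg$image_size[2],
             stage_hash(file.path(data_dir, "manifest.csv")))
  })

  run_stage("make_gt", function() {
    man <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    dir.create(gt_dir, showWarnings = FALSE)
    man$path_gt <- NA_character_
    man$gt_flag <- NA_character_
    for (i in seq_len(nrow(man))) {
      pa <- read_pgm(man$path_pa[i])
      m <- preprocess_pa(pa, config$preprocessing)
      p <- file.path(gt_dir, sprintf("gt_%04d.pgm", i))
      write_pgm(m$pixels, p)
      man$path_gt[i] <- p
      man$gt_flag[i] <- if (is.null(m$flag)) "ok" else m$flag
    }
    utils::write.csv(man, file.path(gt_dir, "manifest.csv"), row.names = FALSE)
    log_line(run_dir, "make_gt: %d masks, %d flagged, hash=%s", nrow(man),
             sum(!man$gt_flag %in% "ok"),
             stage_hash(file.path(gt_dir, "manifest.csv")))
  })

  run_stage("train", function() {
    man <- utils::read.csv(file.path(gt_dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    # flagged (needle-free) frames are excluded from training pairs
    man_tr <- man[man$gt_flag %in% "ok" | man$split == "test", ]
    manifest <- data.frame(path_us = man_tr$path_us,
                           path_mask = man_tr$path_gt, split = man_tr$split)
    nspec <- do.call(network_spec, config$network[
      intersect(names(config$network), names(formals(network_spec)))])
    tcfg_args <- config$training[
      intersect(names(config$training), names(formals(train_config)))]
    tcfg_args$seed <- config$seed
    tcfg_args$loss <- if (nspec$variant == "uiu") "multi_bce" else "bce"
    tcfg <- do.call(train_config, tcfg_args)
    model <- withr::with_seed(config$seed, build_network(nspec))
    ckpt <- train_network(model, manifest, tcfg,
                          log_file = file.path(run_dir, "training_log.csv"),
                          verbose = verbose)
    save_checkpoint(ckpt, file.path(run_dir, "checkpoint.rds"))
    log_line(run_dir, "train: variant=%s best_val=%.5f at iter=%d hash=%s",
             nspec$variant, ckpt$best_val_loss, ckpt$iteration_of_best,
             stage_hash(file.path(run_dir, "training_log.csv")))
  })

  run_stage("predict", function() {
    man <- utils::read.csv(file.path(gt_dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    ckpt <- load_checkpoint(file.path(run_dir, "checkpoint.rds"))
    model <- model_from_checkpoint(ckpt)
    dir.create(pred_dir, showWarnings = FALSE)
    test_idx <- which(man$split == "test")
    man$path_pred <- NA_character_
    for (i in test_idx) {
      us <- read_pgm(man$path_us[i])
      pred <- predict_needle(model, us,
                             binarize_threshold = config$binarize_threshold)
      p <- file.path(pred_dir, sprintf("pred_%04d.pgm", i))
      write_pgm(pred$mask$pixels, p)
      man$path_pred[i] <- p
    }
    utils::write.csv(man[test_idx, ], file.path(pred_dir, "manifest.csv"),
                     row.names = FALSE)
    log_line(run_dir, "predict: %d test images hash=%s", length(test_idx),
             stage_hash(file.path(pred_dir, "manifest.csv")))
  })

  report <- run_stage("evaluate", function() {
    man <- utils::read.csv(file.path(pred_dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    preds <- lapply(man$path_pred, function(p) needle_mask(read_pgm(p) > 0.5))
    gts <- lapply(man$path_mask, function(p) needle_mask(read_pgm(p) > 0.5))
    rep <- evaluate_dataset(preds, gts, config$metrics)
    dir.create(eval_dir, showWarnings = FALSE)
    write_metrics_report(rep, file.path(eval_dir, "report.csv"))
    log_line(run_dir, "evaluate: NLSR=%.2f%% hash=%s", rep$nlsr,
             stage_hash(file.path(eval_dir, "report.csv")))
    rep
  })
  if (is.null(report) && file.exists(file.path(eval_dir, "report.csv"))) {
    report <- utils::read.csv(file.path(eval_dir, "report.csv"))
  }
  out <- run_dir
  attr(out, "report") <- report
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `make-gt`, `train`, `predict`, `evaluate`, `run`.
#' `run` executes the full pipeline from a JSON config; the others are thin
#' wrappers over the corresponding stage functions. Invoked by the
#' `inst/cli/usneedle` launcher script.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: usneedle <simulate|make-gt|train|predict|evaluate|run> [options]"
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  getopt <- function(spec) {
    parser <- optparse::OptionParser(option_list = spec)
    optparse::parse_args(parser, args = rest)
  }
  o <- optparse::make_option
  switch(cmd,
    "run" = {
      opt <- getopt(list(
        o("--config", type = "character", default = NULL),
        o("--out", type = "character", default = "run"),
        o("--seed", type = "integer", default = 1L),
        o("--resume", action = "store_true", default = FALSE)))
      cfg <- if (is.null(opt$config)) default_pipeline_config(opt$seed) else opt$config
      run_pipeline(cfg, run_dir = opt$out, resume = opt$resume, verbose = TRUE)
    },
    "simulate" = {
      opt <- getopt(list(
        o("--n", type = "integer", default = 60L),
        o("--size", type = "integer", default = 64L),
        o("--seed", type = "integer", default = 1L),
        o("--out", type = "character", default = "simdata")))
      cfg <- sim_config(image_size = c(opt$size, opt$size), seed = opt$seed)
      simulate_dataset(cfg, opt$n, outdir = opt$out)
    },
    "make-gt" = {
      opt <- getopt(list(
        o("--in", type = "character", dest = "input"),
        o("--out", type = "character", default = "gt.pgm")))
      m <- preprocess_pa(read_pgm(opt$input))
      write_pgm(m$pixels, opt$out)
    },
    "train" = {
      opt <- getopt(list(
        o("--manifest", type = "character"),
        o("--variant", type = "character", default = "uiu"),
        o("--iterations", type = "integer", default = 500L),
        o("--seed", type = "integer", default = 1L),
        o("--out", type = "character", default = "checkpoint.rds")))
      man <- utils::read.csv(opt$manifest, stringsAsFactors = FALSE)
      spec <- network_spec(opt$variant)
      model <- withr::with_seed(opt$seed, build_network(spec))
      cfg <- train_config(iterations = opt$iterations, seed = opt$seed,
                          loss = if (opt$variant == "uiu") "multi_bce" else "bce")
      save_checkpoint(train_network(model, man, cfg, verbose = TRUE), opt$out)
    },
    "predict" = {
      opt <- getopt(list(
        o("--ckpt", type = "character"),
        o("--in", type = "character", dest = "input"),
        o("--out", type = "character", default = "pred.pgm")))
      pred <- predict_needle(load_checkpoint(opt$ckpt), read_pgm(opt$input))
      write_pgm(pred$mask$pixels, opt$out)
    },
    "evaluate" = {
      opt <- getopt(list(
        o("--pred-dir", type = "character", dest = "pred_dir"),
        o("--gt-dir", type = "character", dest = "gt_dir"),
        o("--out", type = "character", default = "report.csv")))
      pf <- sort(list.files(opt$pred_dir, pattern = "\\.pgm$", full.names = TRUE))
      gf <- sort(list.files(opt$gt_dir, pattern = "\\.pgm$", full.names = TRUE))
      rep <- evaluate_dataset(lapply(pf, function(p) needle_mask(read_pgm(p) > 0.5)),
                              lapply(gf, function(p) needle_mask(read_pgm(p) > 0.5)))
      print(rep)
      write_metrics_report(rep, opt$out)
    },
    {
      message(usage)
      return(invisible(1L))
    })
  invisible(0L)
}
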