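#' Simulator configuration
#'
#' Parameters of the paired US/PA simulator of in-plane needle insertion.
#' The generator emulates what the dual-modal acquisition produces: a
#' speckle-laden B-mode image in which the needle echo weakens with
#' insertion angle and depth and suffers segment dropout and reverberation
#' ghosts, alongside a high-contrast PA frame in which the needle band is
#' bright and clean but accompanied by absorber-artifact blobs. Defaults are
#' fixed, field-realistic choices documented in the methods vignette.
#'
#' @param image_size `(H, W)` pixels.
#' @param angle_range insertion angle range, degrees from horizontal.
#' @param depth_range needle-tip depth range, fraction of image height.
#' @param length_frac_range needle length range, fraction of image width.
#' @param gauges candidate needle gauges; thickness is looked up in
#'   `thickness_by_gauge`.
#' @param thickness_by_gauge named vector mapping gauge to band thickness px.
#' @param needle_dropout per-segment probability of echo dropout in US.
#' @param dropout_segment_len segment length for dropout, px of arclength.
#' @param speckle_scale Rayleigh scale of the background speckle envelope.
#' @param needle_amp peak needle echo amplitude (envelope units).
#' @param angle_falloff_power needle echo falls off as `cos(angle)^power`.
#' @param depth_attenuation exponential depth attenuation rate (per image
#'   height).
#' @param ghost_max maximum number of reverberation ghost lines.
#' @param ghost_offsets row offsets of ghost lines below the needle, px.
#' @param ghost_frac ghost amplitude as a fraction of the needle amplitude.
#' @param pa_artifact_count number of PA absorber blobs.
#' @param pa_artifact_radius blob radius, px.
#' @param pa_artifact_amp amplitude range of blobs (below the needle's 1.0).
#' @param pa_noise Rayleigh scale of the PA noise floor.
#' @param dynamic_range log-compression dynamic range, dB.
#' @param margin minimum distance of needle endpoints from image borders, px.
#' @param seed master seed; every pair derives its own stream from it.
#' @return an object of class `usn_sim_config`.
#' @export
sim_config <- function(image_size = c(256L, 256L), angle_range = c(10, 45),
                       depth_range = c(0.35, 0.8),
                       length_frac_range = c(0.35, 0.75),
                       gauges = c(18L, 23L),
                       thickness_by_gauge = c("18" = 3, "23" = 2),
                       needle_dropout = 0.25, dropout_segment_len = 12,
                       speckle_scale = 0.12, needle_amp = 1.0,
                       angle_falloff_power = 1.5, depth_attenuation = 0.5,
                       ghost_max = 2L, ghost_offsets = c(7L, 13L),
                       ghost_frac = 0.35, pa_artifact_count = 3L,
                       pa_artifact_radius = 4, pa_artifact_amp = c(0.3, 0.7),
                       pa_noise = 0.02, dynamic_range = 50, margin = 8L,
                       seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32L),
            diff(angle_range) >= 0, diff(depth_range) >= 0,
            diff(length_frac_range) >= 0,
            needle_dropout >= 0, needle_dropout <= 1,
            all(thickness_by_gauge >= 1), speckle_scale >= 0,
            ghost_frac >= 0, ghost_frac <= 1, pa_artifact_count >= 0)
  if (!all(as.character(gauges) %in% names(thickness_by_gauge))) {
    stop("every gauge needs an entry in thickness_by_gauge")
  }
  cfg <- as.list(environment())
  cfg$image_size <- as.integer(image_size)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "usn_sim_config")
}

# Distance from every pixel (0-based row, col grid) to a segment p1-p2, plus
# the arclength parameter of the projection (clamped to the segment).
segment_distance_field <- function(H, W, p1, p2) {
  rows <- matrix(rep(0:(H - 1L), W), H, W)
  cols <- matrix(rep(0:(W - 1L), each = H), H, W)
  d <- p2 - p1
  len2 <- sum(d^2)
  t <- ((rows - p1[1]) * d[1] + (cols - p1[2]) * d[2]) / len2
  tc <- pmin(pmax(t, 0), 1)
  pr <- p1[1] + tc * d[1]
  pc <- p1[2] + tc * d[2]
  list(dist = sqrt((rows - pr)^2 + (cols - pc)^2), s = tc * sqrt(len2))
}

rayleigh <- function(n, sigma) sigma * sqrt(-2 * log(runif(n)))

#' Simulate one paired US/PA frame
#'
#' Draws needle geometry (angle, depth, gauge, length, entry side) from the
#' configured ranges, renders the B-mode image (log-compressed Rayleigh
#' speckle plus an anti-aliased needle echo with angle/depth falloff,
#' Bernoulli segment dropout and parallel reverberation ghosts), the PA
#' envelope (clean bright needle band plus absorber blobs kept clear of the
#' needle, plus a noise floor) and the exact binary ground-truth band.
#' Geometry that cannot be placed inside the frame is resampled a bounded
#' number of times before the configuration is rejected.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for this pair (default `cfg$seed`); the same seed
#'   reproduces the pair bit for bit.
#' @return an object of class `usn_simpair`: `us_image` ([bscan_image()]),
#'   `pa_image` ([envelope_image()]), `pa_mask` ([needle_mask()]),
#'   `true_line` ([needle_line()]), `meta`.
#' @export
simulate_pair <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "usn_sim_config"))
  withr::with_seed(as.integer(seed), simulate_pair_impl(cfg, seed))
}

simulate_pair_impl <- function(cfg, seed) {
  H <- cfg$image_size[1]
  W <- cfg$image_size[2]
  mar <- cfg$margin
  geom <- NULL
  for (try in seq_len(25L)) {
    angle <- runif(1, cfg$angle_range[1], cfg$angle_range[2])
    depth <- runif(1, cfg$depth_range[1], cfg$depth_range[2])
    len <- runif(1, cfg$length_frac_range[1], cfg$length_frac_range[2]) * W
    gauge <- if (length(cfg$gauges) == 1L) cfg$gauges else sample(cfg$gauges, 1L)
    side <- sample(c(-1, 1), 1L)  # entry from left (+1) or right (-1)
    th <- angle * pi / 180
    tip_row <- depth * H
    tip_col <- runif(1, mar, W - 1 - mar)
    base_row <- tip_row - len * sin(th)
    base_col <- tip_col - side * len * cos(th)
    ok <- base_row >= mar && base_row <= H - 1 - mar &&
      base_col >= mar && base_col <= W - 1 - mar &&
      tip_row <= H - 1 - mar
    if (ok) {
      geom <- list(angle = angle, depth = depth, gauge = gauge, len = len,
                   tip = c(tip_row, tip_col), base = c(base_row, base_col))
      break
    }
  }
  if (is.null(geom)) {
    stop("could not place a needle inside the frame; configuration rejected")
  }
  thick <- cfg$thickness_by_gauge[[as.character(geom$gauge)]]
  fld <- segment_distance_field(H, W, geom$base, geom$tip)
  band_aa <- pmin(pmax(thick / 2 + 0.5 - fld$dist, 0), 1)  # anti-aliased
  hard_band <- fld$dist <= thick / 2

  # --- US image ---------------------------------------------------------------
  amp <- cfg$needle_amp * cos(geom$angle * pi / 180)^cfg$angle_falloff_power
  rowfrac <- matrix(rep(0:(H - 1L) / H, W), H, W)
  needle_amp_px <- amp * exp(-cfg$depth_attenuation * rowfrac)
  n_seg <- max(1L, ceiling(geom$len / cfg$dropout_segment_len))
  dropped <- runif(n_seg) < cfg$needle_dropout
  seg_of_px <- pmin(floor(fld$s / cfg$dropout_segment_len) + 1L, n_seg)
  keep <- matrix(!dropped[seg_of_px], H, W)
  needle_sig <- needle_amp_px * band_aa * ifelse(keep, 1, 0.1)
  env <- matrix(rayleigh(H * W, cfg$speckle_scale), H, W) + needle_sig
  n_ghost <- if (cfg$ghost_max > 0L) sample(0:cfg$ghost_max, 1L) else 0L
  if (n_ghost > 0L) {
    for (k in seq_len(n_ghost)) {
      off <- cfg$ghost_offsets[(k - 1L) %% length(cfg$ghost_offsets) + 1L]
      gb <- geom$base + c(off, 0)
      gt_ <- geom$tip + c(off, 0)
      if (gt_[1] <= H - 1) {
        gf <- segment_distance_field(H, W, gb, gt_)
        gaa <- pmin(pmax(thick / 2 + 0.5 - gf$dist, 0), 1)
        env <- env + cfg$ghost_frac * needle_amp_px * gaa
      }
    }
  }
  us <- log_compress(env, cfg$dynamic_range)

  # --- PA image and ground truth ---------------------------------------------
  pa <- matrix(rayleigh(H * W, cfg$pa_noise), H, W)
  # small PSF shoulder outside the hard band, well below any plausible
  # threshold so the recovered mask stays the hard band
  shoulder <- ifelse(hard_band, 0,
                     0.12 * exp(-((fld$dist - thick / 2) / 0.5)^2))
  pa <- pa + hard_band * 1.0 + shoulder
  if (cfg$pa_artifact_count > 0L) {
    rows <- matrix(rep(0:(H - 1L), W), H, W)
    cols <- matrix(rep(0:(W - 1L), each = H), H, W)
    placed <- 0L
    for (try in seq_len(50L)) {
      if (placed >= cfg$pa_artifact_count) break
      cr <- runif(1, mar, H - 1 - mar)
      cc <- runif(1, mar, W - 1 - mar)
      # distance of blob centre from the needle segment
      dctr <- {
        d <- geom$tip - geom$base
        t <- ((cr - geom$base[1]) * d[1] + (cc - geom$base[2]) * d[2]) / sum(d^2)
        t <- pmin(pmax(t, 0), 1)
        sqrt((cr - (geom$base[1] + t * d[1]))^2 + (cc - (geom$base[2] + t * d[2]))^2)
      }
      if (dctr < cfg$pa_artifact_radius + 8) next
      a <- runif(1, cfg$pa_artifact_amp[1], cfg$pa_artifact_amp[2])
      pa <- pa + a * exp(-((rows - cr)^2 + (cols - cc)^2) /
                           (2 * (cfg$pa_artifact_radius / 2)^2))
      placed <- placed + 1L
    }
  }
  structure(list(
    us_image = us,
    pa_image = envelope_image(pa),
    pa_mask = needle_mask(hard_band),
    true_line = needle_line(geom$tip, geom$base),
    meta = list(angle = geom$angle, depth = geom$depth, gauge = geom$gauge,
                length = geom$len, echo_amp = amp, seed = as.integer(seed))),
    class = "usn_simpair")
}

# floor-based split sizes, remainder to train
split_sizes <- function(n, split) {
  n_val <- floor(split[2] * n)
  n_test <- floor(split[3] * n)
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

#' Simulate a dataset with train/val/test splits
#'
#' Generates `n` independent pairs (each from its own seed derived from
#' `cfg$seed`) and assigns splits by the given ratios: split sizes are
#' floor-based with the remainder going to train.
#'
#' @param cfg a [sim_config()].
#' @param n number of pairs (>= 10).
#' @param split `(train, val, test)` ratios summing to 1.
#' @param outdir optional directory; when given, US/PA/mask images are
#'   written as PGM files and a `manifest.csv` (columns `path_us`,
#'   `path_mask`, `path_pa`, `split`, `angle`, `depth`, `gauge`, `seed`) is
#'   written alongside.
#' @return an object of class `usn_dataset`: `pairs` (list of
#'   `usn_simpair`), `split` (character vector), `manifest` (data frame).
#' @export
simulate_dataset <- function(cfg, n, split = c(0.8, 0.1, 0.1), outdir = NULL) {
  stopifnot(inherits(cfg, "usn_sim_config"), n >= 10L)
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-9) {
    stop("split must be three non-negative ratios summing to 1")
  }
  n <- as.integer(n)
  sz <- split_sizes(n, split)
  n_train <- sz[1]
  n_val <- sz[2]
  n_test <- sz[3]
  seeds <- withr::with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, n))
  pairs <- lapply(seeds, function(s) simulate_pair(cfg, seed = s))
  split_vec <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  manifest <- data.frame(
    path_us = NA_character_, path_mask = NA_character_, path_pa = NA_character_,
    split = split_vec,
    angle = vapply(pairs, function(p) p$meta$angle, numeric(1)),
    depth = vapply(pairs, function(p) p$meta$depth, numeric(1)),
    gauge = vapply(pairs, function(p) p$meta$gauge, numeric(1)),
    seed = seeds)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      us_p <- file.path(outdir, sprintf("us_%04d.pgm", i))
      mk_p <- file.path(outdir, sprintf("mask_%04d.pgm", i))
      pa_p <- file.path(outdir, sprintf("pa_%04d.pgm", i))
      write_pgm(pairs[[i]]$us_image$values, us_p, maxval = 65535L)
      write_pgm(pairs[[i]]$pa_mask$pixels, mk_p)
      write_pgm(pmin(pairs[[i]]$pa_image$values / max(pairs[[i]]$pa_image$values), 1),
                pa_p, maxval = 65535L)
      manifest$path_us[i] <- us_p
      manifest$path_mask[i] <- mk_p
      manifest$path_pa[i] <- pa_p
    }
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(pairs = pairs, split = split_vec, manifest = manifest),
            class = "usn_dataset")
}

#' Write the canonical unit-test fixture suite
#'
#' Produces the small deterministic fixtures the tests use — a noiseless
#' US/PA pair, a blob-only PA frame (no needle), a two-component tie-area
#' mask, and an empty frame — as ASCII PGM files, with an md5 checksum
#' manifest.
#'
#' @param outdir writable directory.
#' @return data frame of files and checksums (also written as
#'   `checksums.csv`).
#' @export
make_fixture_suite <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(image_size = c(64L, 64L), speckle_scale = 0,
                    needle_dropout = 0, ghost_max = 0L,
                    pa_artifact_count = 0L, pa_noise = 0, seed = 7L)
  pair <- simulate_pair(cfg)
  write_pgm(pair$us_image$values, file.path(outdir, "noiseless_us.pgm"),
            ascii = TRUE)
  write_pgm(pair$pa_mask$pixels, file.path(outdir, "noiseless_mask.pgm"),
            ascii = TRUE)
  blob <- matrix(0, 64, 64)
  rows <- matrix(rep(0:63, 64), 64, 64)
  cols <- matrix(rep(0:63, each = 64), 64, 64)
  for (ctr in list(c(16, 20), c(40, 44))) {
    blob <- blob + 0.8 * exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / 18)
  }
  write_pgm(pmin(blob, 1), file.path(outdir, "blob_only_pa.pgm"), ascii = TRUE)
  tie <- matrix(FALSE, 16, 16)
  tie[3:5, 3:6] <- TRUE    # 12 px
  tie[10:12, 9:12] <- TRUE # 12 px
  write_pgm(tie, file.path(outdir, "tie_components.pgm"), ascii = TRUE)
  write_pgm(matrix(0, 16, 16), file.path(outdir, "empty.pgm"), ascii = TRUE)
  files <- c("noiseless_us.pgm", "noiseless_mask.pgm", "blob_only_pa.pgm",
             "tie_components.pgm", "empty.pgm")
  sums <- tools::md5sum(file.path(outdir, files))
  out <- data.frame(file = files, md5 = unname(sums))
  utils::write.csv(out, file.path(outdir, "checksums.csv"), row.names = FALSE)
  out
}

#' Dice coefficient between two binary masks
#' @param a,b logical matrices or [needle_mask()] objects.
#' @export
dice_coefficient <- function(a, b) {
  pa <- if (inherits(a, "usn_mask")) a$pixels else a
  pb <- if (inherits(b, "usn_mask")) b$pixels else b
  denom <- sum(pa) + sum(pb)
  if (denom == 0) return(1)
  2 * sum(pa & pb) / denom
}
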