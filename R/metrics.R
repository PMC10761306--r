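#' Needle line
#'
#' The tip and base endpoints of a needle segment in 0-based `(row, col)`
#' pixel coordinates, plus the unit direction of the infinite line through
#' them. The tip is the deeper endpoint (larger row = larger axial depth);
#' endpoints are reordered if needed.
#'
#' @param tip,base numeric length-2 vectors `(row, col)`.
#' @return an object of class `usn_line` with `tip`, `base`, `direction`.
#' @export
needle_line <- function(tip, base) {
  tip <- as.numeric(tip)
  base <- as.numeric(base)
  stopifnot(length(tip) == 2L, length(base) == 2L)
  if (all(tip == base)) stop("degenerate line: tip equals base")
  if (tip[1] < base[1]) {
    tmp <- tip
    tip <- base
    base <- tmp
  }
  d <- tip - base
  structure(list(tip = tip, base = base, direction = d / sqrt(sum(d^2))),
            class = "usn_line")
}

#' @export
print.usn_line <- function(x, ...) {
  cat(sprintf("<usn_line> base (%.2f, %.2f) -> tip (%.2f, %.2f), length %.2f px\n",
              x$base[1], x$base[2], x$tip[1], x$tip[2], line_length(x)))
  invisible(x)
}

#' Segment length of a needle line
#' @param line a [needle_line()].
#' @export
line_length <- function(line) sqrt(sum((line$tip - line$base)^2))

mask_points <- function(mask) {
  px <- if (inherits(mask, "usn_mask")) mask$pixels else mask
  which(px, arr.ind = TRUE) - 1  # 0-based (row, col)
}

# Boundary pixels (foreground with a 4-neighbour background), 0-based coords.
mask_edge_points <- function(mask) {
  px <- if (inherits(mask, "usn_mask")) mask$pixels else mask
  H <- nrow(px)
  W <- ncol(px)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- px
  interior <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(px & !interior, arr.ind = TRUE) - 1
}

#' Estimate the needle line from a mask
#'
#' Total-least-squares principal axis of the foreground pixel coordinates;
#' the endpoints are the extreme orthogonal projections of the foreground
#' pixels onto that axis and the tip is the deeper endpoint. An empty or
#' single-pixel mask has no line and returns `NULL` (the caller records a
#' localization failure).
#'
#' @param mask a [needle_mask()] or logical matrix.
#' @return a [needle_line()] or `NULL`.
#' @export
estimate_needle_line <- function(mask) {
  pts <- mask_points(mask)
  if (nrow(pts) < 2L) return(NULL)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen, nu = 0, nv = 2)
  dir <- sv$v[, 1]
  t <- cen %*% dir
  if (max(t) - min(t) < .Machine$double.eps^0.5) return(NULL)  # coincident
  p1 <- ctr + min(t) * dir
  p2 <- ctr + max(t) * dir
  needle_line(p2, p1)
}

#' Directed mean nearest-neighbour distance
#'
#' `d(A, B) = mean over a in A of min over b in B of ||a - b||`.
#' @param A,B numeric matrices of points (rows), same dimensionality.
#' @export
directed_mean_distance <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("point sets must be non-empty")
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  # nearest neighbour per row of A (max.col is the fast C row-argmax), then
  # recompute that one distance in the exact difference form: the expanded
  # form above loses ~1e-8 of precision, which would break zero-on-equality
  j <- max.col(-d2, ties.method = "first")
  mean(sqrt(rowSums((A - B[j, , drop = FALSE])^2)))
}

#' Modified Hausdorff Distance
#'
#' `max(d(A, B), d(B, A))` of the two directed mean nearest-neighbour
#' distances — the robust set-similarity measure used for object matching,
#' in pixel units.
#'
#' @param A,B point matrices, [needle_mask()] objects or logical matrices.
#' @export
mhd <- function(A, B) {
  if (inherits(A, "usn_mask") || is.logical(A)) A <- mask_points(A)
  if (inherits(B, "usn_mask") || is.logical(B)) B <- mask_points(B)
  max(directed_mean_distance(A, B), directed_mean_distance(B, A))
}

# Perpendicular distance from point p (row, col) to the infinite line.
point_line_distance <- function(p, line) {
  v <- as.numeric(p) - line$base
  abs(v[1] * line$direction[2] - v[2] * line$direction[1])
}

#' Localization success test
#'
#' A prediction succeeds iff (1) the estimated needle line passes through the
#' ground truth — at least one ground-truth pixel within `pass_tol` pixels of
#' the line — and (2) the overlap `|S_G intersect S_H|` reaches
#' `overlap_threshold * |S_G|`. An empty prediction or missing line fails.
#'
#' @param gt_mask ground-truth [needle_mask()] (non-empty).
#' @param pred_mask predicted [needle_mask()].
#' @param pred_line the line estimated from the prediction, or `NULL`.
#' @param overlap_threshold required overlap fraction of the ground truth.
#' @param pass_tol perpendicular pass-through tolerance, px.
#' @export
localization_success <- function(gt_mask, pred_mask, pred_line,
                                 overlap_threshold = 0.3, pass_tol = 1) {
  gt <- if (inherits(gt_mask, "usn_mask")) gt_mask$pixels else gt_mask
  pr <- if (inherits(pred_mask, "usn_mask")) pred_mask$pixels else pred_mask
  stopifnot(sum(gt) > 0L)
  if (is.null(pred_line) || sum(pr) == 0L) return(FALSE)
  if (sum(pr & gt) < overlap_threshold * sum(gt)) return(FALSE)
  gpts <- mask_points(gt)
  v <- sweep(gpts, 2, pred_line$base)
  dist <- abs(v[, 1] * pred_line$direction[2] - v[, 2] * pred_line$direction[1])
  any(dist <= pass_tol)
}

#' Targeting error
#'
#' Absolute difference between the perpendicular distances of the true and
#' predicted infinite needle lines to the image centre
#' `((H-1)/2, (W-1)/2)` (0-based pixel coordinates); strongly sensitive to
#' orientation error and symmetric in its arguments.
#'
#' @param true_line,pred_line [needle_line()] objects.
#' @param image_size `(H, W)` in pixels.
#' @export
targeting_error <- function(true_line, pred_line, image_size) {
  ctr <- (image_size - 1) / 2
  abs(point_line_distance(ctr, true_line) - point_line_distance(ctr, pred_line))
}

#' Needle length ratio
#'
#' Predicted tip-to-base Euclidean length divided by the true tip-to-base
#' length; 1 indicates a complete needle prediction.
#' @param pred_line,true_line [needle_line()] objects.
#' @export
needle_length_ratio <- function(pred_line, true_line) {
  lt <- line_length(true_line)
  if (lt <= 0) stop("degenerate true line")
  line_length(pred_line) / lt
}

#' Evaluate a prediction set
#'
#' Per-image success classification followed by success-only scoring: the
#' needle localization success rate (NLSR) is computed over all images, while
#' MHD (between foreground point sets, or edge maps), targeting error and
#' needle length ratio (between total-least-squares needle lines) are
#' computed and summarised (mean, sample sd) over the successful images only.
#'
#' @param pred_masks list of predicted [needle_mask()] objects.
#' @param gt_masks list of ground-truth masks, same length.
#' @param config list: `overlap_threshold` (default 0.3), `pass_tol` (1),
#'   `point_set` (`"mask"` or `"edge"`, default `"mask"`).
#' @return an object of class `usn_metrics_report`: `n_images`, `nlsr`
#'   (percent), `per_image` data frame, `summary` (mean/sd per metric over
#'   successes).
#' @export
evaluate_dataset <- function(pred_masks, gt_masks, config = list()) {
  cfg <- utils::modifyList(list(overlap_threshold = 0.3, pass_tol = 1,
                                point_set = "mask"), config)
  if (length(pred_masks) != length(gt_masks)) {
    stop("pred_masks and gt_masks must have equal length")
  }
  n <- length(pred_masks)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gt <- gt_masks[[i]]
    pr <- pred_masks[[i]]
    gt_line <- estimate_needle_line(gt)
    pr_line <- estimate_needle_line(pr)
    ok <- localization_success(gt, pr, pr_line,
                               overlap_threshold = cfg$overlap_threshold,
                               pass_tol = cfg$pass_tol)
    rec <- data.frame(image = i, success = ok, mhd = NA_real_, te = NA_real_,
                      length_ratio = NA_real_)
    if (ok && !is.null(gt_line)) {
      pts <- if (cfg$point_set == "edge") mask_edge_points else mask_points
      gpx <- if (inherits(gt, "usn_mask")) gt$pixels else gt
      rec$mhd <- mhd(pts(pr), pts(gt))
      rec$te <- targeting_error(gt_line, pr_line, dim(gpx))
      rec$length_ratio <- needle_length_ratio(pr_line, gt_line)
    }
    rows[[i]] <- rec
  }
  per_image <- do.call(rbind, rows)
  succ <- per_image[per_image$success, , drop = FALSE]
  summarise <- function(x) c(mean = mean(x), sd = stats::sd(x))
  structure(list(
    n_images = n,
    nlsr = 100 * nrow(succ) / n,
    per_image = per_image,
    summary = list(mhd = summarise(succ$mhd), te = summarise(succ$te),
                   length_ratio = summarise(succ$length_ratio))),
    class = "usn_metrics_report")
}

#' @export
print.usn_metrics_report <- function(x, ...) {
  cat(sprintf("<usn_metrics_report> %d images\n", x$n_images))
  cat(sprintf("  NLSR               %.2f%%\n", x$nlsr))
  fmt <- function(s) sprintf("%.2f +/- %.2f", s["mean"], s["sd"])
  cat(sprintf("  MHD (px)           %s\n", fmt(x$summary$mhd)))
  cat(sprintf("  Targeting err (px) %s\n", fmt(x$summary$te)))
  cat(sprintf("  Needle length ratio %s\n", fmt(x$summary$length_ratio)))
  cat("  (MHD/TE/length ratio over successful localizations only)\n")
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' Per-image rows plus one summary row with the four headline columns.
#' @param report a `usn_metrics_report`.
#' @param path output CSV path.
#' @export
write_metrics_report <- function(report, path) {
  per <- report$per_image
  summary_row <- data.frame(
    image = NA_integer_, success = NA,
    mhd = report$summary$mhd["mean"], te = report$summary$te["mean"],
    length_ratio = report$summary$length_ratio["mean"])
  out <- rbind(per, summary_row)
  out$nlsr <- c(rep(NA_real_, nrow(per)), report$nlsr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
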