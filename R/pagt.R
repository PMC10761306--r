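#' Binary needle mask
#'
#' Boolean foreground map of the needle, the carrier of both the PA-derived
#' ground truth and network predictions. `flag` marks degenerate results
#' (e.g. an empty mask from a frame without a visible needle) without raising.
#'
#' @param pixels logical matrix.
#' @param flag optional character flag (`"empty"`, `"no_components"`, ...).
#' @return an object of class `usn_mask` with fields `pixels`, `n_foreground`,
#'   `flag`.
#' @export
needle_mask <- function(pixels, flag = NULL) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, n_foreground = sum(pixels), flag = flag),
            class = "usn_mask")
}

#' @export
print.usn_mask <- function(x, ...) {
  cat(sprintf("<usn_mask> %dx%d, %d foreground px%s\n", nrow(x$pixels),
              ncol(x$pixels), x$n_foreground,
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

as_image_matrix <- function(img) {
  v <- if (inherits(img, "usn_bscan") || inherits(img, "usn_envelope")) {
    img$values
  } else {
    img
  }
  stopifnot(is.matrix(v))
  if (!all(is.finite(v)) || any(v < 0)) {
    stop("image must be finite and non-negative")
  }
  v
}

#' Otsu's threshold
#'
#' Maximises between-class variance over a 256-bin histogram of `[0, max]`;
#' returns the threshold value (lower edge of the first foreground bin).
#' @param v non-negative numeric matrix or vector.
#' @param n_bins histogram resolution.
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  m <- max(v)
  if (m == 0) return(0)
  bin <- pmin(floor(v / m * n_bins), n_bins - 1L)   # 0-based bin index
  h <- tabulate(bin + 1L, nbins = n_bins)
  p <- h / sum(h)
  centers <- (seq_len(n_bins) - 0.5) / n_bins * m
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  kstar <- which.max(sigma_b)            # threshold between bin kstar and kstar+1
  kstar / n_bins * m
}

#' Threshold and binarize an image
#'
#' A pixel is foreground iff its value is `>= threshold`. With
#' `method = "otsu"` the threshold comes from [otsu_threshold()]; with
#' `method = "fixed_fraction"` it is `fraction * max(image)`. An all-zero
#' image yields an empty mask flagged `"empty"` (never an error).
#'
#' @param img matrix, [bscan_image()] or [envelope_image()].
#' @param method `"otsu"` or `"fixed_fraction"`.
#' @param fraction fraction of the maximum used when `method = "fixed_fraction"`.
#' @return a [needle_mask()].
#' @export
threshold_binarize <- function(img, method = c("otsu", "fixed_fraction"),
                               fraction = 0.5) {
  method <- match.arg(method)
  v <- as_image_matrix(img)
  if (max(v) == 0) return(needle_mask(v > 0, flag = "empty"))
  thr <- switch(method,
                otsu = otsu_threshold(v),
                fixed_fraction = fraction * max(v))
  needle_mask(v >= thr)
}

#' Connected-component labeling
#'
#' Labels maximal connected foreground regions with positive integers in
#' raster (column-major) discovery order; background is 0.
#'
#' @param mask a [needle_mask()] or logical matrix.
#' @param connectivity 4 or 8 (default 8: needles are thin diagonal
#'   structures).
#' @return list with `labels` (integer matrix) and `areas` (named integer
#'   vector, one entry per label).
#' @export
label_components <- function(mask, connectivity = 8L) {
  px <- if (inherits(mask, "usn_mask")) mask$pixels else mask
  stopifnot(is.matrix(px), is.logical(px), connectivity %in% c(4L, 8L))
  labels <- cpp_label_components(px, as.integer(connectivity))
  n <- max(labels)
  areas <- if (n > 0) tabulate(labels[labels > 0], nbins = n) else integer(0)
  names(areas) <- if (n > 0) as.character(seq_len(n)) else character(0)
  list(labels = labels, areas = areas)
}

#' Keep the large connected component(s)
#'
#' With `policy = "largest"` only the single maximum-area component survives
#' (ties broken by the first label in raster order); with
#' `policy = "area_fraction"` every component with area at least
#' `alpha * max(area)` survives. No components yields an empty mask flagged
#' `"no_components"`.
#'
#' @param labeled output of [label_components()].
#' @param policy `"largest"` or `"area_fraction"`.
#' @param alpha area fraction threshold for `"area_fraction"`.
#' @return a [needle_mask()].
#' @export
select_large_components <- function(labeled, policy = c("largest", "area_fraction"),
                                    alpha = 0.5) {
  policy <- match.arg(policy)
  if (length(labeled$areas) == 0L) {
    return(needle_mask(labeled$labels > 0L, flag = "no_components"))
  }
  keep <- switch(policy,
    largest = which.max(labeled$areas),          # first max in label order
    area_fraction = which(labeled$areas >= alpha * max(labeled$areas)))
  needle_mask(matrix(labeled$labels %in% keep, nrow(labeled$labels)))
}

#' PA preprocessing chain: image to needle ground truth
#'
#' The automated chain used to turn a photoacoustic frame into a binary
#' needle ground-truth mask: thresholding/binarization, connected-component
#' labeling, and large-component selection. Degenerate frames propagate their
#' flag; valid images never raise.
#'
#' @param img PA image (matrix, [envelope_image()] or [bscan_image()]); the
#'   linear envelope and the log-compressed image are both accepted.
#' @param config list of options: `method`, `fraction`, `connectivity`,
#'   `policy`, `alpha` (see the stage functions for meanings and defaults).
#' @return a [needle_mask()].
#' @export
preprocess_pa <- function(img, config = list()) {
  cfg <- utils::modifyList(list(method = "otsu", fraction = 0.5,
                                connectivity = 8L, policy = "largest",
                                alpha = 0.5), config)
  bin <- threshold_binarize(img, method = cfg$method, fraction = cfg$fraction)
  if (!is.null(bin$flag)) return(bin)
  lab <- label_components(bin, connectivity = cfg$connectivity)
  select_large_components(lab, policy = cfg$policy, alpha = cfg$alpha)
}
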