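#' Segmentation network specification
#'
#' Describes one of the four needle-segmentation architectures at a chosen
#' capacity. The default is a desk-scale configuration (4 scales, 8 base
#' channels) trainable on a single CPU; capacity is tunable through
#' `base_channels` and `inner_depths`.
#'
#' @param variant one of `"uiu"` (nested-U network with dilated bottom scales,
#'   interactive-cross attention fusion and deep supervision), `"unet"`,
#'   `"attention_unet"`, `"r2u"`.
#' @param n_scales number of encoder scales (>= 3). A 2x2 max-pool separates
#'   consecutive scales.
#' @param inner_depths for `"uiu"`: internal U-block depth per non-dilated
#'   scale (the bottom two scales always use dilated blocks). Recycled /
#'   truncated to `n_scales - 2`.
#' @param base_channels channel width of the first scale.
#' @param dilation_rates dilation ladder used inside the bottom-scale blocks.
#' @return an object of class `usn_network_spec`.
#' @export
network_spec <- function(variant = c("uiu", "unet", "attention_unet", "r2u"),
                         n_scales = 4L, inner_depths = c(3L, 2L),
                         base_channels = 8L, dilation_rates = c(1L, 2L, 4L)) {
  variant <- match.arg(variant)
  n_scales <- as.integer(n_scales)
  base_channels <- as.integer(base_channels)
  if (n_scales < 3L) stop("n_scales must be >= 3")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  inner_depths <- rep_len(as.integer(inner_depths), n_scales - 2L)
  if (any(inner_depths < 2L)) stop("inner_depths must all be >= 2")
  structure(list(variant = variant, n_scales = n_scales,
                 inner_depths = inner_depths, base_channels = base_channels,
                 dilation_rates = as.integer(dilation_rates)),
            class = "usn_network_spec")
}

# Input side length must be a multiple of this for exact pool/upsample
# round-tripping.
spec_divisor <- function(spec) {
  outer <- 2L^(spec$n_scales - 1L)
  inner <- if (spec$variant == "uiu") 2L^max(spec$inner_depths - 2L, 0L) else 1L
  outer * inner
}

#' Build a segmentation network
#'
#' Instantiates the architecture described by a [network_spec()]. Weights are
#' drawn from the current RNG stream (`set.seed()` before building for
#' reproducible initialisation). All variants share the same contract: a
#' `(H, W, 1, N)` input array in `[0, 1]` yields per-pixel needle logits of
#' identical spatial size; `uiu` additionally yields one side output per
#' decoder level plus the bottom scale, fused by a 1x1 convolution.
#'
#' @param spec a `usn_network_spec`.
#' @return an object of class `usn_model` with elements `spec`, `params`,
#'   `divisor` (admissible input sizes are multiples of it) and the internal
#'   forward closure.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "usn_network_spec"))
  model <- switch(spec$variant,
    uiu = build_uiu(spec),
    unet = build_unet_family(spec, "unet"),
    attention_unet = build_unet_family(spec, "attention_unet"),
    r2u = build_unet_family(spec, "r2u"))
  model$spec <- spec
  model$divisor <- spec_divisor(spec)
  class(model) <- "usn_model"
  model
}

#' @export
print.usn_model <- function(x, ...) {
  cat(sprintf("<usn_model> variant=%s scales=%d base=%d params=%d divisor=%d\n",
              x$spec$variant, x$spec$n_scales, x$spec$base_channels,
              count_params(x), x$divisor))
  invisible(x)
}

#' Number of trainable scalars in a model
#' @param model a `usn_model`.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$val), numeric(1)))
}

check_input_size <- function(model, d) {
  if (d[1] %% model$divisor != 0L || d[2] %% model$divisor != 0L) {
    stop(sprintf(
      "input %dx%d incompatible with this network: both sides must be multiples of %d (minimum admissible size %dx%d)",
      d[1], d[2], model$divisor, model$divisor, model$divisor))
  }
}

build_uiu <- function(spec) {
  s <- spec$n_scales
  B <- spec$base_channels
  mid1 <- max(2L, B %/% 2L)
  cout <- c(B, rep(2L * B, s - 1L))          # encoder output channels
  mid <- c(mid1, rep(B, s - 1L))
  enc <- vector("list", s)
  for (i in seq_len(s)) {
    cin <- if (i == 1L) 1L else cout[i - 1L]
    enc[[i]] <- if (i >= s - 1L) {
      nn_rsuf(cin, mid[i], cout[i], spec$dilation_rates)
    } else {
      nn_rsu(spec$inner_depths[i], cin, mid[i], cout[i])
    }
  }
  dout <- cout                                # decoder output channels
  ups <- vector("list", s - 1L)
  ica <- vector("list", s - 1L)
  dec <- vector("list", s - 1L)
  for (i in seq_len(s - 1L)) {
    src <- if (i == s - 1L) cout[s] else dout[i + 1L]
    ups[[i]] <- nn_convt2(src, cout[i])
    ica[[i]] <- nn_ica(cout[i])
    dec[[i]] <- if (i >= s - 1L) {
      nn_rsuf(2L * cout[i], mid[i], dout[i], spec$dilation_rates)
    } else {
      nn_rsu(spec$inner_depths[i], 2L * cout[i], mid[i], dout[i])
    }
  }
  # Side-head biases start at the background prior (foreground is rare in
  # needle masks), and the fusion conv starts as the mean of the side
  # logits: both standard rare-foreground initialisations that save the
  # first few hundred iterations of prior learning.
  heads <- vector("list", s)                  # side heads: decoders + bottom
  for (i in seq_len(s - 1L)) {
    heads[[i]] <- nn_conv(dout[i], 1L, k = 3L, gain = 1, bias_init = -4)
  }
  heads[[s]] <- nn_conv(cout[s], 1L, k = 3L, gain = 1, bias_init = -4)
  fuse <- nn_conv(s, 1L, k = 1L, gain = 1)
  fuse$params[[1]]$val <- array(1 / s, dim(fuse$params[[1]]$val))
  params <- do.call(nn_params, c(enc, ups, ica, dec, heads, list(fuse)))
  fwd <- function(x, train = TRUE) {
    e <- vector("list", s)
    cur <- x
    for (i in seq_len(s)) {
      e[[i]] <- enc[[i]]$fwd(cur, train)
      if (i < s) cur <- op_pool2(e[[i]])
    }
    d <- vector("list", s - 1L)
    cur <- e[[s]]
    for (i in rev(seq_len(s - 1L))) {
      high <- ups[[i]]$fwd(cur, train)
      fused_skip <- ica[[i]]$fwd(e[[i]], high, train)
      d[[i]] <- dec[[i]]$fwd(fused_skip, train)
      cur <- d[[i]]
    }
    side <- vector("list", s)
    for (i in seq_len(s - 1L)) {
      side[[i]] <- op_upnn(heads[[i]]$fwd(d[[i]], train), 2L^(i - 1L))
    }
    side[[s]] <- op_upnn(heads[[s]]$fwd(e[[s]], train), 2L^(s - 1L))
    fused <- fuse$fwd(op_concat_ch(side), train)
    list(fused = fused, side = side)
  }
  list(fwd = fwd, params = params)
}

build_unet_family <- function(spec, kind) {
  s <- spec$n_scales
  B <- spec$base_channels
  cc <- B * 2L^(seq_len(s) - 1L)
  block <- function(cin, cout) {
    switch(kind,
      r2u = nn_rrcnn(cin, cout),
      nn_doubleconv(cin, cout))
  }
  enc <- vector("list", s)
  for (i in seq_len(s)) enc[[i]] <- block(if (i == 1L) 1L else cc[i - 1L], cc[i])
  ups <- vector("list", s - 1L)
  dec <- vector("list", s - 1L)
  gates <- vector("list", s - 1L)
  for (i in seq_len(s - 1L)) {
    ups[[i]] <- nn_convt2(cc[i + 1L], cc[i])
    dec[[i]] <- block(2L * cc[i], cc[i])
    if (kind == "attention_unet") gates[[i]] <- nn_attgate(cc[i])
  }
  head <- nn_conv(cc[1], 1L, k = 1L, gain = 1, bias_init = -4)
  params <- do.call(nn_params, c(enc, ups, dec,
                                 Filter(Negate(is.null), gates), list(head)))
  fwd <- function(x, train = TRUE) {
    e <- vector("list", s)
    cur <- x
    for (i in seq_len(s)) {
      e[[i]] <- enc[[i]]$fwd(cur, train)
      if (i < s) cur <- op_pool2(e[[i]])
    }
    cur <- e[[s]]
    for (i in rev(seq_len(s - 1L))) {
      g <- ups[[i]]$fwd(cur, train)
      skip <- if (kind == "attention_unet") gates[[i]]$fwd(e[[i]], g, train) else e[[i]]
      cur <- dec[[i]]$fwd(op_concat_ch(list(g, skip)), train)
    }
    list(fused = head$fwd(cur, train), side = list())
  }
  list(fwd = fwd, params = params)
}
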