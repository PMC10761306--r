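# Small neural-network layer library on top of the autograd engine.
# A "module" is a list(fwd = function(...), params = list of ag_param).
# Weight initialisation draws from the caller's RNG stream, so seeding
# happens once at network build time.

nn_conv <- function(cin, cout, k = 3L, dilation = 1L, gain = 2,
                    bias_init = 0) {
  W <- ag_param(array(rnorm(k * k * cin * cout, 0, sqrt(gain / (k * k * cin))),
                      c(k, k, cin, cout)))
  b <- ag_param(array(bias_init, cout))
  list(fwd = function(x, train = TRUE) op_conv(x, W, b, dilation),
       params = list(W, b))
}

nn_convt2 <- function(cin, cout) {
  W <- ag_param(array(rnorm(4L * cin * cout, 0, sqrt(2 / (4 * cin))),
                      c(2L, 2L, cin, cout)))
  b <- ag_param(array(0, cout))
  list(fwd = function(x, train = TRUE) op_convt2(x, W, b),
       params = list(W, b))
}

nn_bn <- function(c) {
  layer <- new.env(parent = emptyenv())
  layer$gamma <- ag_param(array(1, c))
  layer$beta <- ag_param(array(0, c))
  list(fwd = function(x, train = TRUE) op_bn(x, layer, train),
       params = list(layer$gamma, layer$beta))
}

# conv + batch norm + ReLU
nn_cbr <- function(cin, cout, dilation = 1L) {
  cv <- nn_conv(cin, cout, 3L, dilation)
  bn <- nn_bn(cout)
  list(fwd = function(x, train = TRUE) op_relu(bn$fwd(cv$fwd(x, train), train)),
       params = c(cv$params, bn$params))
}

nn_params <- function(...) {
  mods <- list(...)
  unlist(lapply(mods, function(m) {
    if (is.null(m)) list() else m$params
  }), recursive = FALSE)
}

# ReSidual U-block of depth L (resolution preserving): an input projection,
# an internal encoder/decoder with 2x2 pooling and nearest upsampling, a
# dilated bottom convolution, and a residual sum with the projection.
nn_rsu <- function(L, cin, cmid, cout) {
  stopifnot(L >= 2L)
  cin_proj <- nn_cbr(cin, cout)
  enc <- vector("list", L - 1L)
  enc[[1]] <- nn_cbr(cout, cmid)
  if (L > 2L) for (l in 2:(L - 1L)) enc[[l]] <- nn_cbr(cmid, cmid)
  bottom <- nn_cbr(cmid, cmid, dilation = 2L)
  dec <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    dec[[l]] <- nn_cbr(2L * cmid, if (l == 1L) cout else cmid)
  }
  params <- do.call(nn_params, c(list(cin_proj, bottom), enc, dec))
  fwd <- function(x, train = TRUE) {
    hin <- cin_proj$fwd(x, train)
    e <- vector("list", L - 1L)
    e[[1]] <- enc[[1]]$fwd(hin, train)
    if (L > 2L) {
      for (l in 2:(L - 1L)) e[[l]] <- enc[[l]]$fwd(op_pool2(e[[l - 1L]]), train)
    }
    cur <- bottom$fwd(e[[L - 1L]], train)
    for (l in rev(seq_len(L - 1L))) {
      cur <- dec[[l]]$fwd(op_concat_ch(list(cur, e[[l]])), train)
      if (l > 1L) cur <- op_upnn(cur, 2L)
    }
    op_add(hin, cur)
  }
  list(fwd = fwd, params = params, pools = L - 2L)
}

# Dilated variant for the bottom scales: same receptive-field growth without
# any internal resolution change.
nn_rsuf <- function(cin, cmid, cout, dilations = c(1L, 2L, 4L)) {
  cin_proj <- nn_cbr(cin, cout)
  x1 <- nn_cbr(cout, cmid, dilations[1])
  x2 <- nn_cbr(cmid, cmid, dilations[2])
  x3 <- nn_cbr(cmid, cmid, dilations[3])
  y2 <- nn_cbr(2L * cmid, cmid, dilations[2])
  y1 <- nn_cbr(2L * cmid, cout, dilations[1])
  fwd <- function(x, train = TRUE) {
    hin <- cin_proj$fwd(x, train)
    h1 <- x1$fwd(hin, train)
    h2 <- x2$fwd(h1, train)
    h3 <- x3$fwd(h2, train)
    g2 <- y2$fwd(op_concat_ch(list(h3, h2)), train)
    g1 <- y1$fwd(op_concat_ch(list(g2, h1)), train)
    op_add(hin, g1)
  }
  list(fwd = fwd, params = nn_params(cin_proj, x1, x2, x3, y2, y1), pools = 0L)
}

# Interactive-cross attention fusion replacing a plain skip connection.
# Channel attention derived from the high-level (decoder) feature gates the
# low-level (encoder) channels; a spatial attention map computed from the
# channel-pooled statistics of both streams then re-weights the result.
# Output is the concatenation of the attended low-level feature with the
# high-level feature (channel count doubles).
nn_ica <- function(c) {
  hidden <- max(4L, c %/% 2L)
  W1 <- ag_param(matrix(rnorm(hidden * c, 0, sqrt(2 / c)), hidden, c))
  b1 <- ag_param(array(0, hidden))
  W2 <- ag_param(matrix(rnorm(c * hidden, 0, sqrt(2 / hidden)), c, hidden))
  b2 <- ag_param(array(0, c))
  spat <- nn_conv(4L, 1L, k = 3L, gain = 1)
  fwd <- function(low, high, train = TRUE) {
    a <- op_sigmoid(op_dense(op_relu(op_dense(op_gap(high), W1, b1)), W2, b2))
    fca <- op_scale_channels(low, a)
    sp_in <- op_concat_ch(list(op_chanpool(fca), op_chanpool(high)))
    s <- op_sigmoid(spat$fwd(sp_in, train))
    fica <- op_scale_spatial(fca, s)
    op_concat_ch(list(fica, high))
  }
  list(fwd = fwd, params = c(list(W1, b1, W2, b2), spat$params))
}

# Attention gate (additive attention): the gating signal g (decoder, already
# upsampled to the skip's resolution) selects spatial positions of skip x.
nn_attgate <- function(c) {
  inter <- max(2L, c %/% 2L)
  wx <- nn_conv(c, inter, k = 1L, gain = 1)
  wg <- nn_conv(c, inter, k = 1L, gain = 1)
  psi <- nn_conv(inter, 1L, k = 1L, gain = 1)
  fwd <- function(x, g, train = TRUE) {
    a <- op_sigmoid(psi$fwd(op_relu(op_add(wx$fwd(x, train), wg$fwd(g, train))),
                            train))
    op_scale_spatial(x, a)
  }
  list(fwd = fwd, params = nn_params(wx, wg, psi))
}

# Recurrent-residual block: two recurrent conv units with shared recurrent
# weights (t = 2 unrolled steps) plus a 1x1-projected residual connection.
nn_rrcnn <- function(cin, cout, t = 2L) {
  proj <- nn_conv(cin, cout, k = 1L, gain = 1)
  u1 <- nn_cbr(cout, cout)
  u2 <- nn_cbr(cout, cout)
  rec_unit <- function(unit, x, train) {
    h <- unit$fwd(x, train)
    for (i in seq_len(t - 1L)) h <- unit$fwd(op_add(x, h), train)
    h
  }
  fwd <- function(x, train = TRUE) {
    x0 <- proj$fwd(x, train)
    op_add(x0, rec_unit(u2, rec_unit(u1, x0, train), train))
  }
  list(fwd = fwd, params = nn_params(proj, u1, u2))
}

# plain double conv block
nn_doubleconv <- function(cin, cout) {
  c1 <- nn_cbr(cin, cout)
  c2 <- nn_cbr(cout, cout)
  list(fwd = function(x, train = TRUE) c2$fwd(c1$fwd(x, train), train),
       params = nn_params(c1, c2))
}
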