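# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# Every intermediate value is an `ag` node: an environment holding the value,
# an accumulated gradient, the parent nodes and a backward closure that maps
# the node's output gradient to one gradient per parent. backward() does a
# depth-first topological sort from the loss node, so only the subgraph that
# produced the loss is traversed. Tensors are numeric arrays laid out
# (H, W, C, N); scalars are length-1 arrays.

ag_node <- function(val, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$requires <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$requires, logical(1)))
  class(e) <- "ag"
  e
}

ag_param <- function(val, name = NULL) {
  e <- ag_node(val)
  e$requires <- TRUE
  e$is_param <- TRUE
  e$name <- name
  e
}

ag_const <- function(val) ag_node(val)

is_ag <- function(x) inherits(x, "ag")

# Topological order (parents before children) of the subgraph ending at node.
ag_topo <- function(node) {
  order <- vector("list", 0L)
  stack <- list(list(node = node, i = 0L))
  node$.visiting <- TRUE
  seen <- list(node)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    ps <- top$node$parents
    if (top$i < length(ps)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- ps[[top$i + 1L]]
      if (is.null(p$.visiting) && p$requires) {
        p$.visiting <- TRUE
        seen[[length(seen) + 1L]] <- p
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      order[[length(order) + 1L]] <- top$node
      stack[[length(stack)]] <- NULL
    }
  }
  for (s in seen) s$.visiting <- NULL
  order
}

#' @noRd
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$val) == 1L)
  order <- ag_topo(loss)
  for (nd in order) nd$grad <- NULL
  loss$grad <- array(1, dim = 1L)
  for (k in rev(seq_along(order))) {
    nd <- order[[k]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$requires || is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  invisible(loss)
}

# ---- elementwise and structural ops -----------------------------------------

op_relu <- function(x) {
  v <- cpp_relu_fwd(x$val)
  ag_node(v, list(x), function(g) list(cpp_relu_bwd(v, g)))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

op_mul <- function(a, b) {
  ag_node(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

# multiply (H,W,C,N) by per-channel scale (C,N)
op_scale_channels <- function(x, a) {
  d <- dim(x$val)
  av <- array(rep(a$val, each = d[1] * d[2]), dim = d)
  ag_node(x$val * av, list(x, a), function(g) {
    ga <- colSums(matrix(g * x$val, d[1] * d[2]))
    list(g * av, matrix(ga, d[3], d[4]))
  })
}

# multiply (H,W,C,N) by spatial map (H,W,1,N)
op_scale_spatial <- function(x, s) {
  d <- dim(x$val)
  sv <- s$val[, , rep(1L, d[3]), , drop = FALSE]
  ag_node(x$val * sv, list(x, s), function(g) {
    gs <- array(0, dim(s$val))
    gx_times <- g * x$val
    for (cc in seq_len(d[3])) {
      gs <- gs + gx_times[, , cc, , drop = FALSE]
    }
    list(g * sv, gs)
  })
}

op_concat_ch <- function(xs) {
  d1 <- dim(xs[[1]]$val)
  chans <- vapply(xs, function(x) dim(x$val)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  off <- 0L
  for (x in xs) {
    cc <- dim(x$val)[3]
    out[, , off + seq_len(cc), ] <- x$val
    off <- off + cc
  }
  ag_node(out, xs, function(g) {
    gs <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      cc <- chans[i]
      gs[[i]] <- g[, , off + seq_len(cc), , drop = FALSE]
      off <- off + cc
    }
    gs
  })
}

# global average pool (H,W,C,N) -> (C,N)
op_gap <- function(x) {
  d <- dim(x$val)
  v <- matrix(colMeans(matrix(x$val, d[1] * d[2])), d[3], d[4])
  ag_node(v, list(x), function(g) {
    list(array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), dim = d))
  })
}

# dense layer on (C,N) matrices: W (Cout,Cin), b (Cout)
op_dense <- function(x, W, b) {
  v <- W$val %*% x$val + as.vector(b$val)
  ag_node(v, list(x, W, b), function(g) {
    list(t(W$val) %*% g, g %*% t(x$val), rowSums(g))
  })
}

# nearest-neighbour upsample by integer factor f
op_upnn <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x$val)
  ri <- rep(seq_len(d[1]), each = f)
  ci <- rep(seq_len(d[2]), each = f)
  v <- x$val[ri, ci, , , drop = FALSE]
  ag_node(v, list(x), function(g) {
    gx <- array(0, d)
    for (a in seq_len(f)) {
      for (b in seq_len(f)) {
        gx <- gx + g[seq(a, by = f, length.out = d[1]),
                     seq(b, by = f, length.out = d[2]), , , drop = FALSE]
      }
    }
    list(gx)
  })
}

# ---- compiled-kernel ops ----------------------------------------------------

op_conv <- function(x, W, b, dilation = 1L) {
  v <- cpp_conv2d_fwd(x$val, W$val, b$val, as.integer(dilation))
  ag_node(v, list(x, W, b), function(g) {
    gr <- cpp_conv2d_bwd(x$val, W$val, g, as.integer(dilation))
    list(gr$gx, gr$gw, gr$gb)
  })
}

op_convt2 <- function(x, W, b) {
  v <- cpp_convt2_fwd(x$val, W$val, b$val)
  ag_node(v, list(x, W, b), function(g) {
    gr <- cpp_convt2_bwd(x$val, W$val, g)
    list(gr$gx, gr$gw, gr$gb)
  })
}

op_pool2 <- function(x) {
  d <- dim(x$val)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  f <- cpp_maxpool2_fwd(x$val)
  ag_node(f$y, list(x), function(g) {
    list(cpp_maxpool2_bwd(f$idx, g, as.integer(d)))
  })
}

op_chanpool <- function(x) {
  d <- dim(x$val)
  f <- cpp_chanpool_fwd(x$val)
  ag_node(f$y, list(x), function(g) {
    list(cpp_chanpool_bwd(f$idx, g, as.integer(d)))
  })
}

# ---- batch normalisation ----------------------------------------------------

# Stats per channel over (H, W, N), always from the current batch (so a
# checkpoint is fully described by its parameters, and inference on a single
# image normalises by that image's own statistics, instance-norm style).
op_bn <- function(x, layer, train = TRUE) {
  f <- cpp_bn_fwd(x$val, as.vector(layer$gamma$val), as.vector(layer$beta$val),
                  1e-5)
  ag_node(f$y, list(x, layer$gamma, layer$beta), function(g) {
    b <- cpp_bn_bwd(f$xhat, f$sd, as.vector(layer$gamma$val), g)
    list(b$gx, b$ggamma, b$gbeta)
  })
}

# ---- losses -----------------------------------------------------------------

# Numerically stable pixel-mean binary cross-entropy from logits.
op_bce_logits <- function(z, target) {
  zv <- z$val
  yv <- if (is_ag(target)) target$val else target
  l <- mean(pmax(zv, 0) - zv * yv + log1p(exp(-abs(zv))))
  n <- length(zv)
  ag_node(array(l, 1L), list(z), function(g) {
    list(g[1L] * (1 / (1 + exp(-zv)) - yv) / n)
  })
}

op_sum_scalars <- function(xs) {
  v <- sum(vapply(xs, function(x) x$val[1L], numeric(1)))
  ag_node(array(v, 1L), xs, function(g) rep(list(g), length(xs)))
}
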