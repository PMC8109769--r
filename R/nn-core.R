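# Minimal CNN engine backing the SGAN: layers are environments holding
# parameters, gradients and the forward cache; networks are ordered layer
# lists.  Backprop is hand-derived per layer.
#
# Internal activation layout is channel-major ("chw"): a batch of N images
# of C channels is a plain C x (H*W*N) matrix (column index h + H*(w + W*n)).
# Spatial dimensions are static per network, so they are inferred once at
# build time (nn_trace_shapes) and stored on each layer; the batch size is
# recovered from the number of columns.  In this layout the im2col/GEMM
# convolution kernels in src/conv_ops.cpp need no output reordering and
# every column transfer is contiguous.  Dense layers operate on plain
# [features, N] matrices; the reshape layers between the two formats are
# free (a dim() change).  User-facing image batches are [H, W, C, N]
# arrays, converted at the network boundary.
#
# Transposed convolution is the exact adjoint of a stride-2 convolution:
# its forward pass is conv_bwd_x and its backward pass conv_fwd, with the
# kernel stored as the underlying downsampling convolution's.

hwcn_to_chw <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(3, 1, 2, 4))
  dim(y) <- c(d[3], d[1] * d[2] * d[4])
  y
}

chw_to_hwcn <- function(y, H, W, N) {
  C <- nrow(y)
  dim(y) <- c(C, H, W, N)
  aperm(y, c(2, 3, 1, 4))
}

new_layer <- function(type, ...) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = ly)
  ly
}

# kernel stored as (cin*k*k) x cout, input channel fastest
nn_conv <- function(cin, cout, k, stride = 1, pad = 0) {
  new_layer("conv", w = matrix(0, cin * k * k, cout), b = numeric(cout),
            k = k, stride = stride, pad = pad, cin = cin, cout = cout)
}

# stride-2 upsampling; kernel stored as the underlying downsampling
# convolution's, (cout*k*k) x cin, so the adjoint identities hold directly
nn_tconv <- function(cin, cout, k = 5, stride = 2, pad = 2) {
  new_layer("tconv", w = matrix(0, cout * k * k, cin), b = numeric(cout),
            k = k, stride = stride, pad = pad, cin = cin, cout = cout)
}

nn_dense <- function(din, dout) {
  new_layer("dense", w = matrix(0, dout, din), b = numeric(dout),
            din = din, dout = dout)
}

nn_relu       <- function() new_layer("relu")
nn_tanh       <- function() new_layer("tanh")
nn_dropout    <- function(p = 0.3) new_layer("dropout", p = p)
# fused LeakyReLU + dropout (the discriminator's block nonlinearity)
nn_lreludrop  <- function(alpha = 0.2, p = 0.3)
  new_layer("lreludrop", alpha = alpha, p = p)
nn_to_mat     <- function() new_layer("to_mat")    # chw -> (C*H*W) x N
nn_to_chw     <- function(h, w, c) new_layer("to_chw", rh = h, rw = w, rc = c)
nn_gap        <- function() new_layer("gap")
nn_avgpool    <- function(s = 2) new_layer("avgpool", s = s)

nn_network <- function(...) {
  net <- new.env(parent = emptyenv())
  net$layers <- list(...)
  net
}

# propagate the (static) spatial dimensions through the layer stack; every
# chw-consuming layer learns its input side H = W = `side`
nn_trace_shapes <- function(net, input_side = NULL) {
  side <- input_side
  for (ly in net$layers) {
    if (ly$type %in% c("conv", "tconv", "gap", "avgpool", "to_mat")) {
      if (is.null(side)) stop("nn_trace_shapes: unknown spatial input size")
      ly$H <- side
      ly$W <- side
    }
    side <- switch(ly$type,
      conv = (side + 2 * ly$pad - ly$k) %/% ly$stride + 1,
      tconv = side * ly$stride,
      avgpool = side %/% ly$s,
      to_chw = ly$rh,
      gap = ,
      to_mat = NULL,
      side)
  }
  invisible(net)
}

.PARAM_LAYERS <- c("conv", "tconv", "dense")

# He-scaled truncated normal (|z| <= 2 sd) initialisation, biases zero.
# sd = sqrt(2 / fan_in) keeps activation variance roughly constant through
# the ReLU stacks; without it (e.g. a flat sd of 0.02, which presumes
# batch normalisation) activations vanish through five conv layers and
# the discriminator never escapes chance level.
nn_init <- function(net) {
  rtnorm <- function(n, sd) {
    z <- stats::rnorm(n, sd = sd)
    bad <- abs(z) > 2 * sd
    while (any(bad)) {
      z[bad] <- stats::rnorm(sum(bad), sd = sd)
      bad <- abs(z) > 2 * sd
    }
    z
  }
  for (ly in net$layers) {
    if (!ly$type %in% .PARAM_LAYERS) next
    fan_in <- switch(ly$type,
      conv = ly$cin * ly$k^2,
      # adjoint upsampling: each output draws on ~cin * (k/stride)^2 taps
      tconv = ly$cin * (ly$k / ly$stride)^2,
      dense = ly$din)
    d <- dim(ly$w)
    ly$w <- matrix(rtnorm(prod(d), sqrt(2 / fan_in)), d[1], d[2])
    ly$b <- numeric(length(ly$b))
  }
  invisible(net)
}

layer_forward <- function(ly, x, training = FALSE) {
  switch(ly$type,
    conv = {
      n <- ncol(x) %/% (ly$H * ly$W)
      ly$x <- x
      ly$n <- n
      res <- conv_fwd(x, ly$H, ly$W, n, ly$w, ly$b,
                      ly$k, ly$stride, ly$pad, training)
      ly$cols <- res$cols
      res$y
    },
    tconv = {
      n <- ncol(x) %/% (ly$H * ly$W)
      ly$x <- x
      ly$n <- n
      y <- conv_bwd_x(x, ly$H, ly$W, n, ly$w, ly$k,
                      ly$H * ly$stride, ly$W * ly$stride, ly$stride, ly$pad)
      y + ly$b
    },
    dense = {
      ly$x <- x
      ly$w %*% x + ly$b
    },
    relu = {
      ly$mask <- x > 0
      x * ly$mask
    },
    lreludrop = {
      res <- lrelu_dropout(x, ly$alpha, ly$p, training)
      ly$code <- res$code
      ly$mult <- res$mult
      res$y
    },
    tanh = {
      ly$y <- tanh(x)
      ly$y
    },
    dropout = {
      if (training && ly$p > 0) {
        ly$mask <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
        x * ly$mask
      } else {
        ly$mask <- NULL
        x
      }
    },
    to_mat = {
      ly$c <- nrow(x)
      ly$n <- ncol(x) %/% (ly$H * ly$W)
      dim(x) <- c(nrow(x) * ly$H * ly$W, ly$n)
      x
    },
    to_chw = {
      ly$n <- ncol(x)
      dim(x) <- c(ly$rc, ly$rh * ly$rw * ly$n)
      x
    },
    gap = {
      hw <- ly$H * ly$W
      n <- ncol(x) %/% hw
      ly$n <- n
      x %*% kronecker(diag(n), matrix(1 / hw, hw, 1))
    },
    avgpool = {
      n <- ncol(x) %/% (ly$H * ly$W)
      if (is.null(ly$idx) || ly$n != n) {
        ly$idx <- .pool_index(ly$H, ly$W, n, ly$s)
        ly$n <- n
      }
      y <- 0
      for (ii in ly$idx) y <- y + x[, ii, drop = FALSE]
      y / (ly$s * ly$s)
    },
    stop("unknown layer type: ", ly$type)
  )
}

# input-column index sets for s x s average pooling in chw layout
.pool_index <- function(H, W, N, s) {
  ho <- H %/% s; wo <- W %/% s
  g <- expand.grid(h = seq_len(ho) - 1L, w = seq_len(wo) - 1L,
                   n = seq_len(N) - 1L)
  out <- list()
  for (dj in seq_len(s) - 1L) for (di in seq_len(s) - 1L)
    out[[length(out) + 1L]] <-
      (g$h * s + di) + H * (g$w * s + dj) + H * W * g$n + 1L
  out
}

layer_backward <- function(ly, dy, wgrad = TRUE, need_dx = TRUE) {
  switch(ly$type,
    conv = {
      if (wgrad) {
        ly$gw <- conv_bwd_w(ly$x, ly$H, ly$W, ly$n,
                            dy, ly$k, ly$stride, ly$pad, ly$cols)
        ly$gb <- rowSums(dy)
      }
      ly$cols <- NULL
      if (!need_dx) return(NULL)
      ho <- (ly$H + 2 * ly$pad - ly$k) %/% ly$stride + 1
      conv_bwd_x(dy, ho, ho, ly$n, ly$w,
                 ly$k, ly$H, ly$W, ly$stride, ly$pad)
    },
    tconv = {
      # dx = conv forward of dy; its im2col matrix is shared with the
      # kernel gradient dW = im2col(dy) * x'
      Hb <- ly$H * ly$stride
      if (!need_dx && wgrad) {
        ly$gw <- conv_bwd_w(dy, Hb, Hb, ly$n, ly$x, ly$k, ly$stride,
                            ly$pad, NULL)
        ly$gb <- rowSums(dy)
        return(NULL)
      }
      res <- conv_fwd(dy, Hb, Hb, ly$n, ly$w, numeric(ly$cin),
                      ly$k, ly$stride, ly$pad, wgrad)
      if (wgrad) {
        ly$gw <- conv_bwd_w(dy, Hb, Hb, ly$n, ly$x, ly$k, ly$stride,
                            ly$pad, res$cols)
        ly$gb <- rowSums(dy)
      }
      res$y
    },
    dense = {
      if (wgrad) {
        ly$gw <- dy %*% t(ly$x)
        ly$gb <- rowSums(dy)
      }
      if (!need_dx) return(NULL)
      t(ly$w) %*% dy
    },
    relu = dy * ly$mask,
    lreludrop = lrelu_dropout_bwd(dy, ly$code, ly$mult),
    tanh = dy * (1 - ly$y^2),
    dropout = if (is.null(ly$mask)) dy else dy * ly$mask,
    to_mat = {
      dim(dy) <- c(ly$c, ly$H * ly$W * ly$n)
      dy
    },
    to_chw = {
      dim(dy) <- c(ly$rc * ly$rh * ly$rw, ly$n)
      dy
    },
    gap = {
      hw <- ly$H * ly$W
      dy[, rep(seq_len(ly$n), each = hw), drop = FALSE] / hw
    },
    avgpool = {
      s <- ly$s
      dx <- matrix(0, nrow(dy), ly$H * ly$W * ly$n)
      for (ii in ly$idx) dx[, ii] <- dy / (s * s)
      dx
    },
    stop("unknown layer type: ", ly$type)
  )
}

nn_forward <- function(net, x, training = FALSE) {
  for (ly in net$layers) x <- layer_forward(ly, x, training = training)
  x
}

# backprop from layer `from` down to layer 1; parameter gradients are
# stored in the layer environments unless wgrad = FALSE (frozen network);
# returns d(loss)/d(network input), or NULL when input_grad = FALSE (the
# first layer's input gradient is then skipped as dead work)
nn_backward <- function(net, dy, from = length(net$layers), wgrad = TRUE,
                        input_grad = TRUE) {
  for (i in seq(from, 1L))
    dy <- layer_backward(net$layers[[i]], dy, wgrad = wgrad,
                         need_dx = input_grad || i > 1L)
  dy
}

nn_parameters <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% .PARAM_LAYERS) {
      out[[paste0("w", i)]] <- ly$w
      out[[paste0("b", i)]] <- ly$b
    }
  }
  out
}

nn_set_parameters <- function(net, params) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% .PARAM_LAYERS) {
      ly$w <- params[[paste0("w", i)]]
      ly$b <- params[[paste0("b", i)]]
    }
  }
  invisible(net)
}

n_parameters <- function(net) sum(lengths(nn_parameters(net)))

# Adam with Keras-convention decay: the step size anneals as
# lr_t = lr / (1 + decay * t).  (An L2 reading of the decay constant
# interacts badly with Adam's per-parameter normalisation: once task
# gradients are small the penalty term dominates the update and erodes
# the trained weights.)
adam_new <- function(lr = 1e-4, beta1 = 0.8, beta2 = 0.999, eps = 1e-8,
                     weight_decay = 5e-4) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2
  opt$eps <- eps; opt$decay <- weight_decay; opt$t <- 0L
  opt
}

adam_step <- function(opt, net) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  lr_t <- opt$lr / (1 + opt$decay * opt$t)
  for (ly in net$layers) {
    if (!ly$type %in% .PARAM_LAYERS) next
    if (is.null(ly$gw)) stop("adam_step: layer has no gradient")
    gw <- ly$gw
    gb <- ly$gb
    if (is.null(ly$mw)) {
      ly$mw <- gw * 0; ly$vw <- gw * 0
      ly$mb <- gb * 0; ly$vb <- gb * 0
    }
    # moment buffers are updated in place (they are private to the layer)
    ly$w <- adam_update(ly$w, gw, ly$mw, ly$vw, lr_t, b1, b2, opt$eps,
                        corr1, corr2)
    ly$b <- adam_update(ly$b, gb, ly$mb, ly$vb, lr_t, b1, b2, opt$eps,
                        corr1, corr2)
  }
  invisible(net)
}
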