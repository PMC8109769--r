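# The convolution kernels are the numerical foundation of everything else,
# so they are checked against a direct-definition oracle and the adjoint
# identity that links convolution and transposed convolution.

# direct-definition convolution on a [H,W,C,N] array
naive_conv <- function(x, w4, b, stride, pad) {
  d <- dim(x); k <- dim(w4)[1]; cout <- dim(w4)[4]
  ho <- (d[1] + 2 * pad - k) %/% stride + 1
  wo <- (d[2] + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + 1:d[1], pad + 1:d[2], , ] <- x
  y <- array(0, c(ho, wo, cout, d[4]))
  for (n in 1:d[4]) for (co in 1:cout) for (j in 1:wo) for (i in 1:ho) {
    patch <- xp[(i - 1) * stride + 1:k, (j - 1) * stride + 1:k, , n,
                drop = FALSE]
    y[i, j, co, n] <- sum(patch[, , , 1] * w4[, , , co]) + b[co]
  }
  y
}

# pack a [k,k,cin,cout] kernel into the engine's (cin*k*k) x cout layout
pack_kernel <- function(w4) {
  k <- dim(w4)[1]; cin <- dim(w4)[3]; cout <- dim(w4)[4]
  m <- matrix(0, cin * k * k, cout)
  for (co in 1:cout) for (c in 1:cin) for (j in 1:k) for (i in 1:k)
    m[c + cin * ((i - 1) + k * (j - 1)), co] <- w4[i, j, c, co]
  m
}

test_that("convolution forward matches the direct definition", {
  set.seed(42)
  for (case in list(list(s = 2, p = 1, k = 3), list(s = 1, p = 0, k = 5),
                    list(s = 2, p = 2, k = 5))) {
    x <- array(rnorm(10 * 10 * 3 * 2), c(10, 10, 3, 2))
    w4 <- array(rnorm(case$k^2 * 3 * 4), c(case$k, case$k, 3, 4))
    b <- rnorm(4)
    y_ref <- naive_conv(x, w4, b, case$s, case$p)
    res <- ns$conv_fwd(ns$hwcn_to_chw(x), 10L, 10L, 2L, pack_kernel(w4), b,
                       as.integer(case$k), as.integer(case$s),
                       as.integer(case$p), FALSE)
    ho <- dim(y_ref)[1]
    y <- ns$chw_to_hwcn(res$y, ho, ho, 2)
    expect_equal(y, y_ref, tolerance = 1e-12)
  }
})

test_that("conv_bwd_x is the exact adjoint of conv_fwd", {
  set.seed(7)
  x <- matrix(rnorm(5 * 8 * 8 * 3), 5)          # 5 channels, 8x8, 3 images
  w <- matrix(rnorm(5 * 9 * 7), 45, 7)
  dy <- matrix(rnorm(7 * 4 * 4 * 3), 7)
  y <- ns$conv_fwd(x, 8L, 8L, 3L, w, numeric(7), 3L, 2L, 1L, FALSE)$y
  dx <- ns$conv_bwd_x(dy, 4L, 4L, 3L, w, 3L, 8L, 8L, 2L, 1L)
  # <conv(x), dy> == <x, conv^T(dy)> for the bias-free map
  expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-10)
})

test_that("conv_bwd_w matches finite differences", {
  set.seed(8)
  x <- matrix(rnorm(4 * 6 * 6 * 2), 4)
  w <- matrix(rnorm(4 * 9 * 3), 36, 3)
  dy <- matrix(rnorm(3 * 3 * 3 * 2), 3)
  dw <- ns$conv_bwd_w(x, 6L, 6L, 2L, dy, 3L, 2L, 1L, NULL)
  e <- 1e-6
  for (i in sample(length(w), 8)) {
    wp <- w; wp[i] <- wp[i] + e
    wm <- w; wm[i] <- wm[i] - e
    yp <- ns$conv_fwd(x, 6L, 6L, 2L, wp, numeric(3), 3L, 2L, 1L, FALSE)$y
    ym <- ns$conv_fwd(x, 6L, 6L, 2L, wm, numeric(3), 3L, 2L, 1L, FALSE)$y
    expect_equal(dw[i], (sum(yp * dy) - sum(ym * dy)) / (2 * e),
                 tolerance = 1e-6)
  }
})

test_that("transposed convolution doubles the spatial side and is adjoint-consistent", {
  cfg <- tiny_cfg()
  set.seed(1)
  ly <- ns$nn_tconv(5, 4, k = 5)
  ly$H <- 6; ly$W <- 6
  ly$w <- matrix(rnorm(4 * 25 * 5), 100, 5)
  x <- matrix(rnorm(5 * 36 * 2), 5)
  y <- ns$layer_forward(ly, x)
  expect_equal(dim(y), c(4, 12 * 12 * 2))
  # zero bias: forward equals the adjoint of the downsampling convolution
  dy <- matrix(rnorm(4 * 144 * 2), 4)
  dx <- ns$layer_backward(ly, dy, wgrad = FALSE)
  expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-10)
})

test_that("average pooling and global average pooling backprop conserve gradient mass", {
  set.seed(3)
  pool <- ns$nn_avgpool(2)
  pool$H <- 6; pool$W <- 6
  x <- matrix(rnorm(4 * 36 * 2), 4)
  y <- ns$layer_forward(pool, x)
  expect_equal(dim(y), c(4, 9 * 2))
  expect_equal(y[1, 1], mean(x[1, c(1, 2, 7, 8)]))
  dy <- matrix(rnorm(length(y)), nrow(y))
  dx <- ns$layer_backward(pool, dy)
  expect_equal(sum(dx), sum(dy), tolerance = 1e-12)

  gap <- ns$nn_gap()
  gap$H <- 6; gap$W <- 6
  g <- ns$layer_forward(gap, x)
  expect_equal(dim(g), c(4, 2))
  expect_equal(g[2, 1], mean(x[2, 1:36]))
  dg <- matrix(rnorm(8), 4)
  dxg <- ns$layer_backward(gap, dg)
  expect_equal(sum(dxg), sum(dg), tolerance = 1e-12)
})

test_that("channel-major conversion round-trips", {
  x <- rand_images(8, 3)
  expect_equal(ns$chw_to_hwcn(ns$hwcn_to_chw(x), 8, 8, 3), x)
})

test_that("fused LeakyReLU/dropout matches its reference in inference mode and backprops exactly", {
  set.seed(2)
  x <- matrix(rnorm(200), 10)
  res <- ns$lrelu_dropout(x, 0.2, 0.3, FALSE)   # inference: no dropout
  expect_equal(res$y, pmax(x, 0) + 0.2 * pmin(x, 0))
  dy <- matrix(rnorm(200), 10)
  dx <- ns$lrelu_dropout_bwd(dy, res$code, res$mult)
  expect_equal(dx, dy * (0.2 + 0.8 * (x > 0)))
  # training mode: inverted dropout keeps the activation unbiased
  set.seed(4)
  big <- matrix(abs(rnorm(2e5)), 100)
  keep <- ns$lrelu_dropout(big, 0.2, 0.3, TRUE)
  expect_equal(mean(keep$y), mean(big), tolerance = 0.02)
  expect_equal(mean(keep$y == 0), 0.3, tolerance = 0.02)
})
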