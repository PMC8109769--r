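# Closed-form values, brute-force per-sample oracles, and the
# finite-difference gradient checks that certify the whole training path.

test_that("supervised loss matches closed forms and the per-sample oracle", {
  # certain correct prediction -> -log 1 = 0 (up to probability clamping)
  expect_equal(supervised_loss(matrix(c(1, 0, 0)), 0L), 0, tolerance = 1e-6)
  # p = (0.5, 0.5, 0), label 0 -> ln 2
  expect_equal(supervised_loss(matrix(c(0.5, 0.5, 0)), 0L), log(2),
               tolerance = 1e-9)
  # mixed batch equals the one-by-one computation
  p <- rand_probs(3, 25, seed = 11)
  y <- sample(0:1, 25, replace = TRUE)
  expect_equal(supervised_loss(p, y), oracle_sup_loss(p, y),
               tolerance = 1e-9)
})

test_that("supervised loss conditions on the sample being real", {
  # scaling the fake-class probability (renormalising the rest) must not
  # change the loss: the conditioning y < K+1 removes p_fake
  p <- rand_probs(3, 10, seed = 3)
  y <- sample(0:1, 10, replace = TRUE)
  base <- supervised_loss(p, y)
  for (f in c(0, 0.5, 3)) {
    q <- p
    q[3, ] <- p[3, ] * f
    q <- sweep(q, 2, colSums(q), "/")
    expect_equal(supervised_loss(q, y), base, tolerance = 1e-7)
  }
})

test_that("supervised loss rejects fake-class labels", {
  expect_error(supervised_loss(matrix(c(0.5, 0.5, 0)), 2L), "fake")
})

test_that("unsupervised loss matches closed forms and the per-sample oracle", {
  # ideal discriminator: real surely real, generated surely fake -> 0
  expect_equal(unsupervised_loss(matrix(c(0.6, 0.4, 0)),
                                 matrix(c(0, 0, 1))), 0, tolerance = 1e-5)
  # p_fake = 0.5 on both sides -> 2 ln 2
  expect_equal(unsupervised_loss(matrix(c(0.25, 0.25, 0.5)),
                                 matrix(c(0.3, 0.2, 0.5))), 2 * log(2),
               tolerance = 1e-9)
  pu <- rand_probs(3, 17, seed = 5)
  pg <- rand_probs(3, 9, seed = 6)
  expect_equal(unsupervised_loss(pu, pg), oracle_unsup_loss(pu, pg),
               tolerance = 1e-9)
  expect_error(unsupervised_loss(pu[, 0, drop = FALSE], pg), "empty")
})

test_that("discriminator loss decomposes additively", {
  lb <- discriminator_loss(log(2), 2 * log(2))
  expect_equal(lb$l_d, 3 * log(2))
  expect_equal(discriminator_loss(0, 0)$l_d, 0)
  # additivity
  a <- 0.37; b <- 1.21
  expect_equal(discriminator_loss(a, b)$l_d,
               discriminator_loss(a, 0)$l_d + discriminator_loss(0, b)$l_d)
  expect_error(discriminator_loss(NaN, 1), "non-finite")
})

test_that("feature matching loss is the squared distance of mean features", {
  f <- matrix(rnorm(40), 8)
  expect_equal(feature_matching_loss(f, f), 0)
  # means differing by a unit basis vector -> 1
  a <- matrix(0, 5, 4)
  b <- a; b[3, ] <- 1
  expect_equal(feature_matching_loss(a, b), 1)
  # manual summation oracle
  fr <- matrix(rnorm(8 * 6), 8)
  ff <- matrix(rnorm(8 * 10), 8)
  expect_equal(feature_matching_loss(fr, ff),
               sum((rowMeans(fr) - rowMeans(ff))^2), tolerance = 1e-12)
  expect_error(feature_matching_loss(matrix(0, 3, 2), matrix(0, 4, 2)),
               "mismatch")
})

test_that("logit-space losses agree with the probability-space definitions", {
  set.seed(9)
  logits <- matrix(rnorm(3 * 20, sd = 2), 3)
  probs <- ns$softmax_cols(logits)
  y <- sample(0:1, 20, replace = TRUE)
  expect_equal(ns$.sup_logit_grad(logits, y)$loss, supervised_loss(probs, y),
               tolerance = 1e-9)
  lu <- matrix(rnorm(3 * 8, sd = 2), 3)
  lg <- matrix(rnorm(3 * 8, sd = 2), 3)
  expect_equal(ns$.unsup_real_logit_grad(lu)$loss +
                 ns$.unsup_fake_logit_grad(lg)$loss,
               unsupervised_loss(ns$softmax_cols(lu), ns$softmax_cols(lg)),
               tolerance = 1e-9)
})

test_that("analytic discriminator gradients match central finite differences", {
  cfg <- tiny_cfg()
  set.seed(3)
  disc <- build_discriminator(cfg)

  m <- 4
  xl <- rand_images(32, m, seed = 1)
  yl <- sample(0:1, m, replace = TRUE)
  xu <- rand_images(32, m, seed = 2)
  xg <- rand_images(32, m, seed = 3)
  x <- ns$.cat_chw(xl, xu, xg)
  loss_d <- function() {
    logits <- ns$nn_forward(disc, x)
    ns$.sup_logit_grad(logits[, 1:m, drop = FALSE], yl)$loss +
      ns$.unsup_real_logit_grad(logits[, m + 1:m, drop = FALSE])$loss +
      ns$.unsup_fake_logit_grad(logits[, 2 * m + 1:m, drop = FALSE])$loss
  }
  logits <- ns$nn_forward(disc, x)
  s <- ns$.sup_logit_grad(logits[, 1:m, drop = FALSE], yl)
  u <- ns$.unsup_real_logit_grad(logits[, m + 1:m, drop = FALSE])
  f <- ns$.unsup_fake_logit_grad(logits[, 2 * m + 1:m, drop = FALSE])
  dl <- matrix(0, 3, 3 * m)
  dl[, 1:m] <- s$grad; dl[, m + 1:m] <- u$grad; dl[, 2 * m + 1:m] <- f$grad
  ns$nn_backward(disc, dl)
  e <- 1e-5
  set.seed(31)
  for (li in seq_along(disc$layers)) {
    ly <- disc$layers[[li]]
    if (is.null(ly$w)) next
    for (i in sample(length(ly$w), 3)) {
      w0 <- ly$w[i]
      ly$w[i] <- w0 + e; lp <- loss_d()
      ly$w[i] <- w0 - e; lm <- loss_d()
      ly$w[i] <- w0
      g_num <- (lp - lm) / (2 * e)
      expect_lt(abs(g_num - ly$gw[i]) / max(abs(g_num), 1e-3), 1e-4)
    }
  }
})

test_that("analytic generator (feature-matching) gradients match central finite differences", {
  cfg <- tiny_cfg()
  set.seed(4)
  disc <- build_discriminator(cfg)
  gen <- build_generator(cfg)


  z <- sample_noise(2, cfg)
  xr <- rand_images(32, 2, seed = 9)
  nl <- length(disc$layers)
  loss_g <- function() {
    fake <- ns$nn_forward(gen, z)
    ns$nn_forward(disc, ns$.cat_chw(xr, fake))
    fe <- disc$layers[[nl]]$x
    sum((rowMeans(fe[, 1:2, drop = FALSE]) -
           rowMeans(fe[, 3:4, drop = FALSE]))^2)
  }
  fake <- ns$nn_forward(gen, z)
  ns$nn_forward(disc, ns$.cat_chw(xr, fake))
  fe <- disc$layers[[nl]]$x
  d <- rowMeans(fe[, 1:2, drop = FALSE]) - rowMeans(fe[, 3:4, drop = FALSE])
  dfe <- matrix(0, nrow(fe), 4)
  dfe[, 3:4] <- -2 * d / 2
  dx <- ns$nn_backward(disc, dfe, from = nl - 1, wgrad = FALSE)
  hw <- 32 * 32
  invisible(ns$nn_backward(gen, dx[, 2 * hw + seq_len(2 * hw), drop = FALSE]))
  e <- 1e-5
  set.seed(32)
  for (li in seq_along(gen$layers)) {
    ly <- gen$layers[[li]]
    if (is.null(ly$w)) next
    for (i in sample(length(ly$w), 3)) {
      w0 <- ly$w[i]
      ly$w[i] <- w0 + e; lp <- loss_g()
      ly$w[i] <- w0 - e; lm <- loss_g()
      ly$w[i] <- w0
      g_num <- (lp - lm) / (2 * e)
      expect_lt(abs(g_num - ly$gw[i]) / max(abs(g_num), 1e-3), 1e-4)
    }
  }
})

test_that("gradient steps respect the freeze contracts and learning-rate zero", {
  cfg <- tiny_cfg(weight_decay = 0)
  set.seed(5)
  disc <- build_discriminator(cfg)
  gen <- build_generator(cfg)
  disc$opt$lr <- 0   # optimizer step with zero learning rate
  gen$opt$lr <- 0
  batch <- list(x_labeled = rand_images(32, 4, 1),
                y_labeled = c(0L, 1L, 0L, 1L),
                x_unlabeled = rand_images(32, 4, 2),
                x_generated = rand_images(32, 4, 3))
  pd0 <- ns$nn_parameters(disc)
  pg0 <- ns$nn_parameters(gen)
  gradient_step_d(disc, batch)
  expect_identical(ns$nn_parameters(disc), pd0)  # lr 0: unchanged
  expect_identical(ns$nn_parameters(gen), pg0)   # generator untouched
  gradient_step_g(gen, disc, rand_images(32, 2, 4), sample_noise(2, cfg))
  expect_identical(ns$nn_parameters(disc), pd0)  # frozen discriminator
  expect_identical(ns$nn_parameters(gen), pg0)   # lr 0: unchanged

  # with a real learning rate parameters do change and the discriminator
  # loss decreases over repeated steps on a fixed minibatch
  cfg2 <- tiny_cfg(lr_d = 2e-3, lr_g = 1e-3)
  set.seed(6)
  disc2 <- build_discriminator(cfg2)
  l_first <- gradient_step_d(disc2, batch)$l_d
  for (i in 1:19) l_last <- gradient_step_d(disc2, batch)$l_d
  expect_lt(l_last, l_first)

  set.seed(7)
  gen2 <- build_generator(cfg2)
  disc3 <- build_discriminator(cfg2)
  inflate_weights(disc3, 5)  # non-trivial features to match
  xr <- rand_images(32, 2, 5)
  z <- sample_noise(2, cfg2)
  lg_first <- gradient_step_g(gen2, disc3, xr, z)
  for (i in 1:19) lg_last <- gradient_step_g(gen2, disc3, xr, z)
  expect_lt(lg_last, lg_first)
})
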