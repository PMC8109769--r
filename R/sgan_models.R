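#' SGAN configuration
#'
#' Collects every architectural and optimisation hyperparameter of the
#' semi-supervised GAN.  The generator reshapes a latent draw to a
#' `base x base x gen_channels[1]` tensor and upsamples through four
#' 5x5 transposed convolutions (each doubling the spatial side, so the
#' output side is `base * 16`); the discriminator is a fully convolutional
#' (K+1)-class classifier built from stride-2 3x3 convolutions with a
#' global-average-pool feature layer and a softmax head.
#'
#' @param image_side output/input image side in pixels; must equal
#'   `base * 16` and be divisible by 32 (five stride-2 stages in the
#'   discriminator).
#' @param base spatial side of the generator's reshape layer (28 yields the
#'   full-scale 448-pixel model; 4 yields the 64-pixel desk-scale model).
#' @param latent_dim length of the generator's noise input.
#' @param n_classes number of real classes K (crop, weed); the
#'   discriminator adds one fake class, index `K` zero-based.
#' @param gen_channels,disc_channels channel schedules: four generator
#'   stages (the last transposed convolution maps `gen_channels[4]` to 3)
#'   and five discriminator stages.
#' @param gen_kernel,disc_kernel convolution kernel sizes (5 and 3).
#' @param lr_g,lr_d Adam learning rates for generator and discriminator.
#' @param beta1,beta2,weight_decay Adam moment coefficients and L2 penalty.
#' @param batch_size minibatch size m; must be even (the generator step
#'   feeds the discriminator with m/2 real and m/2 fake images).
#' @param epochs number of training epochs.
#' @param dropout discriminator dropout rate.
#' @param unsup_includes_labeled if `TRUE` (default), labeled images also
#'   enter the real-data term of the unsupervised loss, so every real
#'   image in the minibatch is pushed away from the fake class.
#' @param seed integer seed controlling initialisation and batching.
#' @return a `gan_config` list.
#' @export
gan_config <- function(image_side = 64, base = image_side / 16,
                       latent_dim = 100, n_classes = 2,
                       gen_channels = c(512, 256, 128, 64),
                       disc_channels = c(64, 128, 256, 512, 512),
                       gen_kernel = 5, disc_kernel = 3,
                       lr_g = 1e-4, lr_d = 1e-4,
                       beta1 = 0.8, beta2 = 0.999, weight_decay = 5e-4,
                       batch_size = 30, epochs = 1000, dropout = 0.3,
                       unsup_includes_labeled = TRUE, seed = 42L) {
  if (base < 2) stop("gan_config: base must be >= 2")
  if (image_side != base * 16)
    stop("gan_config: image_side must equal base * 16 (got ",
         image_side, " with base ", base, ")")
  if (image_side %% 32 != 0)
    stop("gan_config: image_side must be divisible by 32")
  if (batch_size %% 2 != 0) stop("gan_config: batch_size must be even")
  if (lr_g <= 0 || lr_d <= 0) stop("gan_config: learning rates must be > 0")
  if (length(gen_channels) != 4 || length(disc_channels) != 5)
    stop("gan_config: need 4 generator and 5 discriminator channel counts")
  structure(list(
    image_side = as.integer(image_side), base = as.integer(base),
    latent_dim = as.integer(latent_dim), n_classes = as.integer(n_classes),
    gen_channels = as.integer(gen_channels),
    disc_channels = as.integer(disc_channels),
    gen_kernel = as.integer(gen_kernel), disc_kernel = as.integer(disc_kernel),
    lr_g = lr_g, lr_d = lr_d, beta1 = beta1, beta2 = beta2,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), dropout = dropout,
    unsup_includes_labeled = isTRUE(unsup_includes_labeled),
    seed = as.integer(seed)
  ), class = "gan_config")
}

#' Desk-scale SGAN configuration
#'
#' A narrow-channel profile of [gan_config()] sized for CPU experiments on
#' 64-pixel synthetic field images; all arguments of [gan_config()] can be
#' overridden.
#'
#' @param ... overrides passed on to [gan_config()].
#' @return a `gan_config` list.
#' @export
gan_config_desk <- function(...) {
  args <- list(image_side = 64, gen_channels = c(48, 24, 12, 6),
               disc_channels = c(8, 16, 32, 64, 64), epochs = 150,
               lr_g = 1e-3, lr_d = 1e-3)
  over <- list(...)
  args[names(over)] <- over
  do.call(gan_config, args)
}

#' Build the generator network
#'
#' Latent vector -> dense -> reshape to `base x base x gen_channels[1]` ->
#' four 5x5 transposed convolutions, each doubling the spatial side
#' (channels `gen_channels[1..4]` then 3), ReLU on all hidden layers and
#' Tanh on the output so pixels live in (-1, 1).
#'
#' @param config a [gan_config()].
#' @return an initialised generator network.
#' @export
build_generator <- function(config) {
  ch <- config$gen_channels
  b <- config$base
  k <- config$gen_kernel
  net <- nn_network(
    nn_dense(config$latent_dim, b * b * ch[1]),
    nn_to_chw(b, b, ch[1]),
    nn_relu(),
    nn_tconv(ch[1], ch[2], k = k), nn_relu(),
    nn_tconv(ch[2], ch[3], k = k), nn_relu(),
    nn_tconv(ch[3], ch[4], k = k), nn_relu(),
    nn_tconv(ch[4], 3, k = k),
    nn_tanh()
  )
  nn_trace_shapes(net)
  nn_init(net)
  net$config <- config
  net$opt <- adam_new(lr = config$lr_g, beta1 = config$beta1,
                      beta2 = config$beta2, weight_decay = config$weight_decay)
  net
}

#' Build the (K+1)-class discriminator network
#'
#' Five stride-2 3x3 convolution blocks (LeakyReLU 0.2, dropout) reduce the
#' image to a small grid; global average pooling yields the feature vector
#' used by the feature-matching generator objective, and a final dense layer
#' maps features to K+1 logits (index K+1 is the fake class; softmax is
#' applied in [discriminate()]).
#'
#' @param config a [gan_config()].
#' @return an initialised discriminator network.
#' @export
build_discriminator <- function(config) {
  ch <- config$disc_channels
  k <- config$disc_kernel
  p <- config$dropout
  cin <- c(3, ch[-5])
  blocks <- list()
  for (i in 1:5) {
    blocks <- c(blocks, list(
      nn_conv(cin[i], ch[i], k = k, stride = 2, pad = (k - 1) %/% 2),
      nn_lreludrop(0.2, p)
    ))
  }
  net <- do.call(nn_network, c(blocks, list(nn_gap(),
                 nn_dense(ch[5], config$n_classes + 1))))
  nn_trace_shapes(net, config$image_side)
  nn_init(net)
  net$config <- config
  net$feature_dim <- ch[5]
  net$opt <- adam_new(lr = config$lr_d, beta1 = config$beta1,
                      beta2 = config$beta2, weight_decay = config$weight_decay)
  net
}

#' Sample latent noise
#'
#' @param n number of vectors.
#' @param config a [gan_config()].
#' @return a `latent_dim x n` matrix of standard-normal draws.
#' @export
sample_noise <- function(n, config) {
  matrix(stats::rnorm(config$latent_dim * n), config$latent_dim, n)
}

#' Generate images from noise
#'
#' @param generator network from [build_generator()].
#' @param z a `latent_dim x n` noise matrix.
#' @return an `[side, side, 3, n]` array with values in (-1, 1).
#' @export
generate <- function(generator, z) {
  if (!is.matrix(z)) z <- matrix(z, ncol = 1)
  if (nrow(z) != generator$config$latent_dim)
    stop("generate: noise length ", nrow(z), " != latent_dim ",
         generator$config$latent_dim)
  side <- generator$config$image_side
  chw_to_hwcn(nn_forward(generator, z, training = FALSE),
              side, side, ncol(z))
}

#' Classify images with the discriminator
#'
#' Runs the discriminator in inference mode (dropout off) and returns both
#' the (K+1)-class softmax probabilities and the pooled feature vectors.
#' The probability that an image is real is `1 - p[K+1]`.
#'
#' @param discriminator network from [build_discriminator()].
#' @param images an `[side, side, 3, n]` array (or one `[side, side, 3]`
#'   image) with values in `[-1, 1]`.
#' @return list with `probs` (`(K+1) x n`, columns summing to 1),
#'   `features` (`feature_dim x n`) and `logits`.
#' @export
discriminate <- function(discriminator, images) {
  side <- discriminator$config$image_side
  if (length(dim(images)) != 2) {  # [H,W,C,N] arrays; 2-d = channel-major
    if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
    d <- dim(images)
    if (d[1] != side || d[2] != side || d[3] != 3)
      stop("discriminate: expected ", side, "x", side, "x3 images, got ",
           paste(d[1:3], collapse = "x"))
    images <- hwcn_to_chw(images)
  }
  if (min(images) < -1 - 1e-6 || max(images) > 1 + 1e-6)
    warning("discriminate: input values outside [-1, 1]; normalize first")
  logits <- nn_forward(discriminator, images, training = FALSE)
  nl <- length(discriminator$layers)
  features <- discriminator$layers[[nl]]$x  # dense-layer input = pooled features
  list(probs = softmax_cols(logits), features = features, logits = logits)
}

#' One-line-per-layer architecture summary
#'
#' @param net a network from [build_generator()], [build_discriminator()]
#'   or the internal LeNet builder.
#' @return character vector (one line per layer), invisibly printed.
#' @export
network_summary <- function(net) {
  lines <- vapply(net$layers, function(ly) {
    shape <- if (!is.null(ly$w))
      sprintf(" [%d x %d + %d]", nrow(ly$w), ncol(ly$w), length(ly$b))
    else ""
    sp <- if (!is.null(ly$H)) sprintf(" @%dx%d", ly$H, ly$W) else ""
    paste0(ly$type, sp, shape)
  }, character(1))
  lines <- c(lines, sprintf("total parameters: %d", n_parameters(net)))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.gan_config <- function(x, ...) {
  cat("<gan_config> ", x$image_side, "x", x$image_side,
      " (base ", x$base, "), K = ", x$n_classes,
      ", latent ", x$latent_dim, ", batch ", x$batch_size,
      ", epochs ", x$epochs,
      "\n  G channels ", paste(x$gen_channels, collapse = "/"),
      " (", x$gen_kernel, "x", x$gen_kernel, "), D channels ",
      paste(x$disc_channels, collapse = "/"),
      " (", x$disc_kernel, "x", x$disc_kernel, ")",
      "\n  Adam lr_g ", x$lr_g, ", lr_d ", x$lr_d, ", beta1 ", x$beta1,
      ", decay ", x$weight_decay, ", dropout ", x$dropout,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# column-wise softmax with log-sum-exp stabilisation
softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}
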