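# The SGAN training loop: per iteration one discriminator step on
# L_supervised + L_unsupervised over (labeled, unlabeled, generated)
# minibatches, then one feature-matching generator step on half real /
# half generated images; validation accuracy is recorded every epoch and
# the best-accuracy parameter set is retained.

#' Draw one training minibatch
#'
#' Samples `m` labeled and `m` unlabeled images (with replacement when a
#' pool is smaller than `m`) and generates `m` images from fresh
#' standard-normal noise.
#'
#' @param split a `label_rate_split` whose pools have been stacked into
#'   batch arrays (see [train_sgan()]), or a list with `x_labeled`,
#'   `y_labeled`, `x_unlabeled` arrays.
#' @param generator network from [build_generator()].
#' @param m minibatch size.
#' @return list `x_labeled`, `y_labeled`, `x_unlabeled`, `x_generated`, `z`.
#' @export
make_minibatch <- function(split, generator, m) {
  side <- generator$config$image_side
  nl <- .nimg(split$x_labeled, side)
  nu <- .nimg(split$x_unlabeled, side)
  if (nl == 0) stop("make_minibatch: empty labeled pool")
  il <- sample.int(nl, m, replace = nl < m)
  iu <- if (nu > 0) sample.int(nu, m, replace = nu < m) else
    sample.int(nl, m, replace = nl < m)
  xu <- if (nu > 0) split$x_unlabeled else split$x_labeled
  z <- sample_noise(m, generator$config)
  fake <- if (length(dim(split$x_labeled)) == 4) generate(generator, z) else
    nn_forward(generator, z)
  list(x_labeled = .take_img(split$x_labeled, il, side),
       y_labeled = split$y_labeled[il],
       x_unlabeled = .take_img(xu, iu, side),
       x_generated = fake,
       z = z)
}

# subset images by sample index from either batch format
.take_img <- function(x, idx, side) {
  if (length(dim(x)) == 4) return(x[, , , idx, drop = FALSE])
  take_images(x, as.integer(idx), side * side)
}

#' Validation accuracy of the discriminator
#'
#' Predicts by argmax over the K real classes only (the fake class is
#' excluded, so its logit cannot affect the prediction).
#'
#' @param discriminator network from [build_discriminator()].
#' @param images `[s,s,3,n]` normalized image array.
#' @param labels zero-based true classes.
#' @return accuracy in percent.
#' @export
validate_discriminator <- function(discriminator, images, labels) {
  if (length(labels) == 0) stop("validate_discriminator: empty set")
  pred <- predict_labels(discriminator, images)
  mean(pred == labels) * 100
}

#' Predict crop/weed labels
#'
#' @param discriminator network from [build_discriminator()].
#' @param images `[s,s,3,n]` normalized image array.
#' @return zero-based predicted classes (argmax over real classes).
#' @export
predict_labels <- function(discriminator, images) {
  k <- discriminator$config$n_classes
  out <- discriminate(discriminator, images)
  max.col(t(out$probs[seq_len(k), , drop = FALSE])) - 1L
}

#' Train the semi-supervised GAN
#'
#' Runs `config$epochs` epochs of adversarial training.  One epoch is one
#' pass over the training pool in minibatches of `config$batch_size`; each
#' iteration performs one discriminator update ([gradient_step_d()]) and
#' one generator update ([gradient_step_g()]).  Inputs are normalized to
#' `[-1, 1]` (and resized to `config$image_side`) on entry.  Everything is
#' reproducible from `config$seed`.
#'
#' @param config a [gan_config()].
#' @param split a `label_rate_split` from [apply_label_rate()].
#' @param val_set labeled `field_samples` used for per-epoch validation.
#' @param log_path optional JSON-lines file receiving one record per epoch.
#' @param checkpoint_dir optional directory; the best-validation parameter
#'   sets are saved there as RDS.
#' @param verbose print per-epoch progress.
#' @return a `train_state` list: `config`, `losses` (per-epoch data frame
#'   with `l_supervised`, `l_unsupervised`, `l_d`, `l_g`), `val_accuracy`
#'   (percent, one per epoch), `best_epoch`, `best_val_accuracy`,
#'   `generator`, `discriminator` (final), and `best_params` (discriminator
#'   parameters at the best epoch).
#' @export
train_sgan <- function(config, split, val_set, log_path = NULL,
                       checkpoint_dir = NULL, verbose = FALSE) {
  if (length(split$labeled) == 0) stop("train_sgan: no labeled samples")
  if (length(val_set) == 0 || any(is.na(val_set$labels)))
    stop("train_sgan: val_set must be labeled and non-empty")
  side <- config$image_side
  set.seed(config$seed)
  gen <- build_generator(config)
  disc <- build_discriminator(config)
  pools <- list(
    x_labeled = hwcn_to_chw(as_image_batch(split$labeled, side)),
    y_labeled = split$labeled$labels,
    x_unlabeled = hwcn_to_chw(as_image_batch(split$unlabeled, side)))
  xval <- hwcn_to_chw(as_image_batch(val_set, side))
  yval <- val_set$labels
  m <- config$batch_size
  n_unl <- .nimg(pools$x_unlabeled, side)
  # one epoch = one pass over the full training pool (drop-last batching):
  # the iteration count, and hence the optimisation budget, does not
  # depend on the labeled rate
  n_pool <- .nimg(pools$x_labeled, side) + n_unl
  n_iter <- max(1L, n_pool %/% m)
  half <- m %/% 2
  losses <- matrix(NA_real_, config$epochs, 4,
                   dimnames = list(NULL, c("l_supervised", "l_unsupervised",
                                           "l_d", "l_g")))
  val_acc <- numeric(config$epochs)
  best <- list(epoch = 0L, acc = -Inf, params = NULL)
  if (!is.null(log_path)) unlink(log_path)
  for (epoch in seq_len(config$epochs)) {
    ep <- c(0, 0, 0, 0)
    for (it in seq_len(n_iter)) {
      mb <- make_minibatch(pools, gen, m)
      lb <- gradient_step_d(disc, mb,
                            unsup_includes_labeled = config$unsup_includes_labeled)
      # real half for feature matching: unlabeled images (fall back to
      # labeled when the unlabeled pool is empty)
      xu <- if (n_unl > 0) pools$x_unlabeled else pools$x_labeled
      nxu <- .nimg(xu, side)
      ir <- sample.int(nxu, half, replace = nxu < half)
      lg <- gradient_step_g(gen, disc, .take_img(xu, ir, side),
                            sample_noise(half, config))
      if (!is.finite(lb$l_d) || !is.finite(lg))
        stop("train_sgan: training diverged at epoch ", epoch,
             " (l_d = ", lb$l_d, ", l_g = ", lg, ")")
      ep <- ep + c(lb$l_supervised, lb$l_unsupervised, lb$l_d, lg)
    }
    losses[epoch, ] <- ep / n_iter
    val_acc[epoch] <- validate_discriminator(disc, xval, yval)
    if (val_acc[epoch] > best$acc) {
      best <- list(epoch = epoch, acc = val_acc[epoch],
                   params = nn_parameters(disc))
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(best, file.path(checkpoint_dir, "best_discriminator.rds"))
      }
    }
    if (!is.null(log_path)) {
      rec <- c(list(epoch = epoch), as.list(losses[epoch, ]),
               list(val_acc = val_acc[epoch]))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE, sep = "")
    }
    if (verbose)
      message(sprintf("epoch %3d  l_d %.4f  l_g %.4f  val %.1f%%",
                      epoch, losses[epoch, "l_d"], losses[epoch, "l_g"],
                      val_acc[epoch]))
  }
  structure(list(config = config, losses = as.data.frame(losses),
                 val_accuracy = val_acc, best_epoch = best$epoch,
                 best_val_accuracy = best$acc, best_params = best$params,
                 generator = gen, discriminator = disc),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat("<train_state> ", length(x$val_accuracy), " epochs; best val SSCA ",
      round(x$best_val_accuracy, 2), "% at epoch ", x$best_epoch, "\n",
      sep = "")
  invisible(x)
}

# discriminator with the best-validation parameters restored
best_discriminator <- function(state) {
  disc <- build_discriminator(state$config)
  nn_set_parameters(disc, state$best_params)
  disc
}
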