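# SGAN objectives.
#
# The discriminator minimises L_D = L_supervised + L_unsupervised:
#   L_supervised   = -E log p(y | x, y != fake)          (labeled data)
#   L_unsupervised = -E log(1 - p_fake(x_u))             (unlabeled data)
#                    -E log p_fake(G(z))                 (generated data)
# The generator minimises the feature-matching objective
#   L_G = || E f(x_real) - E f(G(z)) ||^2
# where f is the discriminator's pooled penultimate activation.
#
# The public loss functions operate on probability vectors (clamped before
# logs); training uses the logit-space versions below, which are the same
# quantities computed with log-sum-exp stabilisation together with their
# analytic gradients.

.P_EPS <- 1e-7

.clamp_probs <- function(p) pmin(pmax(p, .P_EPS), 1 - .P_EPS)

.as_prob_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  if (any(p < -1e-9) || any(abs(colSums(p) - 1) > 1e-6))
    stop("class probabilities must be non-negative and sum to 1 per column")
  p
}

#' Supervised discriminator loss
#'
#' Mean negative log probability of the true class, conditioned on the
#' sample being real: the K+1 class probabilities are renormalised over the
#' K real classes before the log, so the value does not depend on the
#' probability mass assigned to the fake class.
#'
#' @param probs `(K+1) x n` matrix of class probabilities (last row = fake
#'   class), columns summing to 1.
#' @param labels integer vector of true classes, zero-based, all `< K`.
#' @return non-negative scalar.
#' @export
supervised_loss <- function(probs, labels) {
  probs <- .as_prob_matrix(probs)
  k <- nrow(probs) - 1L
  if (length(labels) != ncol(probs))
    stop("supervised_loss: ", ncol(probs), " columns but ", length(labels),
         " labels")
  if (any(labels < 0 | labels >= k))
    stop("supervised_loss: labels must be in 0..K-1; the fake class is ",
         "never a ground-truth label")
  preal <- probs[seq_len(k), , drop = FALSE]
  preal <- sweep(preal, 2, colSums(preal), "/")  # condition on y < K+1
  py <- .clamp_probs(preal[cbind(labels + 1L, seq_along(labels))])
  mean(-log(py))
}

#' Unsupervised discriminator loss
#'
#' `-mean log(1 - p_fake)` over unlabeled real images plus
#' `-mean log(p_fake)` over generated images: the first term pushes real
#' data into the K real classes, the second labels generated data as fake.
#'
#' @param probs_unlabeled,probs_generated `(K+1) x n` probability matrices.
#' @return non-negative scalar.
#' @export
unsupervised_loss <- function(probs_unlabeled, probs_generated) {
  pu <- .as_prob_matrix(probs_unlabeled)
  pg <- .as_prob_matrix(probs_generated)
  if (ncol(pu) == 0 || ncol(pg) == 0)
    stop("unsupervised_loss: empty batch")
  pf_u <- .clamp_probs(pu[nrow(pu), ])
  pf_g <- .clamp_probs(pg[nrow(pg), ])
  mean(-log(1 - pf_u)) + mean(-log(pf_g))
}

#' Combine the discriminator loss terms
#'
#' @param supervised,unsupervised finite non-negative loss values.
#' @return a `loss_breakdown` list with `l_supervised`, `l_unsupervised`
#'   and their sum `l_d`.
#' @export
discriminator_loss <- function(supervised, unsupervised) {
  if (!is.finite(supervised) || !is.finite(unsupervised))
    stop("discriminator_loss: non-finite loss term (supervised = ",
         supervised, ", unsupervised = ", unsupervised, ")")
  structure(list(l_supervised = supervised, l_unsupervised = unsupervised,
                 l_d = supervised + unsupervised),
            class = "loss_breakdown")
}

#' Feature-matching generator loss
#'
#' Squared Euclidean distance between the batch-mean discriminator features
#' of real and generated images.
#'
#' @param features_real,features_fake `feature_dim x n` matrices.
#' @return non-negative scalar, zero iff the mean features coincide.
#' @export
feature_matching_loss <- function(features_real, features_fake) {
  if (is.null(dim(features_real))) features_real <- matrix(features_real, ncol = 1)
  if (is.null(dim(features_fake))) features_fake <- matrix(features_fake, ncol = 1)
  if (nrow(features_real) != nrow(features_fake))
    stop("feature_matching_loss: feature length mismatch (",
         nrow(features_real), " vs ", nrow(features_fake), ")")
  sum((rowMeans(features_real) - rowMeans(features_fake))^2)
}

## ---- logit-space losses and gradients (training path) --------------------

.lse_cols <- function(l) {
  m <- apply(l, 2, max)
  m + log(colSums(exp(sweep(l, 2, m))))
}

# supervised: loss_i = lse(real logits) - logit[y_i]; grad zero on fake row
.sup_logit_grad <- function(logits, labels) {
  k <- nrow(logits) - 1L
  n <- ncol(logits)
  lr <- logits[seq_len(k), , drop = FALSE]
  sm <- softmax_cols(lr)
  loss <- mean(.lse_cols(lr) - lr[cbind(labels + 1L, seq_len(n))])
  g <- rbind(sm, 0)
  g[cbind(labels + 1L, seq_len(n))] <- g[cbind(labels + 1L, seq_len(n))] - 1
  list(loss = loss, grad = g / n)
}

# real-data term: loss_i = lse(all) - lse(real) = -log(1 - p_fake)
.unsup_real_logit_grad <- function(logits) {
  k <- nrow(logits) - 1L
  n <- ncol(logits)
  s_all <- softmax_cols(logits)
  s_real <- rbind(softmax_cols(logits[seq_len(k), , drop = FALSE]), 0)
  loss <- mean(.lse_cols(logits) - .lse_cols(logits[seq_len(k), , drop = FALSE]))
  list(loss = loss, grad = (s_all - s_real) / n)
}

# generated-data term: loss_i = lse(all) - logit_fake = -log p_fake
.unsup_fake_logit_grad <- function(logits) {
  n <- ncol(logits)
  s_all <- softmax_cols(logits)
  loss <- mean(.lse_cols(logits) - logits[nrow(logits), ])
  g <- s_all
  g[nrow(logits), ] <- g[nrow(logits), ] - 1
  list(loss = loss, grad = g / n)
}

# number of images in an [H,W,C,N] array or channel-major batch
.nimg <- function(x, side) {
  if (length(dim(x)) == 4) dim(x)[4] else ncol(x) %/% (side * side)
}

# concatenate [H,W,C,N] image batches into one channel-major batch
.cat_chw <- function(...) {
  do.call(cbind, lapply(list(...), function(p) {
    if (length(dim(p)) == 4) hwcn_to_chw(p) else p
  }))
}

#' One discriminator update
#'
#' Performs a single Adam step on `L_D = L_supervised + L_unsupervised`
#' over a minibatch of labeled, unlabeled and generated images (the
#' generator is not touched: generated images enter as data).
#'
#' @param discriminator network from [build_discriminator()]; updated in
#'   place.
#' @param batch list with `x_labeled` (`[s,s,3,m]`), `y_labeled`
#'   (zero-based integer vector), `x_unlabeled`, `x_generated`.
#' @param unsup_includes_labeled if `TRUE`, labeled images also enter the
#'   real-data term of the unsupervised loss.
#' @return a `loss_breakdown` for the minibatch.
#' @export
gradient_step_d <- function(discriminator, batch,
                            unsup_includes_labeled = FALSE) {
  side <- discriminator$config$image_side
  nl <- .nimg(batch$x_labeled, side)
  nu <- .nimg(batch$x_unlabeled, side)
  ng <- .nimg(batch$x_generated, side)
  if (nl == 0) stop("gradient_step_d: empty labeled batch")
  x <- .cat_chw(batch$x_labeled, batch$x_unlabeled, batch$x_generated)
  logits <- nn_forward(discriminator, x, training = TRUE)
  i_l <- seq_len(nl)
  i_u <- nl + seq_len(nu)
  i_g <- nl + nu + seq_len(ng)
  sup <- .sup_logit_grad(logits[, i_l, drop = FALSE], batch$y_labeled)
  i_real <- if (unsup_includes_labeled) c(i_l, i_u) else i_u
  unr <- .unsup_real_logit_grad(logits[, i_real, drop = FALSE])
  unf <- .unsup_fake_logit_grad(logits[, i_g, drop = FALSE])
  lb <- discriminator_loss(sup$loss, unr$loss + unf$loss)
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[, i_l] <- dlogits[, i_l] + sup$grad
  dlogits[, i_real] <- dlogits[, i_real] + unr$grad
  dlogits[, i_g] <- dlogits[, i_g] + unf$grad
  if (!all(is.finite(dlogits)))
    stop("gradient_step_d: non-finite gradient; training diverged")
  nn_backward(discriminator, dlogits, input_grad = FALSE)
  adam_step(discriminator$opt, discriminator)
  lb
}

#' One generator update
#'
#' Freezes the discriminator, feeds it half real and half generated images,
#' and performs one Adam step on the feature-matching loss.  The
#' discriminator's parameters are bit-identical before and after.
#'
#' @param generator network from [build_generator()]; updated in place.
#' @param discriminator frozen feature extractor.
#' @param real_images `[s,s,3,m/2]` array of real images.
#' @param z `latent_dim x m/2` noise matrix.
#' @return the feature-matching loss value for the batch.
#' @export
gradient_step_g <- function(generator, discriminator, real_images, z) {
  fake <- nn_forward(generator, z, training = TRUE)  # chw, side x side
  side <- generator$config$image_side
  nr <- .nimg(real_images, side)
  nf <- ncol(z)
  x <- .cat_chw(real_images, fake)
  nn_forward(discriminator, x, training = FALSE)  # dropout off: clean features
  nlayer <- length(discriminator$layers)
  feats <- discriminator$layers[[nlayer]]$x      # pooled features, F x (nr+nf)
  fr <- feats[, seq_len(nr), drop = FALSE]
  ff <- feats[, nr + seq_len(nf), drop = FALSE]
  diff <- rowMeans(fr) - rowMeans(ff)
  lg <- sum(diff^2)
  if (!is.finite(lg)) stop("gradient_step_g: non-finite loss")
  # dL/d f(fake_j) = -2/nf * diff for every fake column; real columns get 0
  dfeats <- matrix(0, nrow(feats), ncol(feats))
  dfeats[, nr + seq_len(nf)] <- -2 * diff / nf
  gap_idx <- nlayer - 1L  # global-average-pool layer feeding the dense head
  dximg <- nn_backward(discriminator, dfeats, from = gap_idx, wgrad = FALSE)
  hw <- side * side
  dfake <- dximg[, hw * nr + seq_len(hw * nf), drop = FALSE]
  nn_backward(generator, dfake, input_grad = FALSE)
  adam_step(generator$opt, generator)
  lg
}
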