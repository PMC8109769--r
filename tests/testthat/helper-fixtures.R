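# Shared fixtures: a small 32-pixel configuration and dataset so unit
# tests run in seconds; the acceptance tests use the full 64-pixel
# defaults.

ns <- asNamespace("sganweeds")

tiny_cfg <- function(...) {
  args <- list(image_side = 32, base = 2, latent_dim = 8, batch_size = 4,
               gen_channels = c(8, 6, 5, 4), disc_channels = c(4, 5, 6, 7, 8),
               dropout = 0, epochs = 2, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(gan_config, args)
}

tiny_field_params <- function(seed = 5) {
  field_params(resolution = 32, n_plants = c(2, 4),
               crop_leaf_radius = c(4, 7), weed_blade_length = c(6, 11),
               weed_blade_width = c(1.0, 2.0), seed = seed)
}

.tiny_ds_cache <- new.env(parent = emptyenv())
tiny_dataset <- function(n_per_class = 10, seed = 5) {
  key <- paste0("d", n_per_class, "_", seed)
  if (is.null(.tiny_ds_cache[[key]]))
    .tiny_ds_cache[[key]] <- generate_dataset(n_per_class,
                                              tiny_field_params(seed))
  .tiny_ds_cache[[key]]
}

# random normalized image batch
rand_images <- function(side, n, seed = 1) {
  set.seed(seed)
  array(stats::runif(side * side * 3 * n, -1, 1), c(side, side, 3, n))
}

# multiply all weights so activations / gradients are O(1) in
# finite-difference tests (fresh init is deliberately near zero)
inflate_weights <- function(net, f) {
  for (ly in net$layers) if (!is.null(ly$w)) ly$w <- ly$w * f
  invisible(net)
}

# brute-force loss oracles working one sample at a time on probabilities
oracle_sup_loss <- function(probs, labels) {
  k <- nrow(probs) - 1
  vals <- numeric(ncol(probs))
  for (i in seq_len(ncol(probs))) {
    p <- probs[seq_len(k), i]
    vals[i] <- -log(p[labels[i] + 1] / sum(p))
  }
  mean(vals)
}

oracle_unsup_loss <- function(pu, pg) {
  a <- numeric(ncol(pu)); b <- numeric(ncol(pg))
  for (i in seq_len(ncol(pu))) a[i] <- -log(1 - pu[nrow(pu), i])
  for (i in seq_len(ncol(pg))) b[i] <- -log(pg[nrow(pg), i])
  mean(a) + mean(b)
}

# random probability matrix with K+1 rows
rand_probs <- function(k1, n, seed = 1) {
  set.seed(seed)
  p <- matrix(stats::rexp(k1 * n), k1, n)
  sweep(p, 2, colSums(p), "/")
}
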