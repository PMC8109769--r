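# Confusion-matrix accuracy (SSCA / SCA), the supervised LeNet5-style
# baseline trained on labeled data only, and the labeled-rate comparison
# harness.  SSCA and SCA are the same statistic, (TP + TN) / (P + N); the
# distinction is purely which training regime produced the classifier.

#' Confusion matrix over the K real classes
#'
#' @param true_labels,predicted_labels zero-based integer vectors of equal
#'   length, all `< n_classes`.
#' @param n_classes number of real classes K.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(true_labels, predicted_labels, n_classes = 2) {
  if (length(true_labels) != length(predicted_labels))
    stop("confusion: length mismatch")
  if (any(c(true_labels, predicted_labels) < 0) ||
      any(c(true_labels, predicted_labels) >= n_classes))
    stop("confusion: labels must be in 0..K-1")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = c("crop", "weed")[seq_len(n_classes)],
                               predicted = c("crop", "weed")[seq_len(n_classes)]))
  for (i in seq_along(true_labels))
    cm[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      cm[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  cm
}

#' Classification accuracy from a confusion matrix
#'
#' `(TP + TN) / (P + N) * 100`, i.e. trace over total; for K = 2 the
#' "positive" class is class 0 (crop), though the statistic is symmetric.
#'
#' @param cm matrix from [confusion()].
#' @return accuracy in percent.
#' @export
accuracy_from_cm <- function(cm) {
  if (sum(cm) == 0) stop("accuracy_from_cm: empty confusion matrix")
  sum(diag(cm)) / sum(cm) * 100
}

# LeNet5-style small CNN for the supervised baseline: two 5x5 conv +
# average-pool stages, then dense 120 -> 84 -> K with a softmax readout
build_lenet <- function(config) {
  side <- config$image_side
  flat_side <- ((side - 4) / 2 - 4) / 2
  net <- nn_network(
    nn_conv(3, 6, k = 5), nn_relu(), nn_avgpool(2),
    nn_conv(6, 16, k = 5), nn_relu(), nn_avgpool(2),
    nn_to_mat(),
    nn_dense(16 * flat_side^2, 120), nn_relu(),
    nn_dense(120, 84), nn_relu(),
    nn_dense(84, config$n_classes)
  )
  nn_trace_shapes(net, side)
  nn_init(net)
  net$config <- config
  net$opt <- adam_new(lr = config$lr_d, beta1 = config$beta1,
                      beta2 = config$beta2, weight_decay = config$weight_decay)
  net
}

# one softmax cross-entropy Adam step; returns the batch loss
.ce_step <- function(net, x, y) {
  if (length(dim(x)) == 4) x <- hwcn_to_chw(x)
  logits <- nn_forward(net, x, training = TRUE)
  sm <- softmax_cols(logits)
  n <- ncol(logits)
  loss <- mean(.lse_cols(logits) - logits[cbind(y + 1L, seq_len(n))])
  g <- sm
  g[cbind(y + 1L, seq_len(n))] <- g[cbind(y + 1L, seq_len(n))] - 1
  nn_backward(net, g / n, input_grad = FALSE)
  adam_step(net$opt, net)
  loss
}

#' Supervised CNN baseline (SCA)
#'
#' Trains a small LeNet5-style CNN on the labeled subset only, keeps the
#' parameters with the best validation accuracy, and reports test accuracy
#' from the confusion matrix — the supervised classification accuracy
#' (SCA) reference against which the semi-supervised SSCA is compared.
#'
#' @param labeled_subset labeled `field_samples` (the only training data).
#' @param val_set,test_set labeled `field_samples`.
#' @param config a [gan_config()]; `epochs`, `batch_size`, `lr_d`, Adam
#'   moments and `seed` are honoured.
#' @return list with `accuracy_pct` (test SCA), `confusion`,
#'   `val_accuracy` history and the trained `net`.
#' @export
supervised_baseline <- function(labeled_subset, val_set, test_set, config) {
  if (length(labeled_subset) == 0)
    stop("supervised_baseline: empty labeled subset")
  side <- config$image_side
  set.seed(config$seed)
  net <- build_lenet(config)
  x <- as_image_batch(labeled_subset, side)
  y <- labeled_subset$labels
  xv <- hwcn_to_chw(as_image_batch(val_set, side))
  xt <- hwcn_to_chw(as_image_batch(test_set, side))
  n <- length(y)
  m <- min(config$batch_size, n)
  val_acc <- numeric(config$epochs)
  best <- list(acc = -Inf, params = NULL)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = m)) {
      ii <- ord[start:min(start + m - 1, n)]
      .ce_step(net, x[, , , ii, drop = FALSE], y[ii])
    }
    pred <- max.col(t(nn_forward(net, xv))) - 1L
    val_acc[epoch] <- mean(pred == val_set$labels) * 100
    if (val_acc[epoch] > best$acc)
      best <- list(acc = val_acc[epoch], params = nn_parameters(net))
  }
  nn_set_parameters(net, best$params)
  pred_test <- max.col(t(nn_forward(net, xt))) - 1L
  cm <- confusion(test_set$labels, pred_test, config$n_classes)
  list(accuracy_pct = accuracy_from_cm(cm), confusion = cm,
       val_accuracy = val_acc, net = net)
}

#' Test-set SSCA of a trained SGAN
#'
#' Restores the best-validation discriminator from a [train_sgan()] state
#' and reports test accuracy from the confusion matrix (Eq-5-style SSCA).
#'
#' @param state a `train_state`.
#' @param test_set labeled `field_samples`.
#' @return list with `accuracy_pct` and `confusion`.
#' @export
evaluate_sgan <- function(state, test_set) {
  disc <- best_discriminator(state)
  xt <- as_image_batch(test_set, state$config$image_side)
  pred <- predict_labels(disc, xt)
  cm <- confusion(test_set$labels, pred, state$config$n_classes)
  list(accuracy_pct = accuracy_from_cm(cm), confusion = cm)
}

#' Labeled-rate comparison harness
#'
#' For each labeled rate and seed, partitions the same training pool with
#' [apply_label_rate()], trains the SGAN on labeled + unlabeled data (SSCA)
#' and the supervised CNN baseline on the identical labeled subset alone
#' (SCA), and reports test accuracies.  A custom per-image classifier can
#' be plugged in to replace the bundled baseline.
#'
#' @param rates labeled rates in (0, 1].
#' @param dataset list with labeled `train`, `val`, `test` `field_samples`
#'   (e.g. from [split_train_val_test()]).
#' @param config a [gan_config()]; each run reseeds with the run seed.
#' @param seeds integer vector; every (rate, method) cell is run once per
#'   seed.
#' @param baseline function `(labeled_subset, val_set, test_set, config)`
#'   returning a list with `accuracy_pct`; defaults to
#'   [supervised_baseline()].
#' @param csv_path optional output CSV (`method,rate,seed,accuracy_pct`).
#' @param verbose print progress.
#' @return data frame with columns `method` ("sgan" or "supervised_cnn"),
#'   `rate`, `seed`, `accuracy_pct` (NA for failed sub-runs).
#' @export
compare_label_rates <- function(rates, dataset, config, seeds = 1:3,
                                baseline = supervised_baseline,
                                csv_path = NULL, verbose = FALSE) {
  if (any(rates <= 0 | rates > 1))
    stop("compare_label_rates: rates must be in (0, 1]")
  rows <- list()
  for (rate in rates) {
    for (seed in seeds) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      split <- apply_label_rate(dataset$train, rate, seed = seed)
      ssca <- tryCatch({
        st <- train_sgan(cfg, split, dataset$val)
        evaluate_sgan(st, dataset$test)$accuracy_pct
      }, error = function(e) {
        warning("sgan run failed (rate ", rate, ", seed ", seed, "): ",
                conditionMessage(e))
        NA_real_
      })
      sca <- tryCatch(
        baseline(split$labeled, dataset$val, dataset$test, cfg)$accuracy_pct,
        error = function(e) {
          warning("baseline run failed (rate ", rate, ", seed ", seed,
                  "): ", conditionMessage(e))
          NA_real_
        })
      rows[[length(rows) + 1L]] <-
        data.frame(method = c("sgan", "supervised_cnn"), rate = rate,
                   seed = seed, accuracy_pct = c(ssca, sca))
      if (verbose)
        message(sprintf("rate %.0f%% seed %d: SSCA %.1f%%  SCA %.1f%%",
                        rate * 100, seed, ssca, sca))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}

#' Plot accuracy against labeled rate
#'
#' Mean test accuracy per method across seeds, with one point per run —
#' the semi-supervised (SSCA) versus supervised (SCA) comparison figure.
#'
#' @param tab data frame from [compare_label_rates()] or
#'   [run_gain_experiment()].
#' @param path optional PNG path; if `NULL`, draws on the active device.
#' @return `invisible(tab)`.
#' @export
plot_comparison <- function(tab, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  methods <- unique(tab$method)
  cols <- stats::setNames(c("forestgreen", "sienna")[seq_along(methods)],
                          methods)
  graphics::plot(NULL, xlim = range(tab$rate) * 100, ylim = c(40, 100),
                 xlab = "labeled rate (%)", ylab = "test accuracy (%)",
                 main = "Semi-supervised (SSCA) vs supervised (SCA)")
  for (m in methods) {
    sub <- tab[tab$method == m & is.finite(tab$accuracy_pct), ]
    graphics::points(sub$rate * 100, sub$accuracy_pct, col = cols[m],
                     pch = 1)
    agg <- stats::aggregate(accuracy_pct ~ rate, sub, mean)
    graphics::lines(agg$rate * 100, agg$accuracy_pct, col = cols[m],
                    lwd = 2, type = "b", pch = 19)
  }
  graphics::legend("bottomright", legend = methods, col = cols[methods],
                   lwd = 2)
  invisible(tab)
}

#' Scaled-down semi-supervised gain experiment
#'
#' The package's headline experiment on synthetic field imagery: for each
#' training seed, trains the SGAN at a low and a high labeled rate plus
#' the supervised CNN baseline on the identical low-rate labeled subset,
#' and reports test accuracies.  Quantifies (i) the semi-supervised gain
#' SSCA - SCA when most labels are withheld and (ii) the growth of SSCA
#' with the labeled rate.
#'
#' @param seeds training seeds; each (method, rate) cell is run once per
#'   seed on the same dataset.
#' @param config a [gan_config()]; defaults to the desk-scale profile.
#' @param n_train_per_class,n_eval_per_class images per class in the
#'   training pool and in each of the validation/test sets.
#' @param rate_low,rate_high labeled rates compared.
#' @param data_seed seed for the synthetic dataset (train/val/test use
#'   `data_seed`, `data_seed + 1`, `data_seed + 2`).
#' @param field procedural-imagery parameters ([field_params()]); the seed
#'   element is overridden by `data_seed`.
#' @param verbose print per-run progress.
#' @return data frame with columns `method`, `rate`, `seed`,
#'   `accuracy_pct`; the separability-oracle accuracy of the training pool
#'   is attached as attribute `oracle_acc`.
#' @export
run_gain_experiment <- function(seeds = 1:3, config = gan_config_desk(),
                                n_train_per_class = 100,
                                n_eval_per_class = 50,
                                rate_low = 0.2, rate_high = 0.8,
                                data_seed = 101, field = field_params(),
                                verbose = FALSE) {
  fp <- field
  fp$seed <- as.integer(data_seed)
  train_pool <- generate_dataset(n_train_per_class, fp)
  fp$seed <- as.integer(data_seed + 1)
  val <- generate_dataset(n_eval_per_class, fp)
  fp$seed <- as.integer(data_seed + 2)
  test <- generate_dataset(n_eval_per_class, fp)
  rows <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    for (rate in c(rate_low, rate_high)) {
      split <- apply_label_rate(train_pool, rate, seed = seed)
      st <- train_sgan(cfg, split, val)
      acc <- evaluate_sgan(st, test)$accuracy_pct
      rows[[length(rows) + 1L]] <-
        data.frame(method = "sgan", rate = rate, seed = seed,
                   accuracy_pct = acc)
      if (verbose)
        message(sprintf("sgan rate %.0f%% seed %d: SSCA %.1f%%",
                        rate * 100, seed, acc))
      if (rate == rate_low) {
        sca <- supervised_baseline(split$labeled, val, test, cfg)$accuracy_pct
        rows[[length(rows) + 1L]] <-
          data.frame(method = "supervised_cnn", rate = rate, seed = seed,
                     accuracy_pct = sca)
        if (verbose)
          message(sprintf("lenet rate %.0f%% seed %d: SCA %.1f%%",
                          rate * 100, seed, sca))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "oracle_acc") <- separability_oracle(train_pool)
  out
}
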