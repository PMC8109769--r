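# Dataset plumbing: directory loading through EBImage, [-1, 1] pixel
# normalisation, stratified train/val/test splitting and the labeled-rate
# partition used by the semi-supervised experiments.

round_half_up <- function(x) floor(x + 0.5)

#' Image sample collection
#'
#' Lightweight container pairing images with (possibly missing) class
#' labels.  Labels are zero-based: 0 = crop, 1 = weed; the discriminator's
#' fake class (index K) never appears as a ground-truth label.
#'
#' @param images list of `H x W x 3` numeric arrays.
#' @param labels integer vector (NA for unlabeled samples), or `NULL`.
#' @param paths optional character vector of source paths.
#' @return a `field_samples` object.
#' @export
field_samples <- function(images, labels = NULL, paths = NULL) {
  n <- length(images)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  if (length(labels) != n) stop("field_samples: labels length mismatch")
  if (is.null(paths)) paths <- rep(NA_character_, n)
  structure(list(images = images, labels = as.integer(labels),
                 paths = paths), class = "field_samples")
}

#' @export
length.field_samples <- function(x) length(x$images)

#' @export
`[.field_samples` <- function(x, i) {
  field_samples(x$images[i], x$labels[i], x$paths[i])
}

#' @export
print.field_samples <- function(x, ...) {
  lab <- x$labels[!is.na(x$labels)]
  cat("<field_samples> ", length(x), " images (",
      sum(!is.na(x$labels)), " labeled; class counts: ",
      paste(table(factor(lab, levels = 0:1)), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

c_samples <- function(a, b) {
  field_samples(c(a$images, b$images), c(a$labels, b$labels),
                c(a$paths, b$paths))
}

#' Load a one-folder-per-class image directory
#'
#' Reads `root/<class>/*.{png,jpg,jpeg}` in lexicographic order; each image
#' is paired with the index of its class in `class_names` (zero-based).
#' Undecodable files are skipped with a warning.
#'
#' @param root dataset directory.
#' @param class_names ordered class names; default `c("crop", "weed")`.
#' @return a `field_samples` object with raw pixel values in `[0, 255]`.
#' @export
load_image_dir <- function(root, class_names = c("crop", "weed")) {
  images <- list(); labels <- integer(); paths <- character()
  for (ci in seq_along(class_names)) {
    dir <- file.path(root, class_names[ci])
    if (!dir.exists(dir))
      stop("load_image_dir: missing class directory '", dir, "'")
    files <- sort(list.files(dir, pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0)
      stop("load_image_dir: class directory '", dir, "' contains no images")
    for (f in files) {
      img <- tryCatch(read_raw_image(f), error = function(e) {
        warning("skipping undecodable image '", f, "': ",
                conditionMessage(e))
        NULL
      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, ci - 1L)
      paths <- c(paths, f)
    }
  }
  field_samples(images, labels, paths)
}

# EBImage returns [x, y] (or [x, y, c]) intensities in [0, 1]
read_raw_image <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Normalize a raw image for training
#'
#' Resizes to `side x side` (bilinear) and maps each pixel value v in
#' `[0, 255]` to `v / 127.5 - 1`, so the result lies in `[-1, 1]`.
#'
#' @param raw `H x W x 3` array with values in `[0, 255]`.
#' @param side output side; must be divisible by 16.
#' @return `side x side x 3` array in `[-1, 1]`.
#' @export
normalize_image <- function(raw, side) {
  if (side %% 16 != 0)
    stop("normalize_image: side must be divisible by 16, got ", side)
  d <- dim(raw)
  if (d[1] != side || d[2] != side) {
    im <- EBImage::Image(raw / 255, colormode = "Color")
    raw <- EBImage::imageData(EBImage::resize(im, side, side,
                                              filter = "bilinear")) * 255
    raw <- pmin(pmax(raw, 0), 255)
  }
  raw / 127.5 - 1
}

#' Invert the pixel normalisation
#'
#' @param img array in `[-1, 1]`.
#' @return array in `[0, 255]` (no resizing is undone).
#' @export
denormalize_image <- function(img) (img + 1) * 127.5

#' Stratified train/validation/test split
#'
#' Shuffles with the given seed and partitions each class according to
#' `fractions`, so per-class proportions match the overall fractions to
#' within one sample.
#'
#' @param samples a labeled `field_samples` object.
#' @param fractions three non-negative numbers summing to 1.
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` (`field_samples`) and
#'   `fractions`.
#' @export
split_train_val_test <- function(samples, fractions = c(0.70, 0.15, 0.15),
                                 seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0))
    stop("split_train_val_test: fractions must be non-negative and sum to 1")
  if (length(samples) == 0) stop("split_train_val_test: no samples")
  if (any(is.na(samples$labels)))
    stop("split_train_val_test: all samples must be labeled")
  idx_tr <- idx_va <- idx_te <- integer()
  set.seed(seed)
  for (cl in sort(unique(samples$labels))) {
    ii <- which(samples$labels == cl)
    if (length(ii) < 3)
      stop("split_train_val_test: class ", cl, " has fewer than 3 samples")
    ii <- sample(ii)
    n <- length(ii)
    n_tr <- round_half_up(fractions[1] * n)
    n_va <- min(round_half_up(fractions[2] * n), n - n_tr)
    idx_tr <- c(idx_tr, ii[seq_len(n_tr)])
    idx_va <- c(idx_va, ii[n_tr + seq_len(n_va)])
    idx_te <- c(idx_te, ii[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  list(train = samples[idx_tr], val = samples[idx_va],
       test = samples[idx_te], fractions = fractions)
}

#' Labeled/unlabeled counts at a given labeled rate
#'
#' `round(rate * n)` (half up) labeled images, the remainder unlabeled.
#'
#' @param n pool size.
#' @param rate labeled rate in (0, 1].
#' @return named vector `c(labeled =, unlabeled =)`.
#' @export
label_rate_counts <- function(n, rate) {
  if (rate <= 0 || rate > 1)
    stop("label_rate_counts: rate must be in (0, 1], got ", rate)
  l <- round_half_up(rate * n)
  c(labeled = l, unlabeled = n - l)
}

#' Partition a training pool into labeled and unlabeled subsets
#'
#' Selects `round(rate * N)` samples (class-stratified, seed-deterministic)
#' to keep their labels; the remaining samples have labels stripped and
#' form the unlabeled pool.
#'
#' @param train_pool labeled `field_samples`.
#' @param rate labeled rate in (0, 1].
#' @param seed integer seed.
#' @return a `label_rate_split` list: `rate`, `labeled`, `unlabeled`.
#' @export
apply_label_rate <- function(train_pool, rate, seed = 1L) {
  n <- length(train_pool)
  total <- label_rate_counts(n, rate)[["labeled"]]
  if (any(is.na(train_pool$labels)))
    stop("apply_label_rate: training pool must be fully labeled")
  classes <- sort(unique(train_pool$labels))
  # per-class quotas: round half up, then repair the total by adjusting the
  # classes with the largest / smallest fractional remainders
  n_c <- vapply(classes, function(cl) sum(train_pool$labels == cl), numeric(1))
  quota <- round_half_up(rate * n_c)
  frac <- rate * n_c - floor(rate * n_c)
  while (sum(quota) > total) {
    i <- which(quota > 0)[which.min(frac[quota > 0])]
    quota[i] <- quota[i] - 1L
  }
  while (sum(quota) < total) {
    i <- which(quota < n_c)[which.max(frac[quota < n_c])]
    quota[i] <- quota[i] + 1L
  }
  set.seed(seed)
  lab_idx <- integer()
  for (j in seq_along(classes)) {
    ii <- which(train_pool$labels == classes[j])
    lab_idx <- c(lab_idx, sample(ii, quota[j]))
  }
  lab_idx <- sort(lab_idx)
  unl_idx <- setdiff(seq_len(n), lab_idx)
  unlabeled <- train_pool[unl_idx]
  unlabeled$labels <- rep(NA_integer_, length(unl_idx))
  structure(list(rate = rate, labeled = train_pool[lab_idx],
                 unlabeled = unlabeled),
            class = "label_rate_split")
}

#' @export
print.label_rate_split <- function(x, ...) {
  cat("<label_rate_split> rate ", x$rate * 100, "%: ",
      length(x$labeled), " labeled + ", length(x$unlabeled),
      " unlabeled\n", sep = "")
  invisible(x)
}

#' Write a split manifest CSV
#'
#' One row per image: `path,label,subset,labeled` with `labeled` in {0, 1}.
#'
#' @param split list from [split_train_val_test()].
#' @param path output CSV path.
#' @param lr_split optional [apply_label_rate()] result; training rows it
#'   marks unlabeled get `labeled = 0`.
#' @return the manifest data frame, invisibly.
#' @export
write_split_manifest <- function(split, path, lr_split = NULL) {
  rows <- do.call(rbind, lapply(c("train", "val", "test"), function(s) {
    fs <- split[[s]]
    if (length(fs) == 0) return(NULL)
    data.frame(path = fs$paths, label = fs$labels, subset = s,
               labeled = 1L, stringsAsFactors = FALSE)
  }))
  if (!is.null(lr_split)) {
    unl <- rows$subset == "train" & rows$path %in% lr_split$unlabeled$paths
    rows$labeled[unl] <- 0L
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

# stack a field_samples collection into a normalized [side, side, 3, n]
# batch array (raw 0..255 inputs are normalized on the way in)
as_image_batch <- function(samples, side) {
  n <- length(samples)
  out <- array(0, c(side, side, 3, n))
  for (i in seq_len(n)) {
    img <- samples$images[[i]]
    if (max(img) > 1.5) img <- normalize_image(img, side)
    else if (dim(img)[1] != side) img <- normalize_image(denormalize_image(img), side)
    out[, , , i] <- img
  }
  out
}
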