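# Directory loading, pixel normalisation, stratified splitting and the
# labeled-rate partition (including the published pea/strawberry pool
# arithmetic).

write_png_dataset <- function(dir, counts = c(crop = 2, weed = 1)) {
  for (cl in names(counts)) {
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(counts[[cl]])) {
      img <- EBImage::Image(array(stats::runif(16 * 16 * 3), c(16, 16, 3)),
                            colormode = "Color")
      EBImage::writeImage(img, file.path(dir, cl, sprintf("%s%02d.png",
                                                          letters[i], i)))
    }
  }
  dir
}

test_that("load_image_dir pairs images with class indices in stable order", {
  root <- write_png_dataset(withr::local_tempdir())
  s <- load_image_dir(root)
  expect_s3_class(s, "field_samples")
  expect_length(s, 3)
  expect_equal(s$labels, c(0L, 0L, 1L))
  expect_true(all(s$images[[1]] >= 0 & s$images[[1]] <= 255))
  # same dir loaded twice -> identical ordering, labels and pixels
  s2 <- load_image_dir(root)
  expect_identical(s$paths, s2$paths)
  expect_identical(s$images, s2$images)
  # missing class directory and empty class directory are errors
  expect_error(load_image_dir(file.path(root, "nope")), "missing class")
  empty <- withr::local_tempdir()
  dir.create(file.path(empty, "crop")); dir.create(file.path(empty, "weed"))
  expect_error(load_image_dir(empty), "no images")
  # an undecodable file is skipped with a warning
  writeLines("not a png", file.path(root, "crop", "zz.png"))
  expect_warning(s3 <- load_image_dir(root), "undecodable")
  expect_length(s3, 3)
})

test_that("normalize_image maps [0,255] onto [-1,1] and inverts exactly", {
  img0 <- array(0, c(32, 32, 3))
  expect_equal(unique(as.vector(normalize_image(img0, 32))), -1)
  img255 <- array(255, c(32, 32, 3))
  expect_equal(unique(as.vector(normalize_image(img255, 32))), 1)
  img127 <- array(127, c(32, 32, 3))
  expect_equal(unique(as.vector(normalize_image(img127, 32))),
               127 / 127.5 - 1, tolerance = 1e-12)
  # round trip without resizing is exact
  set.seed(1)
  raw <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  expect_equal(denormalize_image(normalize_image(raw, 32)), raw,
               tolerance = 1e-12)
  # monotone in each pixel
  a <- array(100, c(32, 32, 3)); b <- a; b[1, 1, 1] <- 200
  expect_gt(normalize_image(b, 32)[1, 1, 1], normalize_image(a, 32)[1, 1, 1])
  expect_error(normalize_image(raw, 30), "divisible by 16")
})

test_that("normalize_image resizes with bounded values", {
  set.seed(2)
  raw <- array(runif(50 * 50 * 3, 0, 255), c(50, 50, 3))
  out <- normalize_image(raw, 32)
  expect_equal(dim(out), c(32, 32, 3))
  expect_true(all(out >= -1 & out <= 1))
})

test_that("train/val/test split is stratified, exhaustive and seed-deterministic", {
  ds <- tiny_dataset(20)   # 40 images, 20 per class
  sp <- split_train_val_test(ds, c(0.7, 0.15, 0.15), seed = 3)
  expect_equal(length(sp$train), 28)
  expect_equal(length(sp$val), 6)
  expect_equal(length(sp$test), 6)
  for (part in list(sp$train, sp$val, sp$test))
    expect_equal(sum(part$labels == 0), sum(part$labels == 1))
  # disjoint and exhaustive
  all_paths <- sort(c(sp$train$paths, sp$val$paths, sp$test$paths))
  expect_equal(all_paths, sort(ds$paths))
  # determinism
  sp2 <- split_train_val_test(ds, c(0.7, 0.15, 0.15), seed = 3)
  expect_identical(sp$train$paths, sp2$train$paths)
  # degenerate fractions
  sp3 <- split_train_val_test(ds, c(1, 0, 0), seed = 1)
  expect_equal(length(sp3$train), 40)
  expect_equal(length(sp3$test), 0)
  # class with fewer than 3 samples cannot be stratified
  small <- ds[c(1, 3, 5, 2)]   # 3 crop, 1 weed
  expect_error(split_train_val_test(small, seed = 1), "fewer than 3")
})

test_that("labeled-rate arithmetic reproduces the published pea and strawberry pools", {
  # pea pool: 1300 training images
  for (row in list(c(0.20, 260, 1040), c(0.40, 520, 780),
                   c(0.60, 780, 520), c(0.80, 1040, 260))) {
    cnt <- label_rate_counts(1300, row[1])
    expect_equal(unname(cnt["labeled"]), row[2])
    expect_equal(unname(cnt["unlabeled"]), row[3])
  }
  # strawberry pool: 1400 training images
  for (row in list(c(0.20, 280, 1120), c(0.40, 560, 840),
                   c(0.60, 840, 560), c(0.80, 1120, 280))) {
    cnt <- label_rate_counts(1400, row[1])
    expect_equal(unname(cnt["labeled"]), row[2])
    expect_equal(unname(cnt["unlabeled"]), row[3])
  }
  expect_error(label_rate_counts(100, 0), "rate")
  expect_error(label_rate_counts(100, 1.2), "rate")
})

test_that("apply_label_rate partitions exactly, stratified, and keeps pools disjoint", {
  ds <- tiny_dataset(25)   # 50 images
  for (rate in c(0.2, 0.33, 0.5, 0.8, 1.0)) {
    lr <- apply_label_rate(ds, rate, seed = 4)
    n_lab <- floor(rate * 50 + 0.5)
    expect_equal(length(lr$labeled), n_lab)
    expect_equal(length(lr$labeled) + length(lr$unlabeled), 50)
    expect_length(intersect(lr$labeled$paths, lr$unlabeled$paths), 0)
    expect_true(all(is.na(lr$unlabeled$labels)))
    expect_false(anyNA(lr$labeled$labels))
    # stratification within one sample of rate * class size
    for (cl in 0:1)
      expect_lte(abs(sum(lr$labeled$labels == cl) - rate * 25), 1)
  }
  lr1 <- apply_label_rate(ds, 1.0, seed = 1)
  expect_length(lr1$unlabeled, 0)
  expect_identical(apply_label_rate(ds, 0.2, seed = 9)$labeled$paths,
                   apply_label_rate(ds, 0.2, seed = 9)$labeled$paths)
  expect_error(apply_label_rate(ds, 0, seed = 1), "rate")
})

test_that("split manifests record subset membership and label retention", {
  ds <- tiny_dataset(10)
  sp <- split_train_val_test(ds, seed = 2)
  lr <- apply_label_rate(sp$train, 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  man <- write_split_manifest(sp, path, lr)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), length(ds))
  expect_setequal(unique(got$subset), c("train", "val", "test"))
  expect_equal(sum(got$labeled == 0), length(lr$unlabeled))
  expect_true(all(got$labeled[got$subset != "train"] == 1))
})
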