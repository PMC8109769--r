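# Procedural crop/weed field imagery.
#
# Emulates nadir RGB patches of early-growth row crops: a brown textured
# soil background composited with green plant sprites.  Class 0 ("crop")
# renders broad-leaf rosettes, class 1 ("weed") renders tufts of thin
# curved grass blades, mimicking the morphology gap between dicot crops
# and grass weeds.  Colours are drawn directly in RGB; the two classes
# deliberately share the same green hue range so that separability comes
# from morphology and vegetation area, not colour.

#' Synthetic field parameters
#'
#' All sizes are in pixels at the configured resolution (defaults are tuned
#' for 64-pixel patches; scale plant sizes proportionally for larger
#' resolutions).
#'
#' @param resolution image side, >= 32 and divisible by 16.
#' @param n_plants integer range (min, max) of plants per image.
#' @param crop_leaf_radius range of crop leaf lengths (px).  Shrinking this
#'   toward the weed blade scale closes the morphology gap between the
#'   classes and makes the dataset harder.
#' @param crop_leaf_breadth leaf half-width as a fraction of leaf length.
#' @param weed_blade_length,weed_blade_width ranges for grass blades (px).
#' @param soil_rgb mean soil colour (R > G > B).
#' @param soil_var amplitude of the low-frequency soil brightness field.
#' @param noise_sd standard deviation of per-pixel additive noise.
#' @param seed integer seed used by [generate_dataset()] and
#'   [make_soil_background()].
#' @return a `field_params` list.
#' @export
field_params <- function(resolution = 64, n_plants = c(3, 6),
                         crop_leaf_radius = c(6, 10),
                         crop_leaf_breadth = 0.28,
                         weed_blade_length = c(10, 18),
                         weed_blade_width = c(1.0, 2.2),
                         soil_rgb = c(118, 86, 58), soil_var = 18,
                         noise_sd = 6, seed = 1L) {
  if (resolution < 32 || resolution %% 16 != 0)
    stop("field_params: resolution must be >= 32 and divisible by 16")
  if (noise_sd < 0) stop("field_params: noise_sd must be >= 0")
  for (r in list(n_plants, crop_leaf_radius, weed_blade_length,
                 weed_blade_width))
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0)
      stop("field_params: ranges must be positive (min, max) pairs")
  structure(list(resolution = as.integer(resolution),
                 n_plants = n_plants, crop_leaf_radius = crop_leaf_radius,
                 crop_leaf_breadth = crop_leaf_breadth,
                 weed_blade_length = weed_blade_length,
                 weed_blade_width = weed_blade_width,
                 soil_rgb = soil_rgb, soil_var = soil_var,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "field_params")
}

# soil texture from the current RNG stream
.soil <- function(params) {
  res <- params$resolution
  g <- matrix(stats::runif(36, -1, 1) * params$soil_var, 6, 6)
  field <- EBImage::imageData(EBImage::resize(EBImage::Image(g), res, res,
                                              filter = "bilinear"))
  img <- array(0, c(res, res, 3))
  scale <- c(1.0, 0.9, 0.8)  # keep the brown ordering R > G > B
  for (c in 1:3) {
    ch <- params$soil_rgb[c] + scale[c] * field
    if (params$noise_sd > 0)
      ch <- ch + stats::rnorm(res * res, sd = params$noise_sd)
    img[, , c] <- ch
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a bare-soil background
#'
#' Brown-dominated (mean R > G > B) texture: a low-frequency brightness
#' field plus per-pixel Gaussian noise; deterministic in `params$seed`.
#'
#' @param params a [field_params()].
#' @return `res x res x 3` array in `[0, 255]`.
#' @export
make_soil_background <- function(params) {
  set.seed(params$seed)
  .soil(params)
}

# green foliage colour for a sprite; G strictly dominates R and B per pixel
.foliage_rgb <- function(mask) {
  npx <- sum(mask)
  g0 <- stats::runif(1, 115, 165)
  G <- pmin(pmax(g0 + stats::rnorm(npx, sd = 8), 85), 200)
  R <- G * stats::runif(npx, 0.45, 0.75)
  B <- G * stats::runif(npx, 0.25, 0.50)
  cbind(R, G, B)
}

#' Render a single plant sprite
#'
#' Crops are rosettes of 4-8 broad elliptical leaves; weeds are tufts of
#' 5-12 thin curved blades.  Inside the alpha mask every pixel has G > R
#' and G > B.  Uses the current RNG stream (seed externally for
#' reproducible sprites).
#'
#' @param kind `"crop"` or `"weed"`.
#' @param params a [field_params()].
#' @return list with `rgb` (`s x s x 3`) and logical `mask` (`s x s`).
#' @export
render_plant <- function(kind, params) {
  kind <- match.arg(kind, c("crop", "weed"))
  if (kind == "crop") {
    smax <- 2 * ceiling(params$crop_leaf_radius[2]) + 3
    cx <- (smax + 1) / 2
    X <- matrix(seq_len(smax), smax, smax)
    Y <- t(X)
    mask <- matrix(FALSE, smax, smax)
    n_leaves <- sample(4:8, 1)
    for (i in seq_len(n_leaves)) {
      th <- stats::runif(1, 0, 2 * pi)
      a <- stats::runif(1, params$crop_leaf_radius[1],
                        params$crop_leaf_radius[2])
      A <- a / 2
      B <- max(0.9, params$crop_leaf_breadth * a)
      lx <- cx + (A + 0.5) * cos(th)
      ly <- cx + (A + 0.5) * sin(th)
      u <- (X - lx) * cos(th) + (Y - ly) * sin(th)
      v <- -(X - lx) * sin(th) + (Y - ly) * cos(th)
      mask <- mask | ((u / A)^2 + (v / B)^2 <= 1)
    }
  } else {
    smax <- 2 * ceiling(params$weed_blade_length[2]) + 3
    cx <- (smax + 1) / 2
    X <- matrix(seq_len(smax), smax, smax)
    Y <- t(X)
    mask <- matrix(FALSE, smax, smax)
    n_blades <- sample(5:12, 1)
    for (i in seq_len(n_blades)) {
      th0 <- stats::runif(1, 0, 2 * pi)
      L <- stats::runif(1, params$weed_blade_length[1],
                        params$weed_blade_length[2])
      kap <- stats::runif(1, -0.8, 0.8)
      w0 <- stats::runif(1, params$weed_blade_width[1],
                         params$weed_blade_width[2])
      t <- seq(0, 1, length.out = max(8, ceiling(2.5 * L)))
      px <- cx + t * L * cos(th0 + kap * t)
      py <- cx + t * L * sin(th0 + kap * t)
      r <- pmax(0.5, w0 * (1 - 0.6 * t)) / 2
      for (j in seq_along(t)) {
        d2 <- (X - px[j])^2 + (Y - py[j])^2
        mask <- mask | (d2 <= r[j]^2)
      }
    }
  }
  rgb <- array(0, c(smax, smax, 3))
  if (any(mask)) {
    cols <- .foliage_rgb(mask)
    for (c in 1:3) {
      ch <- rgb[, , c]
      ch[mask] <- cols[, c]
      rgb[, , c] <- ch
    }
  }
  list(rgb = rgb, mask = mask)
}

#' Generate one labeled field image
#'
#' Composites `n_plants` sprites of the requested class onto a soil
#' background.  Uses the current RNG stream.
#'
#' @param class_label 0 (crop) or 1 (weed).
#' @param params a [field_params()].
#' @return `res x res x 3` raw image array in `[0, 255]`.
#' @export
generate_sample <- function(class_label, params) {
  if (!class_label %in% c(0, 1))
    stop("generate_sample: class_label must be 0 (crop) or 1 (weed)")
  res <- params$resolution
  img <- .soil(params)
  n <- sample(seq(params$n_plants[1], params$n_plants[2]), 1)
  kind <- if (class_label == 0) "crop" else "weed"
  for (i in seq_len(n)) {
    sp <- render_plant(kind, params)
    s <- nrow(sp$mask)
    margin <- ceiling(s / 3)
    r0 <- round(stats::runif(1, 1 - margin, res - s + margin))
    c0 <- round(stats::runif(1, 1 - margin, res - s + margin))
    rr <- intersect(r0:(r0 + s - 1), 1:res)
    cc <- intersect(c0:(c0 + s - 1), 1:res)
    if (length(rr) == 0 || length(cc) == 0) next
    sr <- rr - r0 + 1
    sc <- cc - c0 + 1
    sub_mask <- sp$mask[sr, sc, drop = FALSE]
    for (ch in 1:3) {
      tile <- img[rr, cc, ch]
      tile[sub_mask] <- sp$rgb[sr, sc, ch][sub_mask]
      img[rr, cc, ch] <- tile
    }
  }
  img
}

#' Generate a balanced labeled dataset
#'
#' `2 * n_per_class` images (classes interleaved), deterministic in
#' `params$seed`.
#'
#' @param n_per_class images per class, >= 1.
#' @param params a [field_params()].
#' @return a labeled `field_samples` object (raw `[0, 255]` pixels).
#' @export
generate_dataset <- function(n_per_class, params) {
  if (n_per_class < 1) stop("generate_dataset: n_per_class must be >= 1")
  set.seed(params$seed)
  labels <- rep(c(0L, 1L), n_per_class)
  images <- lapply(labels, generate_sample, params = params)
  field_samples(images, labels,
                paths = sprintf("synthetic_%04d", seq_along(labels)))
}

#' Hand-crafted image features for the separability oracle
#'
#' `green_fraction`: share of pixels with G > R and G > B;
#' `compactness`: area / perimeter^2 of the green mask (high for broad
#' blobs, low for thin blades).
#'
#' @param img `H x W x 3` image (raw or normalized; the features only use
#'   channel order relations).
#' @return named numeric vector.
#' @export
image_features <- function(img) {
  mask <- img[, , 2] > img[, , 1] & img[, , 2] > img[, , 3]
  area <- sum(mask)
  if (area == 0) return(c(green_fraction = 0, compactness = 0))
  pad <- function(m, dr, dc) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(FALSE, H, W)
    rr <- seq_len(H) + dr; cc <- seq_len(W) + dc
    ok_r <- rr >= 1 & rr <= H; ok_c <- cc >= 1 & cc <= W
    out[ok_r, ok_c] <- m[rr[ok_r], cc[ok_c]]
    out
  }
  interior <- mask & pad(mask, 1, 0) & pad(mask, -1, 0) &
    pad(mask, 0, 1) & pad(mask, 0, -1)
  perim <- sum(mask & !interior)
  c(green_fraction = area / length(mask),
    compactness = area / max(perim, 1)^2)
}

#' Two-feature separability oracle
#'
#' Fits a logistic regression on (`green_fraction`, `compactness`) with a
#' stratified split and reports held-out accuracy, establishing
#' that the synthetic classes are learnable independently of any neural
#' network.
#'
#' @param samples labeled `field_samples`.
#' @param train_frac fraction used for fitting.
#' @param seed split seed.
#' @return held-out accuracy in percent.
#' @export
separability_oracle <- function(samples, train_frac = 0.8, seed = 1L) {
  feats <- t(vapply(samples$images, image_features, numeric(2)))
  df <- data.frame(feats, y = samples$labels)
  set.seed(seed)
  tr <- integer()
  for (cl in unique(df$y)) {
    ii <- which(df$y == cl)
    tr <- c(tr, sample(ii, round_half_up(train_frac * length(ii))))
  }
  fit <- suppressWarnings(
    stats::glm(y ~ green_fraction + compactness, data = df[tr, ],
               family = stats::binomial()))
  te <- setdiff(seq_len(nrow(df)), tr)
  pred <- as.integer(
    suppressWarnings(stats::predict(fit, df[te, ], type = "response")) > 0.5)
  mean(pred == df$y[te]) * 100
}

#' Write a dataset as a one-folder-per-class PNG tree
#'
#' Produces the directory layout consumed by [load_image_dir()], plus a
#' `params.yaml` provenance file.
#'
#' @param samples labeled `field_samples` with raw `[0, 255]` pixels.
#' @param dir output directory.
#' @param class_names folder names in label order.
#' @param params optional [field_params()] recorded as `params.yaml`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, class_names = c("crop", "weed"),
                          params = NULL) {
  for (cl in class_names)
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  counters <- integer(length(class_names))
  for (i in seq_along(samples$images)) {
    cl <- samples$labels[i] + 1L
    counters[cl] <- counters[cl] + 1L
    f <- file.path(dir, class_names[cl],
                   sprintf("img_%04d.png", counters[cl]))
    im <- EBImage::Image(samples$images[[i]] / 255, colormode = "Color")
    EBImage::writeImage(im, f)
  }
  if (!is.null(params))
    yaml::write_yaml(unclass(params), file.path(dir, "params.yaml"))
  invisible(dir)
}
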