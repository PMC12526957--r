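# Segmentation: background subtraction, pixel features, random-forest
# classifier trained on the synthetic library, Otsu fallback, mask cleanup.

FEATURE_VERSION <- "rhizoshape-features-1"

# Detect whether roots are darker than the background: compare the image
# median (background-dominated) with the two Otsu class means; if the median
# sits with the brighter class, the background is bright and roots are dark.
roots_are_dark <- function(values) {
  t <- EBImage::otsu(EBImage::Image(values))
  lo <- values[values <= t]; hi <- values[values > t]
  if (!length(lo) || !length(hi)) return(FALSE)
  med <- median(values)
  abs(med - mean(hi)) < abs(med - mean(lo))
}

# Polarity-normalize so roots are bright.
normalize_polarity <- function(img) {
  if (roots_are_dark(img$values)) {
    raster_image(1 - img$values, img$bit_depth_source, img$channels_source)
  } else {
    img
  }
}

#' Subtract the image background by grayscale morphological opening
#'
#' The image is first polarity-normalized so roots are bright, then the
#' background is estimated by a grayscale opening with a disc structuring
#' element of the given radius (which erases structures thinner than the
#' disc, i.e. the roots) and subtracted; the result is clipped to `[0, 1]`.
#'
#' @param img a [raster_image()].
#' @param radius disc radius in pixels, at least 1.
#' @return A background-subtracted [raster_image()].
#' @export
subtract_background <- function(img, radius = 15) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1) {
    abort("`radius` must be a single number >= 1", class = "rhizo_parameter_error")
  }
  img <- normalize_polarity(img)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(img$values), brush))
  out <- pmin(pmax(img$values - bg, 0), 1)
  raster_image(matrix(out, img$height, img$width),
               img$bit_depth_source, img$channels_source)
}

gaussian_smooth <- function(values, sigma) {
  # gblur's kernel (2*ceil(3*sigma)+1) must not exceed the image; clamp it
  # for small frames
  ks <- 2 * ceiling(3 * sigma) + 1
  maxk <- min(dim(values))
  if (maxk %% 2 == 0) maxk <- maxk - 1
  if (ks <= maxk) {
    return(EBImage::imageData(EBImage::gblur(EBImage::Image(values),
                                             sigma = sigma)))
  }
  k <- EBImage::makeBrush(maxk, "Gaussian", sigma = sigma)
  EBImage::imageData(EBImage::filter2(EBImage::Image(values), k))
}

# Central-difference gradients with replicated borders.
central_diff <- function(m) {
  dr <- (shift_mat(m, -1, 0, fill = NA) - shift_mat(m, 1, 0, fill = NA)) / 2
  dc <- (shift_mat(m, 0, -1, fill = NA) - shift_mat(m, 0, 1, fill = NA)) / 2
  dr[1, ] <- m[2, ] - m[1, ]; dr[nrow(m), ] <- m[nrow(m), ] - m[nrow(m) - 1, ]
  dc[, 1] <- m[, 2] - m[, 1]; dc[, ncol(m)] <- m[, ncol(m)] - m[, ncol(m) - 1]
  list(dr = dr, dc = dc)
}

#' Per-pixel feature stack for pixel classification
#'
#' Builds `1 + 4 * length(scales)` planes: the raw intensity plus, at each
#' Gaussian scale sigma, the smoothed intensity, the gradient magnitude, the
#' smaller Hessian eigenvalue (a ridge detector: strongly negative on bright
#' curvilinear structures) and the local variance.
#'
#' @param img a [raster_image()].
#' @param scales Gaussian sigmas in pixels, all `> 0`.
#' @return A `pixel_feature_stack`: list with a `height x width x planes`
#'   array, plane names, and the scales used.
#' @export
compute_pixel_features <- function(img, scales = c(1, 2, 4)) {
  if (length(scales) < 1 || any(!is.finite(scales)) || any(scales <= 0)) {
    abort("`scales` must be a nonempty vector of positive sigmas",
          class = "rhizo_parameter_error")
  }
  v <- img$values
  planes <- list(raw = v)
  for (s in scales) {
    g <- gaussian_smooth(v, s)
    d1 <- central_diff(g)
    grad <- sqrt(d1$dr^2 + d1$dc^2)
    drr <- central_diff(d1$dr); dcc <- central_diff(d1$dc)
    hrr <- drr$dr; hcc <- dcc$dc; hrc <- (drr$dc + dcc$dr) / 2
    # smaller eigenvalue of [[hrr, hrc], [hrc, hcc]]
    ridge <- (hrr + hcc) / 2 - sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    varloc <- pmax(gaussian_smooth(v^2, s) - g^2, 0)
    tag <- format(s, trim = TRUE)
    planes[[paste0("gauss_", tag)]] <- g
    planes[[paste0("grad_", tag)]] <- grad
    planes[[paste0("ridge_", tag)]] <- ridge
    planes[[paste0("var_", tag)]] <- varloc
  }
  arr <- array(unlist(planes, use.names = FALSE),
               dim = c(img$height, img$width, length(planes)))
  structure(list(planes = arr, names = names(planes), scales = scales),
            class = "pixel_feature_stack")
}

feature_frame <- function(stack) {
  d <- dim(stack$planes)
  m <- matrix(stack$planes, d[1] * d[2], d[3])
  colnames(m) <- stack$names
  as.data.frame(m)
}

#' Train a random-forest pixel segmenter on an image/mask library
#'
#' Pixels are subsampled per image with balanced foreground/background
#' classes (at most `max_samples_per_image` per class) and a probability
#' random forest is fitted on the feature stack. Training is deterministic
#' given `seed`.
#'
#' @param library list of `list(image = raster_image, mask = root_mask)`
#'   pairs, dimension-matched.
#' @param scales feature scales, see [compute_pixel_features()].
#' @param trees number of trees.
#' @param max_samples_per_image per-class pixel cap per image.
#' @param seed integer seed.
#' @return A `segmentation_model` holding the fitted forest and its feature
#'   configuration, which is re-validated at predict time.
#' @export
train_segmenter <- function(library, scales = c(1, 2, 4), trees = 100,
                            max_samples_per_image = 5000, seed = 1L) {
  if (length(library) == 0) {
    abort("training library is empty", class = "rhizo_training_error")
  }
  with_seed(seed, {
    frames <- lapply(library, function(pair) {
      img <- pair$image; msk <- pair$mask
      if (img$width != msk$width || img$height != msk$height) {
        abort("image/mask dimensions differ in training library",
              class = "rhizo_training_error")
      }
      y <- as.vector(msk$values)
      fg <- which(y == 1L); bg <- which(y == 0L)
      if (!length(fg) || !length(bg)) {
        abort("training mask must contain both classes",
              class = "rhizo_training_error")
      }
      stack <- compute_pixel_features(img, scales)
      ff <- feature_frame(stack)
      k <- min(length(fg), length(bg), max_samples_per_image)
      idx <- c(sample(fg, k), sample(bg, k))
      cbind(ff[idx, , drop = FALSE], .class = factor(y[idx], levels = c(0, 1)))
    })
    train <- do.call(rbind, frames)
    # ranger treats seed 0 as "seed from the clock"; draw a nonzero forest
    # seed from the already-seeded RNG instead
    rf <- ranger::ranger(
      dependent.variable.name = ".class", data = train,
      num.trees = trees, probability = TRUE,
      seed = sample.int(.Machine$integer.max - 1L, 1),
      num.threads = 1, importance = "impurity")
    structure(
      list(forest = rf, scales = scales, trees = trees, seed = seed,
           n_train = nrow(train), version = FEATURE_VERSION),
      class = "segmentation_model")
  })
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("<segmentation_model: %d trees, scales {%s}, %d training px, OOB Brier %.4f>\n",
              x$trees, paste(x$scales, collapse = ","), x$n_train,
              x$forest$prediction.error))
  invisible(x)
}

#' Predict per-pixel foreground probability
#'
#' @param model a `segmentation_model`.
#' @param img a [raster_image()].
#' @return Matrix of foreground probabilities, same shape as the image.
#' @export
predict_probability <- function(model, img) {
  if (!identical(model$version, FEATURE_VERSION)) {
    abort("segmentation model feature version does not match this package",
          class = "rhizo_validation_error")
  }
  stack <- compute_pixel_features(img, model$scales)
  ff <- feature_frame(stack)
  if (!identical(colnames(ff), model$forest$forest$independent.variable.names)) {
    abort("feature configuration mismatch between model and image features",
          class = "rhizo_validation_error")
  }
  p <- predict(model$forest, data = ff, num.threads = 1)$predictions[, "1"]
  matrix(p, img$height, img$width)
}

#' Segment an image into a binary root mask
#'
#' In `"otsu"` mode a global Otsu threshold is applied to the
#' background-subtracted image; in model mode the trained random forest's
#' foreground probability is thresholded at `prob_cutoff`.
#'
#' @param img a [raster_image()].
#' @param method `"otsu"` or a `segmentation_model`.
#' @param prob_cutoff foreground probability cutoff in model mode.
#' @param bg_radius background-subtraction disc radius used in Otsu mode.
#' @return A [root_mask()] with the image's dimensions. An all-background
#'   result triggers a warning, not an error.
#' @export
segment <- function(img, method = "otsu", prob_cutoff = 0.5, bg_radius = 15) {
  if (inherits(method, "segmentation_model")) {
    p <- predict_probability(method, img)
    m <- p >= prob_cutoff
  } else if (identical(method, "otsu")) {
    sub <- subtract_background(img, radius = bg_radius)
    thr <- EBImage::otsu(EBImage::Image(sub$values))
    m <- sub$values > thr
  } else {
    abort("`method` must be \"otsu\" or a segmentation_model",
          class = "rhizo_parameter_error")
  }
  if (!any(m)) {
    warn("segmentation produced an empty mask (all background)")
  }
  root_mask(m)
}

# 8-connected component labels. EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged through a union-find pass.
label_components8 <- function(values) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(values * 1)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  for (d in list(c(-1, -1), c(-1, 1))) {
    sh <- shift_mat(lab, d[1], d[2])
    both <- lab > 0 & sh > 0 & lab != sh
    if (any(both)) {
      pairs <- unique(cbind(lab[both], sh[both]))
      for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
    }
  }
  roots <- vapply(seq_len(nlab), function(i) as.integer(find(i)), integer(1))
  remap <- match(roots, unique(roots))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Clean a binary mask
#'
#' Removes 8-connected components smaller than `min_size`, optionally fills
#' interior holes and keeps only the largest component. Idempotent.
#'
#' @param mask a [root_mask()].
#' @param min_size minimum component size in pixels (0 keeps everything).
#' @param fill_holes fill interior background holes.
#' @param keep_largest keep only the largest component.
#' @return A cleaned [root_mask()].
#' @export
clean_mask <- function(mask, min_size = 0, fill_holes = FALSE, keep_largest = FALSE) {
  if (!is.numeric(min_size) || min_size < 0) {
    abort("`min_size` must be >= 0", class = "rhizo_parameter_error")
  }
  v <- mask$values
  if (sum(v) == 0) return(root_mask(v))
  lab <- label_components8(v)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  if (keep_largest && length(keep)) {
    keep <- keep[which.max(sizes[keep])]
  }
  v <- matrix(as.integer(lab %in% keep & lab > 0), nrow(v), ncol(v))
  if (fill_holes && sum(v) > 0) {
    v <- matrix(as.integer(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(v))) > 0), nrow(v), ncol(v))
  }
  root_mask(v)
}

#' Save / load a segmentation model
#'
#' The model file embeds the feature configuration and a version tag;
#' prediction refuses to run when the tag does not match the installed
#' package's feature code.
#'
#' @param model a `segmentation_model`.
#' @param path file path.
#' @return `save_segmenter()` returns `path` invisibly.
#' @export
save_segmenter <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "segmentation_model") ||
      !identical(model$version, FEATURE_VERSION)) {
    abort("file is not a compatible segmentation model",
          class = "rhizo_validation_error")
  }
  model
}
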