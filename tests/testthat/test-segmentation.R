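test_that("background subtraction flattens uniform and ramped backgrounds", {
  flat <- raster_image(matrix(0.4, 40, 40))
  expect_true(all(subtract_background(flat, 10)$values == 0))
  expect_error(subtract_background(flat, 0), class = "rhizo_parameter_error")

  # bright 2-px line on a linear ramp; oracle = brute-force disc opening
  h <- 50; w <- 40
  ramp <- matrix(rep(seq(0, 0.3, length.out = h), w), h, w)
  ramp[, 20:21] <- 0.9
  img <- raster_image(ramp)
  out <- subtract_background(img, 15)
  oracle <- pmin(pmax(ramp - brute_opening(ramp, 15), 0), 1)
  expect_equal(out$values, oracle, tolerance = 1e-9)
  expect_true(all(out$values[, 20:21] >= 0.55))
  expect_lt(mean(out$values[, -(20:21)]), 0.02)
})

test_that("polarity auto-detection makes dark roots bright", {
  v <- matrix(0.9, 50, 50)   # light background, dark root line
  v[, 25] <- 0.1
  out <- subtract_background(raster_image(v), 10)
  expect_gt(mean(out$values[, 25]), 0.5)
  expect_lt(mean(out$values[, -25]), 0.05)
})

test_that("feature stack has 1 + 4 per scale planes and is flat on constants", {
  img <- raster_image(matrix(0.5, 30, 30))
  fs <- compute_pixel_features(img, scales = c(1, 2))
  expect_equal(dim(fs$planes)[3], 9L)
  grad_planes <- grep("^grad_", fs$names)
  ridge_planes <- grep("^ridge_", fs$names)
  var_planes <- grep("^var_", fs$names)
  for (i in c(grad_planes, ridge_planes, var_planes)) {
    expect_lt(max(abs(fs$planes[, , i])), 1e-8)
  }
  expect_equal(dim(compute_pixel_features(img, c(1, 2, 4))$planes)[3], 13L)
  expect_error(compute_pixel_features(img, numeric()),
               class = "rhizo_parameter_error")
  expect_error(compute_pixel_features(img, -1), class = "rhizo_parameter_error")
})

make_bimodal_lib <- function(seeds) {
  lapply(seeds, function(s) {
    m <- rand_blob_mask(s, 48, 48)
    set.seed(s + 5000)
    v <- ifelse(m$values == 1, 0.9, 0.1) + rnorm(48 * 48, 0, 0.02)
    list(image = raster_image(matrix(pmin(pmax(v, 0), 1), 48, 48)), mask = m)
  })
}

test_that("the forest separates a separable library and is deterministic", {
  lib <- make_bimodal_lib(1:5)
  model <- train_segmenter(lib, scales = c(1, 2), trees = 50,
                           max_samples_per_image = 1000, seed = 0)
  # training-set pixel F1: separable by construction
  f1 <- vapply(lib, function(pair) {
    pixel_f1(segment(pair$image, model), pair$mask)
  }, numeric(1))
  expect_true(all(f1 >= 0.99))
  model2 <- train_segmenter(lib, scales = c(1, 2), trees = 50,
                            max_samples_per_image = 1000, seed = 0)
  probe <- make_bimodal_lib(77)[[1]]$image
  expect_identical(predict_probability(model, probe),
                   predict_probability(model2, probe))
  expect_error(train_segmenter(list()), class = "rhizo_training_error")
  # single-class mask cannot train
  allbg <- list(list(image = raster_image(matrix(0.5, 20, 20)),
                     mask = root_mask(matrix(0, 20, 20))))
  expect_error(train_segmenter(allbg), class = "rhizo_training_error")
})

test_that("Otsu segmentation recovers a bimodal synthetic mask", {
  pair <- sim_pair(11, noise_sd = 0.02, blur_sd = 0)
  m <- segment(pair$image, method = "otsu")
  expect_gte(pixel_f1(m, pair$mask), 0.95)
  # all-background image: empty mask plus warning, not an error
  expect_warning(m0 <- segment(raster_image(matrix(0.5, 30, 30))),
                 "empty mask")
  expect_equal(sum(m0$values), 0)
  expect_equal(dim(m0$values), c(30L, 30L))
})

test_that("model predictions refuse a mismatched feature configuration", {
  lib <- make_bimodal_lib(1:2)
  model <- train_segmenter(lib, scales = c(1, 2), trees = 20,
                           max_samples_per_image = 500, seed = 1)
  model$version <- "something-else"
  expect_error(segment(lib[[1]]$image, model), class = "rhizo_validation_error")
})

test_that("segmentation output always matches input dimensions", {
  lib <- make_bimodal_lib(1:2)
  model <- train_segmenter(lib, scales = c(1), trees = 20,
                           max_samples_per_image = 300, seed = 1)
  for (s in 1:10) {
    set.seed(s)
    h <- sample(20:40, 1); w <- sample(20:40, 1)
    img <- raster_image(matrix(runif(h * w), h, w))
    m <- suppressWarnings(segment(img, method = "otsu"))
    expect_equal(dim(m$values), c(h, w))
    m2 <- suppressWarnings(segment(img, method = model))
    expect_equal(dim(m2$values), c(h, w))
  }
})

test_that("mask cleanup removes speckles, fills holes, and is idempotent", {
  v <- matrix(0L, 40, 40)
  v[5:29, 5:24] <- 1L           # 500-px component
  v[35, 35:37] <- 1L            # 3-px speckle
  cleaned <- clean_mask(root_mask(v), min_size = 10)
  expect_equal(sum(cleaned$values), 500)
  expect_equal(sum(cleaned$values[35, ]), 0)

  ring <- matrix(0L, 9, 9); ring[3:7, 3:7] <- 1L; ring[5, 5] <- 0L
  solid <- clean_mask(root_mask(ring), fill_holes = TRUE)
  expect_equal(sum(solid$values), 25)

  empty <- clean_mask(root_mask(matrix(0L, 5, 5)), min_size = 5)
  expect_equal(sum(empty$values), 0)

  # components touching only diagonally survive as one (8-connectivity)
  diagm <- matrix(0L, 10, 10)
  diagm[cbind(1:6, 1:6)] <- 1L
  expect_equal(sum(clean_mask(root_mask(diagm), min_size = 5)$values), 6)

  for (s in 1:10) {
    m <- rand_blob_mask(s)
    once <- clean_mask(m, min_size = 8, fill_holes = TRUE)
    twice <- clean_mask(once, min_size = 8, fill_holes = TRUE)
    expect_identical(once$values, twice$values)
  }
})

test_that("models survive a save/load round trip and version-check on load", {
  lib <- make_bimodal_lib(1:2)
  model <- train_segmenter(lib, scales = c(1), trees = 20,
                           max_samples_per_image = 300, seed = 3)
  d <- withr::local_tempdir()
  p <- file.path(d, "model.rds")
  save_segmenter(model, p)
  back <- load_segmenter(p)
  probe <- lib[[1]]$image
  expect_identical(predict_probability(model, probe),
                   predict_probability(back, probe))
  stale <- model; stale$version <- "v0"
  saveRDS(stale, p)
  expect_error(load_segmenter(p), class = "rhizo_validation_error")
})
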