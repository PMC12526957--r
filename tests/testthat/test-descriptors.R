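test_that("center of mass is bounding-box normalized", {
  sq <- matrix(0L, 30, 30); sq[5:14, 8:17] <- 1L
  expect_equal(unname(center_of_mass(root_mask(sq))), c(0.5, 0.5))

  top <- matrix(0L, 20, 20); top[4, 3:15] <- 1L; top[10, 9] <- 1L
  com <- center_of_mass(root_mask(top))
  expect_lt(com["com_y"], 0.2)

  wide <- matrix(0L, 10, 10); wide[2, 2:8] <- 1L   # 1-px tall box
  expect_equal(unname(center_of_mass(root_mask(wide))["com_y"]), 0.5)
  expect_error(center_of_mass(root_mask(matrix(0L, 4, 4))),
               class = "rhizo_measurement_error")
})

test_that("convex hull area uses pixel centers and matches the oracle", {
  sq <- matrix(0L, 20, 20); sq[5:14, 5:14] <- 1L
  expect_equal(convex_hull_area(root_mask(sq)), 81)

  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  expect_equal(convex_hull_area(root_mask(one)), 0)
  seg <- matrix(0L, 9, 9); seg[3, 2:8] <- 1L      # collinear
  expect_equal(convex_hull_area(root_mask(seg)), 0)

  for (s in 1:100) {
    m <- rand_point_mask(s)
    fg <- which(m$values == 1L, arr.ind = TRUE)
    pts <- cbind(fg[, 2] - 1, fg[, 1] - 1)
    expect_identical(convex_hull_area(m), jarvis_hull_area(pts))
  }
})

test_that("rect profile is a normalized depth histogram", {
  bar <- root_mask(matrix(1L, 40, 3))
  expect_equal(rect_profile(bar, 4), rep(0.25, 4))

  top <- matrix(0L, 40, 10); top[1:10, 3:7] <- 1L; top[40, 5] <- 1L
  p <- rect_profile(root_mask(top), 4)
  expect_gt(p[1], 0.9)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(rect_profile(root_mask(matrix(0L, 3, 3))),
               class = "rhizo_measurement_error")
})

test_that("ellipse ladder is monotone and ends at exactly 1", {
  single <- matrix(0L, 9, 9); single[3, 4] <- 1L
  expect_equal(ellips_profile(root_mask(single), 12), rep(1, 12))
  for (s in 1:20) {
    e <- ellips_profile(rand_blob_mask(s), 12)
    expect_true(all(diff(e) >= 0))
    expect_identical(e[12], 1)
  }
})

test_that("coord_x and diff_x track the layered horizontal extent", {
  rect <- root_mask(matrix(1L, 40, 20))
  cx <- coord_x_profile(rect, 10)
  expect_equal(cx, rep(1, 10))
  expect_equal(diff_x_profile(cx), c(1, rep(0, 9)))

  # triangle widening from 10% to 100% of width across depth
  h <- 100; w <- 60
  tri <- matrix(0L, h, w)
  for (r in 1:h) {
    half <- (0.1 + 0.9 * (r - 1) / (h - 1)) * w / 2
    tri[r, max(1, ceiling(w / 2 - half)):min(w, floor(w / 2 + half))] <- 1L
  }
  cxt <- coord_x_profile(root_mask(tri), 10)
  expect_true(all(diff(cxt) > 0))
  dxt <- diff_x_profile(cxt)
  expect_true(all(dxt[-1] > 0))

  top_only <- matrix(0L, 40, 20); top_only[1:3, 5:14] <- 1L
  # bounding box is just those rows, so band 0 holds everything after
  # band-splitting the 3-row box
  cto <- coord_x_profile(root_mask(top_only), 1)
  expect_equal(cto, 1)
})

test_that("crossing counts equal the number of foreground runs per scan line", {
  m <- matrix(0L, 30, 30)
  m[, c(4, 14, 24)] <- 1L     # 3 disjoint full-depth vertical bars
  ch <- crossing_counts(root_mask(m), "horizontal", 30)
  expect_equal(ch$mean, 3)
  expect_equal(ch$max, 3)
  expect_equal(ch$layers, rep(3, 30))

  vbar <- matrix(0L, 30, 9); vbar[3:27, 5] <- 1L
  cv <- crossing_counts(root_mask(vbar), "vertical", 5)
  expect_equal(cv$mean, 1)
  expect_equal(cv$max, 1)

  # comb: horizontal spine with 7 teeth hanging down
  comb <- matrix(0L, 40, 80)
  comb[5, 5:75] <- 1L
  teeth <- round(seq(6, 74, length.out = 7))
  for (tc in teeth) comb[6:35, tc] <- 1L
  cc <- crossing_counts(root_mask(comb), "horizontal", 30)
  expect_equal(cc$max, 7)
})

test_that("the full trait vector fills the 16 + 96 channel registry", {
  reg <- default_trait_registry()
  expect_equal(unname(registry_counts(reg)), c(16L, 96L))
  m <- rand_blob_mask(5)
  tv <- compute_trait_vector(m, registry = reg)
  expect_equal(ncol(tv), 112L)
  expect_identical(names(tv), registry_channel_names(reg))
  tv2 <- compute_trait_vector(m, registry = reg)
  expect_identical(tv, tv2)
  # graph from a different mask is rejected
  g_other <- skeletonize(rand_blob_mask(6))
  expect_error(compute_trait_vector(m, g_other, reg),
               class = "rhizo_validation_error")
})

test_that("registry JSON round-trips", {
  reg <- default_trait_registry()
  d <- withr::local_tempdir()
  p <- file.path(d, "registry.json")
  write_trait_registry(reg, p)
  back <- read_trait_registry(p)
  expect_identical(registry_channel_names(back), registry_channel_names(reg))
  expect_identical(back$kind, reg$kind)
})

test_that("descriptor invariants hold over random masks", {
  for (s in 1:100) {
    m <- rand_blob_mask(s, 40, 36, n_shapes = 4)
    expect_equal(sum(rect_profile(m, 4)), 1, tolerance = 1e-9)
    e <- ellips_profile(m, 12)
    expect_true(all(diff(e) >= 0))
    expect_identical(e[12], 1)
    com <- center_of_mass(m)
    expect_true(all(com >= 0 & com <= 1))
    cx <- coord_x_profile(m, 10)
    expect_true(all(cx >= 0 & cx <= 1))
    ch <- crossing_counts(m, "horizontal", 10)
    expect_gte(ch$max, ch$mean)
  }
})

test_that("area and crossing statistics are mirror-invariant", {
  for (s in 1:15) {
    m <- rand_blob_mask(s)
    mm <- mirror_mask(m)
    expect_equal(sum(mm$values), sum(m$values))
    a <- crossing_counts(m, "horizontal", 30)
    b <- crossing_counts(mm, "horizontal", 30)
    expect_equal(a$mean, b$mean)
    expect_equal(a$max, b$max)
    av <- crossing_counts(m, "vertical", 30)
    bv <- crossing_counts(mm, "vertical", 30)
    expect_equal(av$mean, bv$mean)
    expect_equal(av$max, bv$max)
  }
})

test_that("adding a disjoint full-depth bar raises cross_hori_mean by one", {
  for (s in 1:5) {
    m <- rand_blob_mask(s, 40, 40)
    bb <- rhizoshape:::mask_bbox(m)
    v <- m$values
    # full-depth bar in a free column strip, spanning the existing bbox rows
    used <- unique(which(v == 1L, arr.ind = TRUE)[, 2])
    # need an empty column whose neighbours are empty too, so the new bar
    # cannot merge with an existing run
    free <- setdiff(seq(2, 39), c(used - 1L, used, used + 1L))
    free <- free[free > bb["min_col"] + 1 & free < bb["max_col"] + 1]
    if (length(free) == 0) next
    col <- free[1]
    v2 <- v
    v2[(bb["min_row"]:bb["max_row"]) + 1L, col] <- 1L
    before <- crossing_counts(m, "horizontal", 30)
    after <- crossing_counts(root_mask(v2), "horizontal", 30)
    expect_equal(after$mean, before$mean + 1)
  }
})
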