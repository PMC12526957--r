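# Shared fixtures: random masks, brute-force oracles, synthetic image pairs.

# Random blob mask: union of a few discs and bars scattered over the frame.
rand_blob_mask <- function(seed, h = 60, w = 60, n_shapes = 6) {
  set.seed(seed)
  v <- matrix(0L, h, w)
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  for (i in seq_len(n_shapes)) {
    if (runif(1) < 0.5) {
      cr <- runif(1, 5, h - 6); cc <- runif(1, 5, w - 6); r <- runif(1, 2, 7)
      v[(rows - cr)^2 + (cols - cc)^2 <= r^2] <- 1L
    } else {
      r0 <- sample(1:(h - 10), 1); c0 <- sample(1:(w - 4), 1)
      len <- sample(5:min(25, h - r0), 1); wd <- sample(1:3, 1)
      v[r0:(r0 + len - 1), c0:min(w, c0 + wd - 1)] <- 1L
    }
  }
  if (sum(v) == 0) v[round(h / 2), round(w / 2)] <- 1L
  root_mask(v)
}

# Sparse random point mask (for hull oracle comparisons).
rand_point_mask <- function(seed, h = 50, w = 50, n_max = 200) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  idx <- sample(h * w, n)
  v <- matrix(0L, h, w)
  v[idx] <- 1L
  root_mask(v)
}

# Gift-wrapping (Jarvis march) convex hull + shoelace: the brute-force
# oracle for convex_hull_area(), independent of the monotone-chain code.
jarvis_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  cross3 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(pts[, 1] + pts[, 2] / 1e9)
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- cross3(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2))) {
        q <- r
      }
    }
    p <- q
    if (p == start || length(hull) > n) break
  }
  poly <- pts[hull, , drop = FALSE]
  m <- nrow(poly)
  if (m < 3) return(0)
  j <- c(2:m, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# Brute-force grayscale opening with a disc: erosion (min) then dilation
# (max) over explicit disc offsets. Oracle for subtract_background().
brute_opening <- function(v, radius) {
  offs <- which(EBImage::makeBrush(2 * radius + 1, "disc") == 1, arr.ind = TRUE)
  offs <- offs - (radius + 1)
  slide <- function(m, fun, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    for (k in seq_len(nrow(offs))) {
      sh <- rhizoshape:::shift_mat(m, offs[k, 1], offs[k, 2], fill = fill)
      out <- fun(out, sh)
    }
    out
  }
  er <- slide(v, pmin, Inf)
  slide(er, pmax, -Inf)
}

pixel_f1 <- function(mask, truth) {
  tp <- sum(mask$values == 1 & truth$values == 1)
  denom <- sum(mask$values) + sum(truth$values)
  if (denom == 0) return(1)
  2 * tp / denom
}

# Clean bimodal image/mask pair via the simulator (no noise controls where
# stated by the test).
sim_pair <- function(seed, angle = 0, ...) {
  sim <- simulate_root_system(synthetic_root_spec(seed = seed, ...))
  v <- render_views(sim, angles = angle)[[1]]
  list(image = v$image, mask = v$mask, sim = sim)
}

rot_mask_cw <- function(mask) {
  v <- mask$values
  root_mask(t(v[nrow(v):1, , drop = FALSE]))
}

mirror_mask <- function(mask) {
  root_mask(mask$values[, ncol(mask$values):1, drop = FALSE])
}

# The no-overlap recovery setting used by the skeleton-recovery checks:
# modest branching so the projected strokes can stay disjoint.
recovery_spec <- function(seed) {
  synthetic_root_spec(seed = seed, n_primary = 2, branch_rate = 0.8,
                      max_order = 1, base_radius = 1.5, noise_sd = 0,
                      blur_sd = 0, canvas = c(240, 260))
}
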