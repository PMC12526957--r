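# Stochastic 3D root-system generator and multi-view orthographic renderer.
# Supplies the training library for the pixel segmenter and exact ground
# truth (length, tips, projected crossing counts) for descriptor validation.

#' Parameters of the synthetic root-system generator
#'
#' Axes grow in 3D from a crown point by fixed-length steps: each step's
#' direction is the previous direction rotated by `N(0, tortuosity_sd)`
#' radians about a random perpendicular axis, then blended toward the
#' downward vertical with weight `gravitropism`. Branches arise as a Poisson
#' process along each parent axis at `branch_rate` expected branches per 100
#' px, leaving at `branch_angle_mean` +/- `branch_angle_sd` degrees from the
#' local parent direction; stroke radius decays by `taper` per branch order.
#' A short upward stem above the crown emulates the cutting's shoot stub, so
#' the crown is always the skeleton's top endpoint.
#'
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param n_primary number of adventitious axes from the crown.
#' @param step_len growth step in px.
#' @param n_steps steps per primary axis.
#' @param tortuosity_sd direction noise, radians per step.
#' @param gravitropism downward pull weight in `[0, 1]`.
#' @param branch_rate expected branches per 100 px of parent axis.
#' @param branch_angle_mean,branch_angle_sd branch departure angle, degrees.
#' @param taper stroke-radius decay factor per branch order.
#' @param base_radius primary-axis stroke radius in px (>= 0.5).
#' @param canvas `c(width, height)` of the rendered frame in px.
#' @param noise_sd additive Gaussian intensity noise.
#' @param blur_sd Gaussian blur sigma applied to the rendered intensity.
#' @param polarity `"bright_roots"` or `"dark_roots"`.
#' @param stem_len length of the upward stem stub in px (0 disables it).
#' @param stem_radius stroke radius of the stem stub in px (cuttings' stems
#'   are thicker than their roots); primaries attach around its perimeter.
#' @param max_order deepest branch order (primaries are order 0).
#' @param tilt_sd sd of the primaries' initial tilt from vertical, degrees.
#' @return A validated `synthetic_root_spec`.
#' @export
synthetic_root_spec <- function(seed = 1L, n_primary = 3L, step_len = 4,
                                n_steps = 40L, tortuosity_sd = 0.08,
                                gravitropism = 0.35, branch_rate = 1.2,
                                branch_angle_mean = 40, branch_angle_sd = 10,
                                taper = 0.75, base_radius = 1.5,
                                canvas = c(200L, 260L), noise_sd = 0.03,
                                blur_sd = 0.7, polarity = "bright_roots",
                                stem_len = 12, stem_radius = 2.5,
                                max_order = 2L, tilt_sd = 25) {
  spec <- list(seed = as.integer(seed), n_primary = as.integer(n_primary),
               step_len = step_len, n_steps = as.integer(n_steps),
               tortuosity_sd = tortuosity_sd, gravitropism = gravitropism,
               branch_rate = branch_rate,
               branch_angle_mean = branch_angle_mean,
               branch_angle_sd = branch_angle_sd, taper = taper,
               base_radius = base_radius,
               canvas = as.integer(canvas), noise_sd = noise_sd,
               blur_sd = blur_sd, polarity = polarity,
               stem_len = stem_len, stem_radius = stem_radius,
               max_order = as.integer(max_order), tilt_sd = tilt_sd)
  rates <- c(spec$tortuosity_sd, spec$branch_rate, spec$noise_sd,
             spec$blur_sd, spec$branch_angle_sd, spec$stem_len)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("rates and noise parameters must be finite and >= 0",
          class = "rhizo_parameter_error")
  }
  if (spec$base_radius < 0.5 || spec$stem_radius < 0.5) {
    abort("`base_radius` and `stem_radius` must be >= 0.5 px",
          class = "rhizo_parameter_error")
  }
  if (spec$gravitropism < 0 || spec$gravitropism > 1) {
    abort("`gravitropism` must lie in [0, 1]", class = "rhizo_parameter_error")
  }
  if (spec$n_primary < 1 || spec$n_steps < 1 || spec$step_len <= 0) {
    abort("need n_primary >= 1, n_steps >= 1, step_len > 0",
          class = "rhizo_parameter_error")
  }
  if (length(spec$canvas) != 2 || any(spec$canvas < 16)) {
    abort("`canvas` must be c(width, height) large enough to hold the crown",
          class = "rhizo_parameter_error")
  }
  if (!spec$polarity %in% c("bright_roots", "dark_roots")) {
    abort("`polarity` must be bright_roots or dark_roots",
          class = "rhizo_parameter_error")
  }
  structure(spec, class = "synthetic_root_spec")
}

unit <- function(v) v / sqrt(sum(v^2))

# random unit vector perpendicular to d (uniform azimuth)
rand_perp <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(pracma_cross(d, a))
  w <- pracma_cross(d, u)
  phi <- runif(1, 0, 2 * pi)
  unit(cos(phi) * u + sin(phi) * w)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotate_by <- function(d, angle_rad) {
  u <- rand_perp(d)
  unit(cos(angle_rad) * d + sin(angle_rad) * u)
}

DOWN <- c(0, 1, 0)  # world axes: x lateral, y depth (down), z toward camera

grow_axis <- function(origin, dir, n_steps, spec) {
  pts <- matrix(0, n_steps + 1, 3)
  pts[1, ] <- origin
  for (i in seq_len(n_steps)) {
    if (spec$tortuosity_sd > 0) {
      dir <- rotate_by(dir, rnorm(1, 0, spec$tortuosity_sd))
    }
    blend <- (1 - spec$gravitropism) * dir + spec$gravitropism * DOWN
    dir <- if (sum(blend^2) < 1e-12) DOWN else unit(blend)
    pts[i + 1, ] <- pts[i, ] + spec$step_len * dir
  }
  pts
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Simulate one 3D root system
#'
#' Deterministic given `spec$seed`. Returns the axis polylines (3D, with
#' stroke radius, branch order and parent attachment) and the exact ground
#' truth the rendered views must recover: total polyline length and tip
#' count (= number of root axes; the stem stub is rendered but is not a
#' tip).
#'
#' @param spec a [synthetic_root_spec()].
#' @return A `root_simulation`: list with `axes` and `ground_truth`.
#' @export
simulate_root_system <- function(spec) {
  if (!inherits(spec, "synthetic_root_spec")) {
    spec <- do.call(synthetic_root_spec, spec)
  }
  with_seed(spec$seed, {
    crown <- c(0, 0, 0)
    axes <- list()
    stem_idx <- NA_integer_
    if (spec$stem_len > 0) {
      axes[[length(axes) + 1]] <- list(
        pts = rbind(crown, crown - c(0, spec$stem_len, 0)),
        radius = spec$stem_radius, order = -1L, parent = NA_integer_,
        attach = crown, is_stem = TRUE)
      stem_idx <- 1L
    }
    # Adventitious axes emerge radially around the stem base (evenly spaced
    # azimuths with jitter), tilted outward then pulled down by gravitropism.
    queue <- list()
    az0 <- runif(1, 0, 2 * pi)
    attach_r <- if (spec$stem_len > 0) 0.8 * spec$stem_radius else 0
    for (i in seq_len(spec$n_primary)) {
      az <- az0 + 2 * pi * (i - 1) / spec$n_primary + rnorm(1, 0, 0.2)
      tilt <- min(max(abs(rnorm(1, 0, spec$tilt_sd * pi / 180)), 0.12),
                  80 * pi / 180)
      dir <- unit(c(sin(tilt) * cos(az), cos(tilt), sin(tilt) * sin(az)))
      origin <- crown + attach_r * c(cos(az), 0, sin(az))
      queue[[length(queue) + 1]] <- list(origin = origin, dir = dir,
                                         n_steps = spec$n_steps, order = 0L,
                                         parent = stem_idx)
    }
    while (length(queue) > 0) {
      job <- queue[[1]]; queue <- queue[-1]
      pts <- grow_axis(job$origin, job$dir, job$n_steps, spec)
      idx <- length(axes) + 1L
      axes[[idx]] <- list(
        pts = pts, radius = spec$base_radius * spec$taper^job$order,
        order = job$order, parent = job$parent, attach = job$origin,
        is_stem = FALSE)
      if (job$order < spec$max_order && spec$branch_rate > 0) {
        len <- polyline_length(pts)
        n_br <- rpois(1, spec$branch_rate * len / 100)
        if (n_br > 0) {
          seg_len <- sqrt(rowSums(diff(pts)^2))
          cum <- c(0, cumsum(seg_len))
          for (b in seq_len(n_br)) {
            s <- runif(1, 0.05, 0.95) * len
            k <- findInterval(s, cum, all.inside = TRUE)
            t <- (s - cum[k]) / seg_len[k]
            at <- pts[k, ] + t * (pts[k + 1, ] - pts[k, ])
            parent_dir <- unit(pts[k + 1, ] - pts[k, ])
            ang <- abs(rnorm(1, spec$branch_angle_mean, spec$branch_angle_sd))
            child_dir <- rotate_by(parent_dir, ang * pi / 180)
            child_steps <- max(4L, round(job$n_steps * runif(1, 0.3, 0.6)))
            queue[[length(queue) + 1]] <- list(
              origin = at, dir = child_dir, n_steps = child_steps,
              order = job$order + 1L, parent = idx)
          }
        }
      }
    }
    root_axes <- axes[!vapply(axes, `[[`, logical(1), "is_stem")]
    gt <- list(
      total_length = sum(vapply(axes, function(a) polyline_length(a$pts),
                                numeric(1))),
      tip_count = length(root_axes),
      n_axes = length(root_axes))
    structure(list(axes = axes, spec = spec, ground_truth = gt),
              class = "root_simulation")
  })
}

#' @export
print.root_simulation <- function(x, ...) {
  cat(sprintf("<root_simulation: %d axes (+%d stem), length %.0f px, %d tips>\n",
              x$ground_truth$n_axes,
              sum(vapply(x$axes, `[[`, logical(1), "is_stem")),
              x$ground_truth$total_length, x$ground_truth$tip_count))
  invisible(x)
}

# project 3D points to (row, col) at turntable angle theta_deg; cospi/sinpi
# keep the 0/180-degree views exact mirror images.
project_points <- function(pts, angle_deg, spec) {
  ct <- cospi(angle_deg / 180); st <- sinpi(angle_deg / 180)
  xr <- pts[, 1] * ct + pts[, 3] * st
  col <- xr + (spec$canvas[1] - 1) / 2
  row <- pts[, 2] + spec$stem_len + 3
  cbind(row = row, col = col)
}

# stamp one thick segment into a 0/1 matrix (pixel centers at integer
# 0-based coords), returning the updated matrix
stamp_segment <- function(m, p, q, r) {
  h <- nrow(m); w <- ncol(m)
  r0 <- max(0, floor(min(p[1], q[1]) - r - 1)); r1 <- min(h - 1, ceiling(max(p[1], q[1]) + r + 1))
  c0 <- max(0, floor(min(p[2], q[2]) - r - 1)); c1 <- min(w - 1, ceiling(max(p[2], q[2]) + r + 1))
  if (r0 > r1 || c0 > c1) return(m)
  rows <- r0:r1; cols <- c0:c1
  R <- matrix(rows, length(rows), length(cols))
  C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  v <- q - p
  L2 <- sum(v^2)
  if (L2 < 1e-12) {
    d2 <- (R - p[1])^2 + (C - p[2])^2
  } else {
    t <- ((R - p[1]) * v[1] + (C - p[2]) * v[2]) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (R - (p[1] + t * v[1]))^2 + (C - (p[2] + t * v[2]))^2
  }
  hit <- d2 <= r^2
  if (any(hit)) {
    sub <- m[rows + 1, cols + 1, drop = FALSE]
    sub[hit] <- 1L
    m[rows + 1, cols + 1] <- sub
  }
  m
}

rasterize_axis <- function(axis2d, radius, width, height) {
  m <- matrix(0L, height, width)
  pts <- axis2d
  for (i in seq_len(nrow(pts) - 1)) {
    m <- stamp_segment(m, pts[i, ], pts[i + 1, ], radius)
  }
  m
}

#' Render turntable views of a simulated root system
#'
#' Rotates the 3D polylines about the vertical axis, orthographically
#' projects them, and rasterizes strokes with the per-axis radius. The mask
#' is the exact rasterization; the image adds polarity, Gaussian blur and
#' additive noise (seeded per angle so re-rendering is deterministic).
#'
#' @param sim a `root_simulation`.
#' @param angles view angles in degrees, each in `[0, 360)`.
#' @param per_axis also return each axis's own mask (used by the
#'   overlap-rejection sampler and crossing ground truth).
#' @return A list keyed by angle, each entry holding `image` (a
#'   [raster_image()]), `mask` (a [root_mask()]) and optionally `axis_masks`.
#' @export
render_views <- function(sim, angles = 0, per_axis = FALSE) {
  if (length(sim$axes) == 0) {
    abort("nothing to render: simulation has no axes", class = "rhizo_parameter_error")
  }
  if (any(angles < 0 | angles >= 360)) {
    abort("angles must lie in [0, 360)", class = "rhizo_parameter_error")
  }
  spec <- sim$spec
  w <- spec$canvas[1]; h <- spec$canvas[2]
  out <- list()
  for (a in angles) {
    axis_masks <- lapply(sim$axes, function(ax) {
      rasterize_axis(project_points(ax$pts, a, spec), ax$radius, w, h)
    })
    mask <- Reduce(function(x, y) pmax(x, y), axis_masks)
    img <- if (spec$polarity == "bright_roots") mask * 1 else 1 - mask
    if (spec$blur_sd > 0) {
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = spec$blur_sd))
    }
    if (spec$noise_sd > 0) {
      img <- with_seed((spec$seed * 131L + round(a)) %% 2147483647L,
                       img + rnorm(length(img), 0, spec$noise_sd))
    }
    img <- pmin(pmax(img, 0), 1)
    entry <- list(
      image = raster_image(matrix(img, h, w)),
      mask = root_mask(mask))
    if (per_axis) entry$axis_masks <- axis_masks
    out[[as.character(a)]] <- entry
  }
  out
}

#' Ground-truth maximum horizontal crossing count
#'
#' For each image row, sums over axes the number of times the axis
#' centerline passes through that row in the given projection, and returns
#' the maximum. Computed from the vector geometry, independent of any
#' rasterization — the oracle for the image-based crossing counter.
#'
#' @param sim a `root_simulation`.
#' @param angle view angle in degrees.
#' @return Integer maximum crossing count.
#' @export
ground_truth_crossing_max <- function(sim, angle = 0) {
  spec <- sim$spec
  rows <- seq(0, spec$canvas[2] - 1)
  total <- numeric(length(rows))
  for (ax in sim$axes) {
    pr <- project_points(ax$pts, angle, spec)[, 1]
    lo <- pmin(head(pr, -1), tail(pr, -1))
    hi <- pmax(head(pr, -1), tail(pr, -1))
    total <- total + vapply(rows, function(y) sum(lo < y & y <= hi), numeric(1))
  }
  max(total)
}

# Rejection sampler: resample (reseeded) until, in the projected view, no
# two axes' strokes merge away from their shared attachment point. Enables
# exact tip / crossing recovery tests.
#' Simulate a root system whose projected axes do not overlap
#'
#' Repeatedly simulates with derived seeds until the rendered strokes of
#' distinct axes touch only near their attachment points in the given view.
#'
#' @param spec a [synthetic_root_spec()].
#' @param angle the view angle the no-overlap guarantee applies to.
#' @param max_tries resampling budget.
#' @return A `root_simulation` (with `$views` holding the accepted rendering),
#'   or the last attempt with a warning if the budget is exhausted.
#' @export
simulate_nonoverlapping <- function(spec, angle = 0, max_tries = 100L) {
  base_seed <- spec$seed
  for (t in seq_len(max_tries)) {
    spec$seed <- as.integer((base_seed + 9973L * (t - 1L)) %% 2147483647L)
    sim <- simulate_root_system(spec)
    views <- render_views(sim, angles = angle, per_axis = TRUE)
    am <- views[[1]]$axis_masks
    # dilate so strokes that merely touch (which still merge under
    # 8-connectivity) count as overlapping
    kern <- EBImage::makeBrush(3, "box")
    dm <- lapply(am, function(x)
      EBImage::imageData(EBImage::dilate(EBImage::Image(x), kern)))
    ok <- TRUE
    n <- length(sim$axes)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ov <- which(dm[[i]] >= 1 & am[[j]] == 1L, arr.ind = TRUE)
        if (nrow(ov) == 0) next
        ai <- sim$axes[[i]]; aj <- sim$axes[[j]]
        share <- NULL
        if (identical(aj$parent, i)) share <- aj$attach
        if (identical(ai$parent, j)) share <- ai$attach
        if (is.null(share) && identical(ai$parent, aj$parent) &&
            sqrt(sum((ai$attach - aj$attach)^2)) <= 2 * sim$spec$stem_radius) {
          share <- (ai$attach + aj$attach) / 2  # siblings around the crown
        }
        if (is.null(share)) { ok <- FALSE; break }
        sp <- project_points(matrix(share, 1), angle, sim$spec)
        allow <- 3 * (ai$radius + aj$radius) + 2
        d <- sqrt((ov[, 1] - 1 - sp[1])^2 + (ov[, 2] - 1 - sp[2])^2)
        if (any(d > allow)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      sim$views <- views
      return(sim)
    }
  }
  warn("no-overlap budget exhausted; returning last (overlapping) simulation")
  sim$views <- views
  sim
}

#' Generate a synthetic training library on disk
#'
#' Samples `n_images` specs uniformly within per-field ranges (seeded),
#' renders one view each, and writes `img_####.png`, `mask_####.png` and a
#' `manifest.json` recording every spec and its ground truth. Re-running
#' with the same seed reproduces identical files.
#'
#' @param n_images number of image/mask pairs, `>= 1`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param spec_ranges named list of `c(lo, hi)` ranges overriding the
#'   default sampling ranges for numeric spec fields.
#' @param base_spec spec supplying all non-sampled fields.
#' @return Invisibly, the manifest as a tibble.
#' @export
make_library <- function(n_images, out_dir, seed = 1L, spec_ranges = list(),
                         base_spec = synthetic_root_spec()) {
  stopifnot_scalar_count(n_images, "n_images")
  defaults <- list(n_primary = c(2, 4), n_steps = c(30, 45),
                   tortuosity_sd = c(0.04, 0.12), gravitropism = c(0.25, 0.45),
                   branch_rate = c(0.5, 1.8), base_radius = c(1, 2.5),
                   noise_sd = c(0.01, 0.06), blur_sd = c(0.4, 1.0))
  ranges <- utils::modifyList(defaults, spec_ranges)
  bad <- vapply(ranges, function(r) length(r) != 2 || r[1] > r[2], logical(1))
  if (any(bad)) {
    abort(sprintf("invalid spec ranges: %s",
                  paste(names(ranges)[bad], collapse = ", ")),
          class = "rhizo_parameter_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- with_seed(seed, {
    rows <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      spec <- unclass(base_spec)
      for (f in names(ranges)) {
        val <- runif(1, ranges[[f]][1], ranges[[f]][2])
        if (f %in% c("n_primary", "n_steps")) val <- as.integer(round(val))
        spec[[f]] <- val
      }
      spec$seed <- as.integer((seed * 1009L + i) %% 2147483647L)
      spec <- do.call(synthetic_root_spec, spec)
      angle <- (i - 1) %% 360
      sim <- simulate_root_system(spec)
      view <- render_views(sim, angles = angle)[[1]]
      png::writePNG(view$image$values,
                    file.path(out_dir, sprintf("img_%04d.png", i)))
      png::writePNG(view$mask$values * 1,
                    file.path(out_dir, sprintf("mask_%04d.png", i)))
      rows[[i]] <- tibble(
        id = i, image = sprintf("img_%04d.png", i),
        mask = sprintf("mask_%04d.png", i), angle = angle,
        seed = spec$seed,
        total_length = sim$ground_truth$total_length,
        tip_count = sim$ground_truth$tip_count,
        spec = list(unclass(spec)))
    }
    bind_rows(rows)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Simulate a multiangle accession batch on disk
#'
#' Emulates the turntable acquisition: for each synthetic accession and
#' replicate, one 3D root system is simulated and rendered at every angle
#' of the protocol; images are written as
#' `<accession>_r<replicate>_a<angle>.png` so the standard filename parser
#' applies.
#'
#' @param n_accessions number of synthetic accessions.
#' @param out_dir output directory.
#' @param replicates biological replicates per accession (default 3).
#' @param step_deg angular step (default 15, i.e. 24 views).
#' @param seed integer seed.
#' @param base_spec generator spec for every plant (per-replicate seeds are
#'   derived from `seed`).
#' @param write_masks also write `mask_`-prefixed ground-truth masks.
#' @return Invisibly, a tibble describing the files written.
#' @export
simulate_accession_batch <- function(n_accessions, out_dir, replicates = 3L,
                                     step_deg = 15L, seed = 1L,
                                     base_spec = synthetic_root_spec(),
                                     write_masks = TRUE) {
  n_views <- expected_view_count(step_deg)
  angles <- seq(0, 359, by = step_deg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (a in seq_len(n_accessions)) {
    acc <- sprintf("SYN%04d", a)
    for (r in seq_len(replicates)) {
      spec <- base_spec
      spec$seed <- as.integer((seed * 7919L + a * 101L + r) %% 2147483647L)
      sim <- simulate_root_system(spec)
      views <- render_views(sim, angles = angles)
      for (ang in angles) {
        fn <- sprintf("%s_r%d_a%03d.png", acc, r, ang)
        png::writePNG(views[[as.character(ang)]]$image$values,
                      file.path(out_dir, fn))
        if (write_masks) {
          png::writePNG(views[[as.character(ang)]]$mask$values * 1,
                        file.path(out_dir, paste0("mask_", fn)))
        }
        rows[[length(rows) + 1]] <- tibble(
          accession = acc, replicate = r, angle = ang, file = fn,
          total_length = sim$ground_truth$total_length,
          tip_count = sim$ground_truth$tip_count)
      }
    }
  }
  invisible(bind_rows(rows))
}
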