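# Layered shape descriptors: the 16 macrophenotypes and 96 layered
# microphenotypes computed from a root mask and its skeleton graph.

#' The default trait registry: 16 macrophenotypes, 96 microphenotypes
#'
#' Seven structural descriptors (`com_x`, `com_y`, `ellips`, `rect`,
#' `convexhull`, `coord_x`, `diff_x`) and nine morphological descriptors
#' (`diam_mean`, `length`, `area`, `directionality`, `tip_count`,
#' `cross_hori_mean`, `cross_hori_max`, `cross_vert_mean`,
#' `cross_vert_max`) each contribute one macro channel; the layered
#' descriptors additionally contribute micro channels: `ellips` over a
#' `K_ellips`-rung ladder, `rect` over `L_rect` depth strata, `coord_x` and
#' `diff_x` over `L_coord` depth layers, and the two crossing means over
#' `L_cross` bands. With the defaults the totals are 16 macro and
#' 12 + 4 + 10 + 10 + 30 + 30 = 96 micro channels.
#'
#' @param L_rect depth strata for `rect` (default 4).
#' @param L_coord depth layers for `coord_x` / `diff_x` (default 10).
#' @param K_ellips ellipse-ladder size (default 12).
#' @param L_cross crossing-count bands (default 30).
#' @return A `trait_registry` tibble with one row per descriptor: `name`,
#'   `kind`, `layering`, `layers`, and the micro channel names.
#' @export
default_trait_registry <- function(L_rect = 4L, L_coord = 10L,
                                   K_ellips = 12L, L_cross = 30L) {
  stopifnot_scalar_count(L_rect, "L_rect")
  stopifnot_scalar_count(L_coord, "L_coord")
  stopifnot_scalar_count(K_ellips, "K_ellips")
  stopifnot_scalar_count(L_cross, "L_cross")
  idx <- function(n) seq_len(n) - 1L
  reg <- tibble(
    name = c("com_x", "com_y", "ellips", "rect", "convexhull", "coord_x",
             "diff_x",
             "diam_mean", "length", "area", "directionality", "tip_count",
             "cross_hori_mean", "cross_hori_max", "cross_vert_mean",
             "cross_vert_max"),
    kind = c(rep("structural", 7), rep("morphological", 9)),
    layering = c("none", "none", "ellipse_ladder", "horizontal_bands",
                 "none", "horizontal_bands", "horizontal_bands",
                 "none", "none", "none", "none", "none",
                 "horizontal_bands", "none", "vertical_bands", "none"),
    layers = c(0L, 0L, K_ellips, L_rect, 0L, L_coord, L_coord,
               0L, 0L, 0L, 0L, 0L, L_cross, 0L, L_cross, 0L),
    micro = list(
      character(), character(),
      paste0("ellips_", idx(K_ellips)),
      paste0("rect_", idx(L_rect)),
      character(),
      paste0("coord_x_", idx(L_coord)),
      paste0("diff_x_", idx(L_coord)),
      character(), character(), character(), character(), character(),
      paste0("cross_hori_", idx(L_cross), "_mean"),
      character(),
      paste0("cross_vert_", idx(L_cross), "_mean"),
      character())
  )
  class(reg) <- c("trait_registry", class(reg))
  reg
}

#' Channel names and counts of a registry
#'
#' Macro channels come first (registry order) followed by every descriptor's
#' micro channels; this is also the trait-table column order.
#'
#' @param registry a `trait_registry`.
#' @return `registry_channel_names()`: character vector of all channels;
#'   `registry_counts()`: named vector with `macro` and `micro` totals.
#' @export
registry_channel_names <- function(registry) {
  c(registry$name, unlist(registry$micro, use.names = FALSE))
}

#' @rdname registry_channel_names
#' @export
registry_counts <- function(registry) {
  c(macro = nrow(registry),
    micro = length(unlist(registry$micro, use.names = FALSE)))
}

#' Serialize / deserialize a trait registry as JSON
#'
#' @param registry a `trait_registry`.
#' @param path file path.
#' @return `read_trait_registry()` returns a `trait_registry`.
#' @export
write_trait_registry <- function(registry, path) {
  jsonlite::write_json(
    list(descriptors = registry[, c("name", "kind", "layering", "layers")],
         micro = setNames(registry$micro, registry$name)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trait_registry
#' @export
read_trait_registry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- as_tibble(obj$descriptors)
  reg$layers <- as.integer(reg$layers)
  reg$micro <- lapply(obj$micro[reg$name], function(x) as.character(unlist(x)))
  class(reg) <- c("trait_registry", class(reg))
  reg
}

#' Center of mass of the root, normalized to the bounding box
#'
#' Foreground centroid expressed in `[0, 1]` relative to the root bounding
#' box on each axis; a degenerate 1-px-wide box reports 0.5 on that axis.
#'
#' @param mask a nonempty [root_mask()].
#' @return Named vector `c(com_x, com_y)`.
#' @export
center_of_mass <- function(mask) {
  fg <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("empty mask", class = "rhizo_measurement_error")
  }
  bb <- mask_bbox(mask)
  rbar <- mean(fg[, 1] - 1); cbar <- mean(fg[, 2] - 1)
  wx <- bb["max_col"] - bb["min_col"]
  wy <- bb["max_row"] - bb["min_row"]
  c(com_x = if (wx == 0) 0.5 else unname((cbar - bb["min_col"]) / wx),
    com_y = if (wy == 0) 0.5 else unname((rbar - bb["min_row"]) / wy))
}

# Andrew monotone-chain convex hull of (x, y) points; returns hull vertices
# counterclockwise. Input: 2-col matrix.
monotone_chain_hull <- function(pts) {
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2) return(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    hull <- integer(0)
    for (i in idx) {
      while (length(hull) >= 2 &&
             cross(pts[hull[length(hull) - 1], ], pts[hull[length(hull)], ],
                   pts[i, ]) <= 0) {
        hull <- hull[-length(hull)]
      }
      hull <- c(hull, i)
    }
    hull
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  pts[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Convex hull area of the root
#'
#' Area of the minimal convex polygon over foreground pixel centers
#' (monotone-chain hull + shoelace). Collinear point sets report 0.
#'
#' @param mask a nonempty [root_mask()].
#' @return Area in px^2.
#' @export
convex_hull_area <- function(mask) {
  fg <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("empty mask", class = "rhizo_measurement_error")
  }
  pts <- cbind(x = fg[, 2] - 1, y = fg[, 1] - 1)
  shoelace_area(monotone_chain_hull(pts))
}

#' Stratified depth profile of root area
#'
#' The bounding-box rows are split into `L` equal-height half-open bands
#' (the last band absorbs the remainder); each channel is the fraction of
#' foreground pixels falling in that band, so the channels sum to 1.
#'
#' @param mask a nonempty [root_mask()].
#' @param L number of strata (default 4).
#' @return Numeric vector of `L` proportions.
#' @export
rect_profile <- function(mask, L = 4L) {
  L <- stopifnot_scalar_count(L, "L")
  fg <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("empty mask", class = "rhizo_measurement_error")
  }
  bb <- mask_bbox(mask)
  H <- bb["max_row"] - bb["min_row"] + 1
  band <- band_index(fg[, 1] - 1 - bb["min_row"], H, L)
  counts <- tabulate(band, nbins = L)
  counts / sum(counts)
}

#' Ellipse-ladder coverage profile
#'
#' Concentric ellipses centred on the root apex (centroid of the topmost
#' foreground row) with base semi-axes `a0 = max(W/2, 1)` horizontally and
#' `b0 = max(H, 1)` vertically from the bounding box; each pixel's
#' normalized ellipse coordinate is `s = sqrt((dx/a0)^2 + (dy/b0)^2)` and
#' channel `k` is the fraction of root pixels with `s <= (k/K) * s_max`.
#' Channels are non-decreasing and the last channel is exactly 1.
#'
#' @param mask a nonempty [root_mask()].
#' @param K ladder size (default 12).
#' @return Numeric vector of `K` fractions.
#' @export
ellips_profile <- function(mask, K = 12L) {
  K <- stopifnot_scalar_count(K, "K")
  fg <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("empty mask", class = "rhizo_measurement_error")
  }
  bb <- mask_bbox(mask)
  rows0 <- fg[, 1] - 1; cols0 <- fg[, 2] - 1
  top <- rows0 == bb["min_row"]
  apex <- c(row = unname(bb["min_row"]), col = mean(cols0[top]))
  W <- bb["max_col"] - bb["min_col"] + 1
  H <- bb["max_row"] - bb["min_row"] + 1
  a0 <- max(W / 2, 1); b0 <- max(H, 1)
  s <- sqrt(((cols0 - apex["col"]) / a0)^2 + ((rows0 - apex["row"]) / b0)^2)
  smax <- max(s)
  if (smax == 0) return(rep(1, K))
  vapply(seq_len(K), function(k) mean(s <= (k / K) * smax + 1e-12), numeric(1))
}

#' Layered horizontal extent of the root shape
#'
#' `coord_x_profile()`: per depth band, the horizontal extent of foreground
#' in that band (`max_col - min_col + 1`) normalized by the bounding-box
#' width; 0 for empty bands. `diff_x_profile()`: first differences of the
#' coord_x layers (`diff_x_0 = coord_x_0`); larger values indicate a wider
#' opening angle at that depth.
#'
#' @param mask a nonempty [root_mask()].
#' @param L number of depth layers (default 10).
#' @return Numeric vector of `L` values.
#' @export
coord_x_profile <- function(mask, L = 10L) {
  L <- stopifnot_scalar_count(L, "L")
  fg <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("empty mask", class = "rhizo_measurement_error")
  }
  bb <- mask_bbox(mask)
  W <- bb["max_col"] - bb["min_col"] + 1
  H <- bb["max_row"] - bb["min_row"] + 1
  band <- band_index(fg[, 1] - 1 - bb["min_row"], H, L)
  out <- numeric(L)
  for (i in unique(band)) {
    cc <- fg[band == i, 2]
    out[i] <- (max(cc) - min(cc) + 1) / W
  }
  out
}

#' @rdname coord_x_profile
#' @param coord_x a vector returned by `coord_x_profile()`.
#' @export
diff_x_profile <- function(coord_x) {
  c(coord_x[1], diff(coord_x))
}

# Count maximal runs of 1s in each row of a 0/1 matrix, vectorised.
row_run_counts <- function(m) {
  starts <- m == 1L & cbind(1L, m[, -ncol(m), drop = FALSE] != 1L)
  rowSums(starts)
}

#' Scan-line crossing counts
#'
#' For every scan line inside the root bounding box, the number of maximal
#' foreground runs it crosses — a proxy for the number of distinct roots at
#' that depth (horizontal axis) or width (vertical axis). Returns the global
#' mean and max over scan lines plus the mean run count within each of `L`
#' equal bands of the bounding box (0 for empty bands).
#'
#' @param mask a nonempty [root_mask()].
#' @param axis `"horizontal"` (scan rows over depth) or `"vertical"`.
#' @param L number of layer bands (default 30).
#' @return List with `mean`, `max`, and `layers` (length `L`).
#' @export
crossing_counts <- function(mask, axis = c("horizontal", "vertical"), L = 30L) {
  axis <- match.arg(axis)
  L <- stopifnot_scalar_count(L, "L")
  if (sum(mask$values) == 0) {
    abort("empty mask", class = "rhizo_measurement_error")
  }
  bb <- mask_bbox(mask)
  sub <- mask$values[(bb["min_row"]:bb["max_row"]) + 1L,
                     (bb["min_col"]:bb["max_col"]) + 1L, drop = FALSE]
  if (axis == "vertical") sub <- t(sub)
  counts <- row_run_counts(sub)
  n <- length(counts)
  band <- band_index(seq_len(n) - 1L, n, L)
  layers <- vapply(seq_len(L), function(i) {
    x <- counts[band == i]
    if (length(x)) mean(x) else 0
  }, numeric(1))
  list(mean = mean(counts), max = max(counts), layers = layers)
}

#' Compute the full trait vector for one view
#'
#' Fills every channel of the registry from a root mask and its skeleton
#' graph. Macro summaries of the layered descriptors are: `ellips` = the
#' coverage at rung `ceiling(K/2)`, `rect` = the top stratum's proportion,
#' `coord_x` = mean over layers, `diff_x` = mean over layers 1..L-1,
#' crossing means/maxes = global scan-line statistics. Deterministic.
#'
#' @param mask a nonempty [root_mask()].
#' @param graph the `skeleton_graph` derived from `mask` (computed when
#'   omitted); passing a graph from a different mask is a validation error.
#' @param registry a `trait_registry`.
#' @return A one-row tibble with one column per registry channel.
#' @export
compute_trait_vector <- function(mask, graph = NULL,
                                 registry = default_trait_registry()) {
  if (sum(mask$values) == 0) {
    abort("empty mask", class = "rhizo_measurement_error")
  }
  if (is.null(graph)) graph <- skeletonize(mask)
  if (!identical(graph$mask_dim, c(mask$height, mask$width)) ||
      graph$mask_area != sum(mask$values) ||
      any(graph$skeleton == 1L & mask$values == 0L)) {
    abort("skeleton graph was not derived from this mask",
          class = "rhizo_validation_error")
  }
  layers_of <- function(nm) registry$layers[registry$name == nm]
  com <- center_of_mass(mask)
  K <- layers_of("ellips"); Lr <- layers_of("rect"); Lc <- layers_of("coord_x")
  Lh <- layers_of("cross_hori_mean"); Lv <- layers_of("cross_vert_mean")
  ell <- ellips_profile(mask, K)
  rect <- rect_profile(mask, Lr)
  cx <- coord_x_profile(mask, Lc)
  dx <- diff_x_profile(cx)
  ch <- crossing_counts(mask, "horizontal", Lh)
  cv <- crossing_counts(mask, "vertical", Lv)
  macro <- c(
    com_x = unname(com["com_x"]), com_y = unname(com["com_y"]),
    ellips = ell[ceiling(K / 2)],
    rect = rect[1],
    convexhull = convex_hull_area(mask),
    coord_x = mean(cx),
    diff_x = mean(dx[-1]),
    diam_mean = mean_diameter(graph),
    length = measure_length(graph),
    area = sum(mask$values),
    directionality = if (nrow(graph$edges)) directionality(graph) else 0,
    tip_count = count_tips(graph),
    cross_hori_mean = ch$mean, cross_hori_max = ch$max,
    cross_vert_mean = cv$mean, cross_vert_max = cv$max)
  micro <- c(
    setNames(ell, registry$micro[[which(registry$name == "ellips")]]),
    setNames(rect, registry$micro[[which(registry$name == "rect")]]),
    setNames(cx, registry$micro[[which(registry$name == "coord_x")]]),
    setNames(dx, registry$micro[[which(registry$name == "diff_x")]]),
    setNames(ch$layers, registry$micro[[which(registry$name == "cross_hori_mean")]]),
    setNames(cv$layers, registry$micro[[which(registry$name == "cross_vert_mean")]]))
  vec <- c(macro, micro)
  stopifnot(identical(names(vec), registry_channel_names(registry)))
  as_tibble(as.list(vec))
}
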