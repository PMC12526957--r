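#' Construct a raster image
#'
#' A raster image is a numeric matrix of intensities in `[0, 1]` with the
#' origin at the top-left corner: row index is depth (increases downward),
#' indices are 0-based in all user-facing coordinate output.
#'
#' @param values numeric matrix in `[0, 1]`, rows = image rows.
#' @param bit_depth_source source bit depth, 8 or 16.
#' @param channels_source `"gray"` or `"rgb"`.
#' @return A `raster_image` object.
#' @export
raster_image <- function(values, bit_depth_source = 8L, channels_source = "gray") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", class = "rhizo_format_error")
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    abort("image must have width >= 1 and height >= 1", class = "rhizo_format_error")
  }
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    abort("image values must lie in [0, 1]", class = "rhizo_format_error")
  }
  structure(
    list(values = values, width = ncol(values), height = nrow(values),
         bit_depth_source = as.integer(bit_depth_source),
         channels_source = channels_source),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d px, %d-bit %s source>\n",
              x$width, x$height, x$bit_depth_source, x$channels_source))
  invisible(x)
}

#' Construct a binary root mask
#'
#' @param values matrix coercible to 0/1; same orientation as [raster_image()].
#' @return A `root_mask` object.
#' @export
root_mask <- function(values) {
  if (!is.matrix(values)) {
    abort("`values` must be a matrix", class = "rhizo_format_error")
  }
  v <- matrix(as.integer(values != 0), nrow(values), ncol(values))
  structure(list(values = v, width = ncol(v), height = nrow(v)),
            class = "root_mask")
}

#' @export
print.root_mask <- function(x, ...) {
  cat(sprintf("<root_mask %d x %d px, %d foreground px>\n",
              x$width, x$height, sum(x$values)))
  invisible(x)
}

mask_area <- function(mask) sum(mask$values)

# Bounding box of foreground as 0-based [min_row, max_row, min_col, max_col].
mask_bbox <- function(mask) {
  fg <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("mask has no foreground pixels", class = "rhizo_measurement_error")
  }
  c(min_row = min(fg[, 1]) - 1L, max_row = max(fg[, 1]) - 1L,
    min_col = min(fg[, 2]) - 1L, max_col = max(fg[, 2]) - 1L)
}

rgb_luminance <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Load a PNG or TIFF image as a normalized grayscale raster
#'
#' 8-bit sources are scaled by 1/255 and 16-bit sources by 1/65535 so all
#' values land in `[0, 1]`. RGB images are converted to luminance with the
#' ITU-R 601 weights `0.299 R + 0.587 G + 0.114 B`; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [raster_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path), class = "rhizo_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    depth <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    depth <- if (!is.null(bits)) as.integer(bits[1]) else 8L
  } else {
    abort(sprintf("unsupported image format '%s' for %s", ext, path),
          class = "rhizo_format_error")
  }
  if (!depth %in% c(8L, 16L)) {
    abort(sprintf("unsupported bit depth %d in %s", depth, path),
          class = "rhizo_format_error")
  }
  channels <- "gray"
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      arr <- rgb_luminance(arr)
      channels <- "rgb"
    } else {
      arr <- arr[, , 1]   # gray + alpha: keep the gray plane
    }
  }
  # readPNG/readTIFF already divide by 2^depth - 1; clamp fp residue.
  vals <- pmin(pmax(unclass(arr), 0), 1)
  raster_image(matrix(vals, nrow(arr), ncol(arr)),
               bit_depth_source = depth, channels_source = channels)
}

#' Load a binary mask from a PNG (background 0, foreground 255)
#'
#' @param path path to a PNG mask file.
#' @return A [root_mask()].
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  root_mask(img$values > 0.5)
}

#' Parse accession / replicate / angle from a filename
#'
#' The pattern is a template with `{accession}`, `{replicate}` and `{angle}`
#' placeholders, e.g. `"{accession}_r{replicate}_a{angle}.png"`. The angle is
#' normalized to `[0, 360)` and validated against the angular step of the
#' turntable protocol.
#'
#' @param filename file name (directory part ignored).
#' @param pattern template string containing all three placeholders.
#' @param step_deg angular step in degrees the angle must be a multiple of;
#'   `NULL` skips the check. Default 15, the 24-view protocol.
#' @return A one-row tibble with columns `accession`, `replicate`, `angle`.
#' @export
#' @examples
#' parse_view_metadata("Psi0924_r1_a015.png")
parse_view_metadata <- function(filename,
                                pattern = "{accession}_r{replicate}_a{angle}.png",
                                step_deg = 15L) {
  fn <- basename(filename)
  fields <- c("accession", "replicate", "angle")
  # Escape regex metacharacters, then swap placeholders for capture groups.
  rx <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pattern)
  order <- regmatches(pattern, gregexpr("\\{(accession|replicate|angle)\\}", pattern))[[1]]
  order <- gsub("[{}]", "", order)
  if (!setequal(order, fields)) {
    abort("pattern must contain {accession}, {replicate} and {angle} exactly once",
          class = "rhizo_parameter_error")
  }
  rx <- sub("\\\\\\{accession\\\\\\}", "(.+?)", rx)
  rx <- sub("\\\\\\{replicate\\\\\\}", "([0-9]+)", rx)
  rx <- sub("\\\\\\{angle\\\\\\}", "([0-9]+)", rx)
  m <- regexec(paste0("^", rx, "$"), fn)
  parts <- regmatches(fn, m)[[1]]
  if (length(parts) != 4) {
    abort(sprintf("filename '%s' does not match pattern '%s'", fn, pattern),
          class = "rhizo_parse_error")
  }
  vals <- setNames(parts[-1], order)
  angle <- as.integer(vals[["angle"]]) %% 360L
  replicate <- as.integer(vals[["replicate"]])
  if (replicate < 1) {
    abort("replicate must be >= 1", class = "rhizo_validation_error")
  }
  if (!is.null(step_deg) && angle %% step_deg != 0) {
    abort(sprintf("angle %d is not a multiple of the %d degree step", angle, step_deg),
          class = "rhizo_validation_error")
  }
  tibble(accession = vals[["accession"]], replicate = replicate, angle = angle)
}

key_columns <- function(table) {
  intersect(c("accession", "replicate", "angle"), names(table))
}

#' Write / read a trait table as CSV
#'
#' The on-disk format is plain UTF-8 CSV with `.` decimals: key columns
#' (`accession`, `replicate`, `angle` — whichever are present) followed by the
#' registry's channel columns in registry order. Lines starting with `#` are
#' provenance comments and are skipped on read. A round trip reproduces key
#' columns bitwise and values to at least 12 significant digits.
#'
#' @param table tibble of trait rows.
#' @param path output CSV path.
#' @param registry trait registry defining the expected channel columns.
#' @param comment_lines optional character vector written as `#`-prefixed
#'   provenance header lines.
#' @return `write_trait_table()` returns `path` invisibly; `read_trait_table()`
#'   returns a tibble.
#' @export
write_trait_table <- function(table, path, registry = default_trait_registry(),
                              comment_lines = NULL) {
  chans <- registry_channel_names(registry)
  keys <- key_columns(table)
  missing <- setdiff(chans, names(table))
  if (length(missing)) {
    abort(sprintf("table lacks registry channels: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "rhizo_schema_error")
  }
  out <- table[, c(keys, chans), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment_lines)) {
    writeLines(paste0("# ", comment_lines), con)
  }
  writeLines(paste(c(keys, chans), collapse = ","), con)
  if (nrow(out) > 0) {
    fmt_cell <- function(x) {
      if (is.numeric(x) && !is.integer(x)) sprintf("%.15g", x) else as.character(x)
    }
    body <- do.call(cbind, lapply(out, fmt_cell))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path, registry = default_trait_registry()) {
  if (!file.exists(path)) {
    abort(sprintf("trait table not found: %s", path), class = "rhizo_io_error")
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  chans <- registry_channel_names(registry)
  missing <- setdiff(chans, names(tbl))
  if (length(missing)) {
    abort(sprintf("CSV header lacks registry channels: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "rhizo_schema_error")
  }
  if ("replicate" %in% names(tbl)) tbl$replicate <- as.integer(tbl$replicate)
  if ("angle" %in% names(tbl)) tbl$angle <- as.integer(tbl$angle)
  as_tibble(tbl[, c(key_columns(tbl), chans), drop = FALSE])
}
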