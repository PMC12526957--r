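# End-to-end per-view trait extraction: image -> mask -> skeleton -> traits.

#' Extract the trait vector from a single image or mask
#'
#' Runs segmentation (unless a pre-made mask is supplied), mask cleanup,
#' skeletonization and the full descriptor set.
#'
#' @param img a [raster_image()], or `NULL` when `mask` is given.
#' @param mask optional pre-made [root_mask()]; skips segmentation.
#' @param method segmentation method: `"otsu"` or a `segmentation_model`.
#' @param registry trait registry.
#' @param min_size,fill_holes,keep_largest mask cleanup, see [clean_mask()].
#' @param bg_radius background-subtraction radius for Otsu mode.
#' @return One-row tibble of trait channels.
#' @export
extract_traits <- function(img = NULL, mask = NULL, method = "otsu",
                           registry = default_trait_registry(),
                           min_size = 20, fill_holes = FALSE,
                           keep_largest = FALSE, bg_radius = 15) {
  if (is.null(mask)) {
    if (is.null(img)) {
      abort("need an image or a mask", class = "rhizo_parameter_error")
    }
    mask <- segment(img, method = method, bg_radius = bg_radius)
  }
  mask <- clean_mask(mask, min_size = min_size, fill_holes = fill_holes,
                     keep_largest = keep_largest)
  compute_trait_vector(mask, registry = registry)
}

#' Extract traits for every view image in a directory
#'
#' Scans `in_dir` for files matching the filename pattern, parses the
#' (accession, replicate, angle) key from each name, and measures the full
#' trait vector per view. With `mode = "masks"`, pre-made binary masks named
#' `mask_<image name>` are used instead of running segmentation.
#'
#' @param in_dir input directory.
#' @param pattern filename template, see [parse_view_metadata()].
#' @param mode `"otsu"`, `"model"` or `"masks"`.
#' @param model a `segmentation_model` (required for `mode = "model"`).
#' @param step_deg angular step for key validation.
#' @inheritParams extract_traits
#' @return A trait table tibble: key columns plus one column per channel.
#' @export
measure_traits_dir <- function(in_dir,
                               pattern = "{accession}_r{replicate}_a{angle}.png",
                               mode = c("otsu", "model", "masks"),
                               model = NULL, step_deg = 15L,
                               registry = default_trait_registry(),
                               min_size = 20, fill_holes = FALSE,
                               keep_largest = FALSE, bg_radius = 15) {
  mode <- match.arg(mode)
  if (mode == "model" && !inherits(model, "segmentation_model")) {
    abort("mode = \"model\" requires a trained segmentation model",
          class = "rhizo_parameter_error")
  }
  files <- list.files(in_dir, pattern = "\\.(png|tif|tiff)$")
  files <- files[!startsWith(files, "mask_")]
  keyed <- list()
  for (f in files) {
    key <- tryCatch(parse_view_metadata(f, pattern, step_deg),
                    error = function(e) NULL)
    if (!is.null(key)) keyed[[f]] <- key
  }
  if (length(keyed) == 0) {
    abort(sprintf("no files in %s match pattern '%s'", in_dir, pattern),
          class = "rhizo_io_error")
  }
  rows <- imap(keyed, function(key, f) {
    traits <- if (mode == "masks") {
      mp <- file.path(in_dir, paste0("mask_", f))
      if (!file.exists(mp)) {
        abort(sprintf("pre-made mask not found: %s", mp), class = "rhizo_io_error")
      }
      extract_traits(mask = load_mask(mp), registry = registry,
                     min_size = min_size, fill_holes = fill_holes,
                     keep_largest = keep_largest)
    } else {
      extract_traits(img = load_image(file.path(in_dir, f)),
                     method = if (mode == "model") model else "otsu",
                     registry = registry, min_size = min_size,
                     fill_holes = fill_holes, keep_largest = keep_largest,
                     bg_radius = bg_radius)
    }
    bind_cols(key, traits)
  })
  bind_rows(rows) %>% arrange(.data$accession, .data$replicate, .data$angle)
}
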