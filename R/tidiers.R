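# broom-style tidiers for fitted objects and result matrices.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segmentation model
#'
#' One row per feature plane with its impurity importance.
#'
#' @param x a `segmentation_model`.
#' @param ... unused.
#' @return A tibble with `feature` and `importance`, most important first.
#' @export
tidy.segmentation_model <- function(x, ...) {
  imp <- ranger::importance(x$forest)
  tibble(feature = names(imp), importance = unname(imp)) %>%
    arrange(dplyr::desc(.data$importance))
}

#' Glance at a segmentation model
#'
#' @param x a `segmentation_model`.
#' @param ... unused.
#' @return One-row tibble: trees, features, training pixels, out-of-bag
#'   Brier score, seed.
#' @export
glance.segmentation_model <- function(x, ...) {
  tibble(trees = x$trees,
         n_features = length(x$forest$forest$independent.variable.names),
         n_train_px = x$n_train,
         oob_brier = x$forest$prediction.error,
         seed = x$seed)
}

#' Tidy a trait correlation matrix
#'
#' @param x a `trait_correlation` matrix.
#' @param ... unused.
#' @return Long tibble with `channel_a`, `channel_b`, `r`.
#' @export
tidy.trait_correlation <- function(x, ...) {
  tidy_correlation(x)
}

#' Glance at a trait correlation matrix
#'
#' @param x a `trait_correlation` matrix.
#' @param ... unused.
#' @return One-row tibble: channel count, finite-pair count, strongest
#'   off-diagonal correlation.
#' @export
glance.trait_correlation <- function(x, ...) {
  off <- unclass(x); diag(off) <- NA
  tibble(n_channels = ncol(x),
         n_defined_pairs = sum(!is.na(off)) / 2,
         max_abs_r = if (all(is.na(off))) NA_real_ else max(abs(off), na.rm = TRUE))
}
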