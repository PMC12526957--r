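# ggplot2 visualisations for masks, skeletons and correlation matrices.

mask_to_df <- function(values) {
  idx <- which(values != 0, arr.ind = TRUE)
  tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
}

#' Plot a root mask
#'
#' Foreground pixels as tiles, depth increasing downward.
#'
#' @param object a [root_mask()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.root_mask <- function(object, ...) {
  df <- mask_to_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(fill = "grey15") +
    ggplot2::scale_y_reverse(limits = c(object$height - 1, 0)) +
    ggplot2::coord_fixed(xlim = c(0, object$width - 1)) +
    ggplot2::labs(x = "column (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
}

#' Plot a skeleton graph over its mask outline
#'
#' Edges as paths, endpoints and junctions as points sized by local radius;
#' the crown node is highlighted.
#'
#' @param object a `skeleton_graph`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.skeleton_graph <- function(object, ...) {
  edf <- purrr::imap(object$edges$chain, function(ch, i) {
    tibble(edge = i, row = ch[, 1], col = ch[, 2])
  }) %>% bind_rows()
  ndf <- object$nodes %>%
    mutate(role = dplyr::case_when(
      .data$id == object$crown_node ~ "crown",
      .data$degree == 1 ~ "tip",
      TRUE ~ "junction"))
  p <- ggplot2::ggplot()
  if (nrow(edf)) {
    p <- p + ggplot2::geom_path(
      data = edf,
      ggplot2::aes(x = .data$col, y = .data$row, group = .data$edge),
      colour = "grey40")
  }
  if (nrow(ndf)) {
    p <- p + ggplot2::geom_point(
      data = ndf,
      ggplot2::aes(x = .data$col, y = .data$row, colour = .data$role,
                   size = .data$radius))
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(x = "column (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a trait correlation matrix
#'
#' @param object a `trait_correlation`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.trait_correlation <- function(object, ...) {
  df <- tidy_correlation(object)
  lev <- rownames(object)
  df$channel_a <- factor(df$channel_a, levels = lev)
  df$channel_b <- factor(df$channel_b, levels = rev(lev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel_a, y = .data$channel_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Depth profile of layered microphenotype channels
#'
#' Bar chart of one layered descriptor's channels from a trait vector row.
#'
#' @param traits one-row tibble from [compute_trait_vector()].
#' @param descriptor layered descriptor name, e.g. `"coord_x"` or `"rect"`.
#' @param registry the trait registry used to compute `traits`.
#' @return A ggplot.
#' @export
plot_layer_profile <- function(traits, descriptor = "coord_x",
                               registry = default_trait_registry()) {
  chans <- registry$micro[[match(descriptor, registry$name)]]
  if (is.null(chans) || !length(chans)) {
    abort(sprintf("'%s' is not a layered descriptor", descriptor),
          class = "rhizo_parameter_error")
  }
  df <- tibble(layer = seq_along(chans) - 1L,
               value = as.numeric(traits[1, chans]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = sprintf("%s layer", descriptor), y = "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
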