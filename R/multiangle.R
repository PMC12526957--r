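# Multiangle view aggregation, trait correlation, and the 1/n suggestive
# association threshold.

#' Expected number of views per full turntable revolution
#'
#' @param step_deg angular step in degrees; must divide 360. The 15-degree
#'   protocol yields 24 views.
#' @return Integer view count `360 / step_deg`.
#' @export
expected_view_count <- function(step_deg) {
  stopifnot_scalar_count(step_deg, "step_deg")
  if (step_deg > 360 || 360 %% step_deg != 0) {
    abort("`step_deg` must divide 360", class = "rhizo_parameter_error")
  }
  as.integer(360 / step_deg)
}

#' Aggregate per-view trait vectors into per-accession summaries
#'
#' Takes a trait table with one row per (accession, replicate, angle) view
#' and returns per-accession arithmetic means over all views, replicates
#' pooled. Population standard deviations (n denominator) are appended as
#' `<channel>_sd` columns when `include_sd` is `TRUE`. A warning lists the
#' missing angles of any replicate with fewer than the expected number of
#' views.
#'
#' @param table tibble with key columns `accession` (and optionally
#'   `replicate`, `angle`) plus registry channel columns.
#' @param registry the `trait_registry` defining the channel columns.
#' @param step_deg angular step used to detect incomplete view sets.
#' @param include_sd append per-channel standard deviations.
#' @return A tibble with `accession`, `n_views`, and channel columns.
#' @export
aggregate_accessions <- function(table, registry = default_trait_registry(),
                                 step_deg = 15L, include_sd = FALSE) {
  if (nrow(table) == 0) {
    abort("no view rows to aggregate", class = "rhizo_validation_error")
  }
  chans <- registry_channel_names(registry)
  missing <- setdiff(chans, names(table))
  if (length(missing)) {
    abort(sprintf("trait table lacks registry channels: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "rhizo_validation_error")
  }
  if (!"accession" %in% names(table)) {
    abort("trait table lacks an `accession` key column",
          class = "rhizo_validation_error")
  }
  if (all(c("replicate", "angle") %in% names(table))) {
    dup <- table %>% dplyr::count(.data$accession, .data$replicate, .data$angle) %>%
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort("duplicate (accession, replicate, angle) view keys",
            class = "rhizo_validation_error")
    }
    n_exp <- expected_view_count(step_deg)
    short <- table %>%
      group_by(.data$accession, .data$replicate) %>%
      summarise(n = dplyr::n(),
                missing = paste(setdiff(seq(0, 359, by = step_deg),
                                        .data$angle), collapse = ","),
                .groups = "drop") %>%
      filter(.data$n < n_exp)
    if (nrow(short) > 0) {
      warn(sprintf(
        "incomplete view sets: %s",
        paste(sprintf("%s r%d missing angles {%s}", short$accession,
                      short$replicate, short$missing), collapse = "; ")))
    }
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  means <- table %>%
    group_by(.data$accession) %>%
    summarise(n_views = dplyr::n(),
              across(all_of(chans), mean), .groups = "drop")
  if (include_sd) {
    sds <- table %>%
      group_by(.data$accession) %>%
      summarise(across(all_of(chans), pop_sd, .names = "{.col}_sd"),
                .groups = "drop")
    means <- left_join(means, sds, by = "accession")
  }
  means
}

#' Pearson correlation matrix over trait channels
#'
#' Pairwise Pearson r over accession-level channel values. Channels with
#' zero variance yield `NA` entries and a warning. The diagonal is exactly 1
#' for well-defined channels.
#'
#' @param table accession-level tibble (rows = accessions) containing the
#'   registry channel columns; at least 3 rows.
#' @param registry the `trait_registry` naming the channels.
#' @return A symmetric `trait_correlation` matrix with channel dimnames.
#' @export
pearson_correlation_matrix <- function(table, registry = default_trait_registry()) {
  chans <- intersect(registry_channel_names(registry), names(table))
  if (nrow(table) < 3) {
    abort("need at least 3 accessions for correlation",
          class = "rhizo_statistics_error")
  }
  m <- as.matrix(table[, chans, drop = FALSE])
  const <- apply(m, 2, function(x) isTRUE(sd(x) == 0))
  if (any(const)) {
    warn(sprintf("constant channels yield undefined correlations: %s",
                 paste(head(chans[const], 8), collapse = ", ")))
  }
  r <- suppressWarnings(cor(m, method = "pearson"))
  d <- diag(r); d[!const] <- 1; diag(r) <- d
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  structure(r, class = c("trait_correlation", class(r)))
}

#' Write a trait correlation matrix as CSV
#'
#' Writes the square labeled matrix, and optionally a long-format table
#' (`channel_a`, `channel_b`, `r`) for plotting.
#'
#' @param r a `trait_correlation` matrix.
#' @param path output CSV path for the square matrix.
#' @param long_path optional output path for the long format.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(r, path, long_path = NULL) {
  df <- cbind(tibble(channel = rownames(r)), as_tibble(unclass(r)))
  readr::write_csv(df, path, progress = FALSE)
  if (!is.null(long_path)) {
    readr::write_csv(tidy_correlation(r), long_path, progress = FALSE)
  }
  invisible(path)
}

tidy_correlation <- function(r) {
  tibble(
    channel_a = rep(rownames(r), times = ncol(r)),
    channel_b = rep(colnames(r), each = nrow(r)),
    r = as.vector(unclass(r)))
}

#' Suggestive genome-wide significance threshold
#'
#' The reciprocal of the effective number of independent tests, `1 / n` —
#' with the panel's 639,988 SNPs this is 1.56e-6.
#'
#' @param n_tests effective number of independent tests, `>= 1`.
#' @return The threshold probability.
#' @export
suggestive_threshold <- function(n_tests) {
  if (length(n_tests) != 1 || !is.numeric(n_tests) || is.na(n_tests) ||
      n_tests < 1) {
    abort("`n_tests` must be a single number >= 1",
          class = "rhizo_parameter_error")
  }
  1 / n_tests
}
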