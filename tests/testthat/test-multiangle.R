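test_that("view counts follow the angular step", {
  expect_equal(expected_view_count(15), 24L)
  expect_equal(expected_view_count(90), 4L)
  expect_error(expected_view_count(7), class = "rhizo_parameter_error")
  expect_error(expected_view_count(0), class = "rhizo_parameter_error")
})

mk_view_table <- function(values_by_view, angles, accession = "A", rep = 1L) {
  reg <- default_trait_registry()
  chans <- registry_channel_names(reg)
  rows <- lapply(seq_along(angles), function(i) {
    vals <- tibble::as_tibble(as.list(setNames(rep(values_by_view[i],
                                                   length(chans)), chans)))
    dplyr::bind_cols(tibble::tibble(accession = accession, replicate = rep,
                                    angle = angles[i]), vals)
  })
  dplyr::bind_rows(rows)
}

test_that("accession aggregation averages all views", {
  angles <- seq(0, 345, by = 15)
  tbl <- mk_view_table(rep(3.5, 24), angles)
  agg <- aggregate_accessions(tbl, include_sd = TRUE)
  expect_equal(agg$n_views, 24L)
  expect_equal(agg$convexhull, 3.5)
  expect_equal(agg$convexhull_sd, 0)

  tbl2 <- mk_view_table(c(2, 4), c(0, 15))
  expect_warning(agg2 <- aggregate_accessions(tbl2, include_sd = TRUE),
                 "missing angles")
  expect_equal(agg2$length, 3)
  expect_equal(agg2$length_sd, 1)   # population sd of {2, 4}

  tbl23 <- mk_view_table(rep(1, 23), angles[-7])
  expect_warning(agg3 <- aggregate_accessions(tbl23), "90")
  expect_equal(agg3$n_views, 23L)
})

test_that("aggregation is permutation-invariant and validates keys", {
  angles <- seq(0, 345, by = 15)
  set.seed(1)
  tbl <- mk_view_table(runif(24, 0, 10), angles)
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(aggregate_accessions(tbl), aggregate_accessions(shuffled))

  dup <- dplyr::bind_rows(tbl, tbl[1, ])
  expect_error(aggregate_accessions(dup), class = "rhizo_validation_error")
  expect_error(aggregate_accessions(tbl[0, ]), class = "rhizo_validation_error")
})

test_that("correlation matrix matches hand-built relationships", {
  reg <- default_trait_registry()
  chans <- registry_channel_names(reg)
  set.seed(42)
  n <- 12
  base <- runif(n)
  m <- matrix(runif(n * length(chans)), n)
  colnames(m) <- chans
  m[, "com_x"] <- base
  m[, "com_y"] <- 2 * base          # perfectly correlated
  m[, "length"] <- -base            # perfectly anti-correlated
  tbl <- dplyr::bind_cols(tibble::tibble(accession = sprintf("A%02d", 1:n)),
                          tibble::as_tibble(m))
  r <- pearson_correlation_matrix(tbl, reg)
  expect_equal(r["com_x", "com_y"], 1)
  expect_equal(r["com_x", "length"], -1)
  expect_true(isSymmetric(unclass(r), tol = 1e-12))
  fin <- r[is.finite(r)]
  expect_true(all(fin >= -1 - 1e-12 & fin <= 1 + 1e-12))
  expect_true(all(diag(r) == 1))

  m2 <- m; m2[, "area"] <- 7        # constant channel
  tbl2 <- dplyr::bind_cols(tibble::tibble(accession = sprintf("A%02d", 1:n)),
                           tibble::as_tibble(m2))
  expect_warning(r2 <- pearson_correlation_matrix(tbl2, reg), "constant")
  expect_true(all(is.na(r2["area", ])))

  expect_error(pearson_correlation_matrix(tbl[1:2, ], reg),
               class = "rhizo_statistics_error")
})

test_that("correlation tidiers and CSV writer agree with the matrix", {
  reg <- default_trait_registry()
  chans <- registry_channel_names(reg)
  set.seed(3)
  m <- matrix(runif(10 * length(chans)), 10)
  colnames(m) <- chans
  tbl <- dplyr::bind_cols(tibble::tibble(accession = sprintf("A%d", 1:10)),
                          tibble::as_tibble(m))
  r <- pearson_correlation_matrix(tbl, reg)
  long <- tidy(r)
  expect_equal(nrow(long), length(chans)^2)
  expect_equal(long$r[long$channel_a == "com_x" & long$channel_b == "com_y"],
               r["com_x", "com_y"])
  d <- withr::local_tempdir()
  write_correlation_csv(r, file.path(d, "corr.csv"),
                        long_path = file.path(d, "corr_long.csv"))
  sq <- readr::read_csv(file.path(d, "corr.csv"), show_col_types = FALSE)
  expect_equal(nrow(sq), length(chans))
  g <- glance(r)
  expect_equal(g$n_channels, length(chans))
})

test_that("suggestive threshold is 1/n and strictly decreasing", {
  expect_equal(signif(suggestive_threshold(639988), 3), 1.56e-6)
  expect_equal(suggestive_threshold(1), 1)
  expect_equal(suggestive_threshold(20), 0.05)
  expect_error(suggestive_threshold(0), class = "rhizo_parameter_error")
  ns <- c(1, 2, 10, 1e3, 1e6, 639988 * 2)
  th <- vapply(sort(ns), suggestive_threshold, numeric(1))
  expect_true(all(diff(th) < 0))
})
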