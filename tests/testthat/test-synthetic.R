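test_that("degenerate growth settings give analytic root systems", {
  # no branching: exactly one axis, one tip
  s1 <- synthetic_root_spec(seed = 2, n_primary = 1, branch_rate = 0,
                            stem_len = 0)
  sim1 <- simulate_root_system(s1)
  expect_equal(sim1$ground_truth$n_axes, 1L)
  expect_equal(sim1$ground_truth$tip_count, 1L)

  # zero tortuosity + full gravitropism: straight vertical axis
  s2 <- synthetic_root_spec(seed = 5, n_primary = 1, tortuosity_sd = 0,
                            gravitropism = 1, branch_rate = 0, stem_len = 0,
                            step_len = 4, n_steps = 40)
  sim2 <- simulate_root_system(s2)
  expect_equal(sim2$ground_truth$total_length, 4 * 40)
  pts <- sim2$axes[[1]]$pts
  expect_lt(max(abs(pts[, 1] - pts[1, 1])), 1e-9)
  expect_lt(max(abs(pts[, 3] - pts[1, 3])), 1e-9)

  # determinism
  expect_identical(simulate_root_system(s1)$axes,
                   simulate_root_system(s1)$axes)
  expect_error(synthetic_root_spec(base_radius = 0.1),
               class = "rhizo_parameter_error")
  expect_error(synthetic_root_spec(gravitropism = 2),
               class = "rhizo_parameter_error")
})

test_that("ground truth length equals the polyline sum", {
  for (s in 1:5) {
    sim <- simulate_root_system(synthetic_root_spec(seed = s))
    direct <- sum(vapply(sim$axes, function(a) {
      sum(sqrt(rowSums(diff(a$pts)^2)))
    }, numeric(1)))
    expect_equal(sim$ground_truth$total_length, direct, tolerance = 1e-9)
  }
})

test_that("rendered views obey orthographic turntable geometry", {
  sim <- simulate_root_system(synthetic_root_spec(seed = 9, noise_sd = 0,
                                                  blur_sd = 0))
  v <- render_views(sim, angles = c(0, 180))
  m0 <- v[["0"]]$mask$values
  m180 <- v[["180"]]$mask$values
  expect_identical(m0, m180[, ncol(m180):1])
  # noiseless, blurless bright roots: image equals mask
  expect_identical(v[["0"]]$image$values, m0 * 1)

  # straight vertical axis renders as a vertical bar: 1 run per row
  sv <- synthetic_root_spec(seed = 1, n_primary = 1, tortuosity_sd = 0,
                            gravitropism = 1, branch_rate = 0, stem_len = 0,
                            noise_sd = 0, blur_sd = 0)
  for (ang in c(0, 45, 240)) {
    mv <- render_views(simulate_root_system(sv), angles = ang)[[1]]$mask
    cc <- crossing_counts(mv, "horizontal", 5)
    expect_equal(cc$max, 1)
  }
  expect_error(render_views(sim, angles = 400), class = "rhizo_parameter_error")

  # mask is at least as large as a 1-px-wide stroke of the same length
  expect_gte(sum(v[["0"]]$mask$values), sim$ground_truth$total_length)
})

test_that("dark polarity and noise stay in range", {
  sim <- simulate_root_system(synthetic_root_spec(seed = 4,
                                                  polarity = "dark_roots",
                                                  noise_sd = 0.05))
  v <- render_views(sim, angles = 30)[[1]]
  expect_gte(min(v$image$values), 0)
  expect_lte(max(v$image$values), 1)
  # roots darker than background
  expect_lt(mean(v$image$values[v$mask$values == 1]),
            mean(v$image$values[v$mask$values == 0]))
})

test_that("the on-disk library is reproducible and carries ground truth", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  man1 <- make_library(5, d1, seed = 11)
  man2 <- make_library(5, d2, seed = 11)
  expect_equal(nrow(man1), 5L)
  for (f in c("img_0001.png", "mask_0003.png", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # manifest ground truth for a branchless spec
  d3 <- withr::local_tempdir()
  man3 <- make_library(2, d3, seed = 3,
                       spec_ranges = list(branch_rate = c(0, 0),
                                          n_primary = c(1, 1)))
  expect_true(all(man3$tip_count == 1L))
  expect_error(make_library(2, d3, spec_ranges = list(branch_rate = c(2, 1))),
               class = "rhizo_parameter_error")
})

test_that("branching intensity responds to the branch rate", {
  tips_at <- function(rate, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_root_system(synthetic_root_spec(
        seed = s, branch_rate = rate, n_primary = 2))
      sim$ground_truth$tip_count
    }, numeric(1))
  }
  lo <- tips_at(0.5, 1:50)
  hi <- tips_at(2.0, 51:100)
  expect_gt(mean(hi), mean(lo))
  p <- wilcox.test(hi, lo, alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("multiangle accession batches parse with the standard pattern", {
  d <- withr::local_tempdir()
  man <- simulate_accession_batch(2, d, replicates = 1, step_deg = 120,
                                  seed = 5)
  files <- list.files(d, pattern = "^SYN.*png$")
  expect_equal(length(files), 2 * 3)
  k <- parse_view_metadata(files[1], step_deg = 120)
  expect_match(k$accession, "^SYN")
})
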