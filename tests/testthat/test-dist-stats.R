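test_that("first-fixation extraction honours the containment rule", {
  s <- extract_first_fixations(tiny_dataset())
  ## trial 1: lead fixation straddles onset, second (300 ms) is selected;
  ## trial 2: single contained 200 ms fixation;
  ## trial 3: every fixation straddles the offset, contributes nothing
  expect_identical(s$n, 2L)
  expect_setequal(s$values, c(300, 200))
})

test_that("outlier filtering is a strict-threshold rule and idempotent", {
  s <- latency_sample(c(100, 1600, 300))
  f <- filter_outliers(s, quiet = TRUE)
  expect_identical(f$values, c(100, 300))
  expect_identical(attr(f, "n_removed"), 1L)
  ## exactly 1500 is retained ("longer than" rule)
  b <- filter_outliers(latency_sample(c(1500, 1501)), quiet = TRUE)
  expect_identical(b$values, 1500)
  expect_identical(filter_outliers(f, quiet = TRUE)$values, f$values)
  expect_warning(filter_outliers(latency_sample(c(2000, 3000)), quiet = TRUE),
                 "all latencies")
})

test_that("KS statistic matches hand-derivable cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6))$D, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "nonempty")
})

test_that("KS agrees with brute-force ECDF enumeration and is symmetric", {
  set.seed(14)
  for (k in 1:40) {
    a <- sample(1:30, sample(2:20, 1), replace = TRUE)
    b <- sample(1:30, sample(2:20, 1), replace = TRUE) + runif(1, -2, 2)
    D <- ks_two_sample(a, b)$D
    expect_equal(D, ks_brute(a, b), tolerance = 1e-12)
    expect_equal(D, ks_two_sample(b, a)$D)
    ## invariant under a common strictly monotone transform
    expect_equal(ks_two_sample(log(a + 3), log(b + 3))$D, D,
                 tolerance = 1e-12)
  }
})

test_that("z test matches its closed formula", {
  expect_equal(z_test(c(5, 10, 15), 10, 4)$z, 0)
  expect_equal(z_test(c(5, 10, 15), 10, 4)$p, 1)
  ## mean 200 vs mu0 190, sigma0 77.7, n 782
  v <- rep(200, 782)
  expect_equal(z_test(v, 190, 77.7)$z, 10 / (77.7 / sqrt(782)),
               tolerance = 1e-12)
  expect_equal(round(z_test(v, 190, 77.7)$z, 3), 3.599)
  ## doubling the mean offset doubles z
  expect_equal(z_test(rep(220, 50), 200, 10)$z,
               2 * z_test(rep(210, 50), 200, 10)$z)
  expect_error(z_test(v, 190, 0), "sigma0")
})

test_that("distribution comparison bundles KS and z coherently", {
  x <- c(120, 150, 180, 210, 260, 310)
  same <- compare_distributions(latency_sample(x, "model"),
                                latency_sample(x, "human"))
  expect_equal(same$D, 0)
  expect_equal(same$z, 0)
  shifted <- compare_distributions(latency_sample(x + 50, "model"),
                                   latency_sample(x, "human"))
  expect_gt(shifted$D, 0)
  expect_gt(shifted$z, 0)
  ## spreadsheet-style oracle on two fixed small samples
  a <- c(100, 140, 180, 220)
  b <- c(120, 160, 200)
  cmp <- compare_distributions(latency_sample(a, "model"),
                               latency_sample(b, "human"))
  expect_equal(cmp$D, ks_brute(a, b))
  expect_equal(cmp$z, (mean(a) - mean(b)) / (sd(b) / sqrt(4)),
               tolerance = 1e-12)
  expect_equal(cmp$mean_model, 160)
  expect_equal(cmp$sd_truth, 40)
})

test_that("censored runs are excluded before comparison", {
  sim <- data.frame(image_id = 1:4, run_id = 1L,
                    latency_ms = c(100, 200, NA, 300),
                    censored = c(FALSE, FALSE, TRUE, FALSE))
  s <- sim_to_sample(sim, quiet = TRUE)
  expect_identical(s$n, 3L)
  expect_identical(attr(s, "n_censored"), 1L)
  all_cens <- data.frame(image_id = 1, run_id = 1, latency_ms = NA_real_,
                         censored = TRUE)
  expect_error(sim_to_sample(all_cens), "censored")
})

test_that("variance decomposition separates image-driven variability", {
  ## deterministic model: repeated zero-noise runs per image
  maps <- synthetic_map_set(4, 8, 8, seed = 6)
  p <- sal_params(defaults$lif, defaults$wta, zero_noise)
  sim <- batch_simulate(maps, p, runs_per_image = 4, seed = 2)
  v <- variance_decomposition(sim)
  expect_equal(v$within_image_sd, 0)
  expect_gt(v$between_image_sd, 0)
  ## human-like data varies within image
  d <- generate_first_fixations(latency_config("dataset1"), seed = 9)
  ff <- saclif:::first_fix_df(d)
  ff <- ff[ff$latency_ms <= 1500, ]
  vh <- variance_decomposition(ff)
  expect_gt(vh$within_image_sd, 20)
  ## all-equal latencies: both components zero
  eq <- data.frame(image_id = rep(1:3, each = 2), latency_ms = 180,
                   censored = FALSE)
  ve <- variance_decomposition(eq)
  expect_equal(ve$within_image_sd, 0)
  expect_equal(ve$between_image_sd, 0)
})
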