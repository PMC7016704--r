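test_that("dataset1 generator reproduces the printed first-fixation anatomy", {
  cf <- latency_config("dataset1")
  d <- generate_first_fixations(cf, seed = 101)
  s <- extract_first_fixations(d)
  f <- filter_outliers(s, quiet = TRUE)
  ## exactly 782 retained first fixations over 44 images at 16-19 per image
  expect_identical(f$n, 782L)
  counts <- lengths(latencies_by_image(d))
  expect_length(counts, 44)
  expect_true(all(counts >= 16 & counts <= 19))
  ## positively skewed overall and per image (Fig. 8-style property)
  expect_gt(sample_skewness(f$values), 0)
  sk <- vapply(latencies_by_image(d), sample_skewness, numeric(1))
  expect_gte(mean(sk > 0), 0.9)
})

test_that("generation is reproducible bit-for-bit under a fixed seed", {
  cf <- latency_config("dataset1")
  expect_identical(generate_first_fixations(cf, seed = 7),
                   generate_first_fixations(cf, seed = 7))
  expect_identical(generate_all_fixations(latency_config("dataset2"), seed = 8),
                   generate_all_fixations(latency_config("dataset2"), seed = 8))
  expect_false(identical(generate_first_fixations(cf, seed = 7),
                         generate_first_fixations(cf, seed = 9)))
})

test_that("pre-exclusion outlier mass matches the configured tail weight", {
  s1 <- extract_first_fixations(
    generate_first_fixations(latency_config("dataset1"), seed = 5))
  expect_lt(abs(100 * mean(s1$values > 1500) - 1), 0.5)
  s2 <- extract_first_fixations(
    generate_first_fixations(latency_config("dataset2"), seed = 5))
  expect_identical(filter_outliers(s2, quiet = TRUE)$n, 1593L)
  expect_lt(abs(100 * mean(s2$values > 1500) - 3), 0.5)
})

test_that("all-fixation generator packs valid trials at the printed totals", {
  d <- generate_all_fixations(latency_config("dataset2"), seed = 31)
  by_img <- latencies_by_image(d, first_only = FALSE)
  expect_identical(sum(lengths(by_img)), 60186L)
  expect_true(all(lengths(by_img) >= 542 & lengths(by_img) <= 794))
  expect_true(all(d$records$duration_ms > 0))
  expect_equal(d$records$duration_ms,
               d$records$offset_ms - d$records$onset_ms)
  ## fixation sequences are ordered and inside the presentation window
  key <- interaction(d$records$participant_id, d$records$image_id)
  ord_ok <- tapply(seq_len(nrow(d$records)), key, function(i) {
    r <- d$records[i, ][order(d$records$fixation_index[i]), ]
    all(diff(r$onset_ms) > 0) && all(r$offset_ms > r$onset_ms)
  })
  expect_true(all(ord_ok))
  expect_true(all(d$records$onset_ms >= 1000 & d$records$offset_ms <= 9000))
})

test_that("infeasible count constraints are rejected", {
  expect_error(latency_config("dataset1", total_first_fixations = 100),
               "infeasible")
  expect_error(latency_config("dataset1", n_images = 10), "infeasible")
  expect_error(latency_config("dataset1", outlier_range = c(1000, 2000)),
               "1500")
})

test_that("synthetic saliency maps honour the peak specification", {
  m <- synthetic_saliency_map(20, 30, list(list(loc = c(10, 20), height = 1)))
  expect_equal(unname(saliency_argmax(m)), c(10, 20))
  expect_true(all(m$values >= 0))
  ## default scale: features of order 1e-9
  expect_gt(max(m$values), 1e-10)
  expect_lt(max(m$values), 1e-8)
  ## the highest requested peak wins
  m2 <- synthetic_saliency_map(20, 30, list(list(loc = c(3, 4), height = 0.5),
                                            list(loc = c(15, 25), height = 0.9)))
  expect_equal(unname(saliency_argmax(m2)), c(15, 25))
  expect_equal(max(m2$values), 0.9e-9)
  ## empty peak list and out-of-grid peaks
  expect_true(all(synthetic_saliency_map(5, 5, list())$values == 0))
  expect_error(synthetic_saliency_map(5, 5, list(list(loc = c(9, 2),
                                                      height = 1))),
               "outside")
})

test_that("pop-out displays render deterministically", {
  a <- synthetic_popout_image(64, 64, feature = "color", seed = 3)
  b <- synthetic_popout_image(64, 64, feature = "color", seed = 3)
  expect_identical(a, b)
  expect_true(all(a$image >= 0 & a$image <= 1))
  bg <- synthetic_popout_image(64, 64, n_items = 0, seed = 1)$image
  expect_identical(length(unique(as.vector(bg))), 1L)
})

test_that("fixation datasets round-trip through CSV", {
  d <- generate_first_fixations(latency_config("dataset1", n_images = 4L,
                                               total_first_fixations = 70L),
                                seed = 2)
  f <- tempfile(fileext = ".csv")
  write_fixations(d, f)
  d2 <- read_fixations(f)
  expect_equal(d2$records$duration_ms, d$records$duration_ms)
  expect_equal(extract_first_fixations(d2)$values,
               extract_first_fixations(d)$values)
})
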