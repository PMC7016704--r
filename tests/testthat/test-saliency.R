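gray_image <- function(h = 64, w = 64, level = 0.5) array(level, c(h, w, 3))

test_that("a uniform image has zero saliency everywhere", {
  m <- compute_saliency(gray_image())
  expect_true(all(m$values == 0))
  expect_equal(m$map_scale, 16)
})

test_that("the map is rescaled so its maximum equals map_range", {
  img <- synthetic_popout_image(96, 96, feature = "intensity", seed = 2)
  m <- compute_saliency(img$image, map_range = 1e-9)
  expect_equal(max(m$values), 1e-9)
  expect_true(all(m$values >= 0))
  m2 <- compute_saliency(img$image, map_range = 3.5)
  expect_equal(max(m2$values), 3.5)
})

test_that("saliency is invariant to a constant added to all channels", {
  img <- synthetic_popout_image(64, 64, feature = "orientation", seed = 5)$image
  m1 <- compute_saliency(img)
  m2 <- compute_saliency(pmin(img + 0.08, 1))
  expect_equal(m1$values, m2$values, tolerance = 1e-6)
})

test_that("the pop-out item attracts the saliency maximum on each channel", {
  for (feat in c("color", "intensity", "orientation")) {
    ## oriented bars need a sparser display: adjacent bars form joint
    ## texture edges that compete at the centre-surround scales
    n_items <- if (feat == "orientation") 9 else 16
    pop <- synthetic_popout_image(128, 128, n_items = n_items,
                                  feature = feat, seed = 11)
    m <- compute_saliency(pop$image)
    am <- saliency_argmax(m, image_coords = TRUE)
    d <- sqrt(sum((am - pop$popout_center)^2))
    ## within the item's extent, allowing one map-scale cell of slack
    expect_lt(d, pop$popout_radius + m$map_scale)
  }
})

test_that("centre-surround differences vanish without contrast", {
  pyr <- gaussian_pyramid(matrix(0.7, 64, 64))
  maps <- center_surround(pyr)
  expect_length(maps, 6)
  for (m in maps) expect_equal(max(abs(m)), 0, tolerance = 1e-12)
  expect_error(center_surround(pyr[1:4]), "out of range")
})

test_that("a bright bar drives centre-surround maxima at its location", {
  img <- matrix(0, 64, 64)
  img[, 29:36] <- 1   # vertical bar straddling map columns 2-3
  maps <- center_surround(gaussian_pyramid(img))
  agg <- Reduce(`+`, lapply(maps, function(m) {
    attributes(m) <- list(dim = dim(m))
    m
  }))
  peak_cols <- which(agg == max(agg), arr.ind = TRUE)[, 2]
  expect_true(all(peak_cols %in% 2:3))
})

test_that("normalisation promotes maps with a single dominant peak", {
  single <- synthetic_saliency_map(20, 20, list(list(loc = c(10, 10),
                                                     height = 1)),
                                   value_range = 1)$values
  multi <- synthetic_saliency_map(20, 20,
    list(list(loc = c(5, 5), height = 1), list(loc = c(15, 15), height = 1),
         list(loc = c(5, 15), height = 1), list(loc = c(15, 5), height = 1)),
    value_range = 1)$values
  expect_gt(max(normalize_map(single)), max(normalize_map(multi)))
  expect_true(all(normalize_map(matrix(0, 8, 8)) == 0))
  m <- matrix(runif(100), 10, 10)
  expect_identical(normalize_map(m), normalize_map(m))
})

test_that("arbitrary valid images yield finite nonnegative maps", {
  for (s in 1:3) {
    img <- saclif:::with_seed(s, array(runif(48 * 40 * 3), c(48, 40, 3)))
    m <- compute_saliency(img)
    expect_true(all(is.finite(m$values)))
    expect_true(all(m$values >= 0))
  }
  expect_error(compute_saliency(array(0.5, c(16, 16, 3))), "too small")
  expect_error(compute_saliency(array(c(NA, 0.5), c(32, 32, 3))),
               "non-finite")
})

test_that("images round-trip through PNG within 8-bit precision", {
  img <- synthetic_popout_image(48, 48, n_items = 4, seed = 13)$image
  f <- tempfile(fileext = ".png")
  write_image_png(img, f)
  img2 <- read_image_png(f)
  expect_equal(dim(img2), dim(img))
  expect_lt(max(abs(img2 - img)), 1 / 255)
})

test_that("saliency maps round-trip through CSV with metadata", {
  m <- compute_saliency(synthetic_popout_image(64, 64, seed = 9)$image)
  f <- tempfile(fileext = ".csv")
  write_saliency_map(m, f)
  m2 <- read_saliency_map(f)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(m2$map_scale, m$map_scale)
  expect_equal(m2$value_range, m$value_range)
})
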