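#' Saliency map container
#'
#' A nonnegative 2D conspicuity field at a reduced resolution. `map_scale`
#' records the downsampling factor relative to the source image (1 for
#' synthetic maps built directly on the map grid); `value_range` is the
#' nominal maximum after rescaling.
#'
#' @param values numeric matrix, nonnegative.
#' @param map_scale integer downsampling factor.
#' @param value_range nominal maximum of the map.
#' @return A `saliency_map` object.
#' @export
new_saliency_map <- function(values, map_scale = 1, value_range = max(values)) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  attributes(values) <- list(dim = dim(values))
  structure(list(values = values, map_scale = as.integer(map_scale),
                 value_range = value_range), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("Saliency map %d x %d (map scale 1/%d, max %.3g)\n",
              nrow(x$values), ncol(x$values), x$map_scale, max(x$values)))
  invisible(x)
}

## 5-tap binomial low-pass used between pyramid levels.
.pyr_kernel <- local({
  k <- c(1, 4, 6, 4, 1) / 16
  outer(k, k)
})

#' Dyadic Gaussian pyramid
#'
#' Repeated binomial smoothing and factor-2 decimation. Levels whose
#' dimensions would fall below one pixel are kept at 1; a 1 x 1 level acts
#' as the global mean for the coarsest surround scales.
#'
#' @param mat numeric matrix (level 0).
#' @param levels total number of levels including the input.
#' @return List of matrices, level 0 first.
#' @export
gaussian_pyramid <- function(mat, levels = 9) {
  stopifnot(is.matrix(mat), levels >= 1)
  pyr <- vector("list", levels)
  pyr[[1]] <- mat
  for (l in seq_len(levels - 1)) {
    prev <- pyr[[l]]
    if (nrow(prev) >= 5 && ncol(prev) >= 5) {
      sm <- EBImage::filter2(prev, .pyr_kernel, boundary = "replicate")
      pyr[[l + 1]] <- sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2),
                         drop = FALSE]
    } else if (nrow(prev) >= 2 || ncol(prev) >= 2) {
      ## level smaller than the smoothing kernel: plain bilinear decimation
      pyr[[l + 1]] <- .resize_to(prev, max(1, floor(nrow(prev) / 2)),
                                 max(1, floor(ncol(prev) / 2)))
    } else {
      pyr[[l + 1]] <- prev
    }
  }
  pyr
}

.resize_to <- function(mat, nr, nc) {
  if (nrow(mat) == nr && ncol(mat) == nc) return(mat)
  if (nrow(mat) == 1 && ncol(mat) == 1) return(matrix(mat[1, 1], nr, nc))
  EBImage::resize(mat, w = nr, h = nc)
}

#' Centre-surround feature maps across pyramid scales
#'
#' For every centre scale `c` and surround scale `c + delta`, both levels
#' are resampled to the map scale and the rectified absolute difference is
#' taken -- the pyramidal implementation of centre-surround receptive
#' fields.
#'
#' @param pyramid list of matrices from [gaussian_pyramid()] (level 0
#'   first).
#' @param center_scales centre pyramid levels (0-based).
#' @param surround_deltas offsets added to each centre scale.
#' @param map_level pyramid level (0-based) defining the common map
#'   resolution.
#' @return List of nonnegative matrices, one per (centre, surround) pair,
#'   each carrying attributes `center` and `surround`.
#' @export
center_surround <- function(pyramid, center_scales = c(2, 3, 4),
                            surround_deltas = c(3, 4), map_level = 4) {
  n <- length(pyramid)
  smax <- max(center_scales) + max(surround_deltas)
  if (smax > n - 1 || map_level > n - 1 || min(center_scales) < 0) {
    stop("pyramid scale index out of range")
  }
  nr <- nrow(pyramid[[map_level + 1]])
  nc <- ncol(pyramid[[map_level + 1]])
  maps <- list()
  for (cs in center_scales) {
    cmap <- .resize_to(pyramid[[cs + 1]], nr, nc)
    for (d in surround_deltas) {
      smap <- .resize_to(pyramid[[cs + d + 1]], nr, nc)
      m <- abs(cmap - smap)
      attr(m, "center") <- cs
      attr(m, "surround") <- cs + d
      maps[[length(maps) + 1]] <- m
    }
  }
  maps
}

#' Map normalisation promoting unique peaks
#'
#' Rescales a nonnegative map to `[0, 1]` and multiplies it by
#' \eqn{(M - \bar m)^2}, where \eqn{M} is the global maximum (1 after
#' rescaling) and \eqn{\bar m} the mean of the remaining local maxima. A map
#' with one dominant peak keeps its weight; a map with many comparable peaks
#' is suppressed. This is the max-based variant of the operator; the
#' iterative difference-of-Gaussians alternative is out of scope.
#'
#' @param map nonnegative numeric matrix.
#' @param thresh local maxima below `thresh` (after rescaling) are ignored.
#' @return Weighted map on the same grid.
#' @export
normalize_map <- function(map, thresh = 0.1) {
  stopifnot(is.matrix(map), all(is.finite(map)), all(map >= 0))
  M <- max(map)
  if (M == 0) return(map)
  m <- map / M
  lm <- local_maxima_values(m, thresh)
  ## drop one instance of the global maximum, average the rest
  if (length(lm)) lm <- lm[-which.max(lm)]
  mbar <- if (length(lm)) mean(lm) else 0
  m * (1 - mbar)^2
}

## Values at strict-in-neighbourhood local maxima (8-connected), above
## `thresh`; plateaus count via >= comparison against neighbours with at
## least one strict drop handled implicitly by the global-max removal.
local_maxima_values <- function(m, thresh = 0.1) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(max(m))
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nb <- pmax(pad[1:nr, 2:(nc + 1)], pad[3:(nr + 2), 2:(nc + 1)],
             pad[2:(nr + 1), 1:nc], pad[2:(nr + 1), 3:(nc + 2)],
             pad[1:nr, 1:nc], pad[1:nr, 3:(nc + 2)],
             pad[3:(nr + 2), 1:nc], pad[3:(nr + 2), 3:(nc + 2)])
  keep <- m >= nb & m >= thresh
  m[keep]
}

## Quadrature Gabor pair at a given orientation; zero-mean even component so
## constant regions produce no response.
gabor_kernels <- function(angle, size = 9, lambda = 7, sigma = 2.8,
                          gamma = 1) {
  half <- (size - 1) / 2
  x <- matrix(rep(-half:half, size), size, size)
  y <- t(x)
  xr <- x * cos(angle) + y * sin(angle)
  yr <- -x * sin(angle) + y * cos(angle)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / lambda)
  odd <- env * sin(2 * pi * xr / lambda)
  even <- even - mean(even)
  list(even = even, odd = odd)
}

gabor_energy <- function(mat, kernels) {
  ## levels smaller than the kernel carry no resolvable orientation
  if (nrow(mat) < nrow(kernels$even) || ncol(mat) < ncol(kernels$even)) {
    return(matrix(0, nrow(mat), ncol(mat)))
  }
  e <- EBImage::filter2(mat, kernels$even, boundary = "replicate")
  o <- EBImage::filter2(mat, kernels$odd, boundary = "replicate")
  sqrt(e^2 + o^2)
}

#' Compute a bottom-up saliency map from an RGB image
#'
#' The classic recipe: a 9-level dyadic Gaussian pyramid per channel;
#' intensity as the channel mean; red-green and blue-yellow opponency from
#' broadly tuned colour channels; orientation energy from a quadrature Gabor
#' pair at 0, 45, 90 and 135 degrees; centre-surround differences at centre
#' scales \{2, 3, 4\} with surround offsets \{3, 4\}, resampled to 1/16 of
#' the image resolution; per-channel conspicuity maps built from
#' [normalize_map()]-weighted feature maps and averaged with equal weights.
#' The result is rescaled linearly so its maximum equals `map_range`; the
#' stage is fully deterministic (noise enters later, at simulation time).
#'
#' All features are contrast-based, so adding a constant to every channel
#' leaves the map unchanged up to numerical tolerance.
#'
#' @param image H x W x 3 array with values in `[0, 1]`, H and W at least
#'   32 (pyramid depth requirement).
#' @param map_range maximum of the returned map (map units).
#' @param center_scales,surround_deltas pyramid scales of the
#'   centre-surround stage.
#' @param map_level pyramid level of the output grid (4 = 1/16 resolution).
#' @param orientations Gabor orientations in radians.
#' @return A `saliency_map` with `map_scale = 2^map_level`.
#' @export
compute_saliency <- function(image, map_range = 1e-9,
                             center_scales = c(2, 3, 4),
                             surround_deltas = c(3, 4), map_level = 4,
                             orientations = pi * (0:3) / 4) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be an H x W x 3 array")
  if (d[1] < 32 || d[2] < 32) stop("image too small for the pyramid (min 32)")
  if (!all(is.finite(image))) stop("image contains non-finite values")

  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  intens <- (r + g + b) / 3
  ## broadly tuned colour channels; invariant to a common additive shift.
  ## The two poles of each opponency axis are kept as separate rectified
  ## channels, so a lone red item among green distractors yields a
  ## single-peak feature map (which the normalisation then promotes)
  ## rather than being folded onto the distractors' pole.
  R <- r - (g + b) / 2
  G <- g - (r + b) / 2
  B <- b - (r + g) / 2
  Y <- (r + g) / 2 - abs(r - g) / 2 - b
  rg <- pmax(R - G, 0)
  gr <- pmax(G - R, 0)
  by <- pmax(B - Y, 0)
  yb <- pmax(Y - B, 0)

  levels <- 9
  cs <- function(mat) {
    center_surround(gaussian_pyramid(mat, levels), center_scales,
                    surround_deltas, map_level)
  }
  conspicuity <- function(maps) {
    Reduce(`+`, lapply(maps, normalize_map))
  }

  ci <- conspicuity(cs(intens))
  cc <- conspicuity(c(cs(rg), cs(gr), cs(by), cs(yb)))
  gk <- lapply(orientations, gabor_kernels)
  ipyr <- gaussian_pyramid(intens, levels)
  omaps <- list()
  for (k in gk) {
    opyr <- lapply(ipyr, gabor_energy, kernels = k)
    omaps <- c(omaps, center_surround(opyr, center_scales, surround_deltas,
                                      map_level))
  }
  co <- conspicuity(omaps)

  S <- (normalize_map(ci) + normalize_map(cc) + normalize_map(co)) / 3
  S[S < 0] <- 0
  if (max(S) > 0) S <- S / max(S) * map_range
  new_saliency_map(S, map_scale = 2^map_level, value_range = map_range)
}

#' Location of the map maximum
#'
#' @param map a `saliency_map`.
#' @param image_coords if `TRUE`, scale the (row, col) index back to source
#'   image pixels using `map_scale`.
#' @return Numeric `(row, col)`.
#' @export
saliency_argmax <- function(map, image_coords = FALSE) {
  idx <- which.max(map$values)
  rc <- c(row = (idx - 1) %% nrow(map$values) + 1,
          col = (idx - 1) %/% nrow(map$values) + 1)
  if (image_coords) rc <- (rc - 0.5) * map$map_scale
  rc
}

#' Write / read a saliency map as a CSV matrix
#'
#' Two comment lines (`# map_scale:`, `# value_range:`) precede the matrix
#' so a map round-trips with its metadata.
#'
#' @param map a `saliency_map`.
#' @param file CSV path.
#' @return `file` invisibly (`write_saliency_map`); a `saliency_map`
#'   (`read_saliency_map`).
#' @export
write_saliency_map <- function(map, file) {
  stopifnot(inherits(map, "saliency_map"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# map_scale: %d", map$map_scale),
               sprintf("# value_range: %.17g", map$value_range)), con)
  utils::write.table(map$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' Read / write RGB images as PNG
#'
#' Thin wrappers (requiring the `png` package) between PNG files and the
#' H x W x 3 arrays in `[0, 1]` the saliency front-end consumes. Grayscale
#' images are replicated across channels; an alpha channel is dropped.
#'
#' @param file PNG path.
#' @param image H x W x 3 array in `[0, 1]` (or a list with an `image`
#'   element, as returned by [synthetic_popout_image()]).
#' @return `read_image_png`: an H x W x 3 array; `write_image_png`: `file`,
#'   invisibly.
#' @export
read_image_png <- function(file) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG image IO")
  }
  x <- png::readPNG(file)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, file) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG image IO")
  }
  if (is.list(image) && !is.null(image$image)) image <- image$image
  png::writePNG(image, file)
  invisible(file)
}

#' @rdname write_saliency_map
#' @export
read_saliency_map <- function(file) {
  hdr <- readLines(file, n = 2)
  ms <- as.integer(sub("# map_scale: *", "", hdr[1]))
  vr <- as.numeric(sub("# value_range: *", "", hdr[2]))
  vals <- as.matrix(utils::read.table(file, sep = ",", skip = 2))
  dimnames(vals) <- NULL
  new_saliency_map(vals, map_scale = ms, value_range = vr)
}
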