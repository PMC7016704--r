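#' Ex-Gaussian random deviates
#'
#' The ex-Gaussian (a normal convolved with an exponential) is the standard
#' parametric family for positively skewed reaction-time data; its mean is
#' `mu + tau` and its variance `sigma^2 + tau^2`.
#'
#' @param n number of deviates.
#' @param mu,sigma mean and SD of the normal component (ms).
#' @param tau mean of the exponential component (ms).
#' @return Numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(mu > 0, sigma > 0, tau > 0)
  stats::rnorm(n, mean = mu, sd = sigma) + stats::rexp(n, rate = 1 / tau)
}

## Ex-Gaussian draws restricted to (lo, hi]; simple rejection, the tail mass
## outside the band is negligible at the calibrated defaults.
rexgauss_trunc <- function(n, mu, sigma, tau, lo = 1, hi = 1500) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rexgauss(n - length(out) + 8L, mu, sigma, tau)
    out <- c(out, x[x > lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Configuration of the human-like latency generator
#'
#' Describes a fixation dataset with the anatomy of a pooled visual-search
#' eye-tracking corpus: per-image first-fixation samples with a positively
#' skewed (ex-Gaussian) latency distribution, mild between-image variation,
#' and a small long-tail outlier component beyond the 1500 ms exclusion
#' threshold.
#'
#' The two presets mirror the published dataset anatomy: `dataset1` has 44
#' images and 782 first fixations (post-exclusion) with a 1\% outlier tail;
#' `dataset2` has 91 images, 1593 first fixations and 60,186 fixations in
#' total with a 3\% tail on its first fixations. The default ex-Gaussian
#' parameters (`mu` = 118.8, `sigma` = 25.07, `tau` = 72 ms, between-image
#' shift SD 15 ms) are solved so that the post-exclusion mixture has mean
#' 190.8 ms and SD 77.7 ms:
#' `mu + tau = 190.8` and `sigma^2 + tau^2 + shift_sd^2 = 77.7^2`.
#'
#' @param dataset `"dataset1"` or `"dataset2"` preset.
#' @param mu,sigma,tau ex-Gaussian parameters of the first-fixation latency
#'   component (ms).
#' @param per_image_shift_sd SD of the per-image shift applied to `mu` (ms).
#' @param outlier_weight probability mass of the long-tail component among
#'   pre-exclusion first-fixation records.
#' @param outlier_range range (ms) of the uniform outlier component; the
#'   lower end must be at least 1500.
#' @param n_images number of distinct images.
#' @param first_fix_per_image inclusive range of retained first fixations per
#'   image.
#' @param all_fix_per_image inclusive range of retained fixations per image
#'   for the all-fixation dataset.
#' @param total_first_fixations retained (post-exclusion) first-fixation
#'   count.
#' @param total_all_fixations retained fixation count of the all-fixation
#'   dataset.
#' @param all_mu,all_sigma,all_tau ex-Gaussian parameters of non-initial
#'   fixation durations (ms); later fixations in search are shorter than the
#'   first, which also keeps ~40 fixations per 8-second trial feasible.
#' @param all_outlier_weight outlier mass among pre-exclusion records of the
#'   all-fixation dataset.
#' @param all_outlier_range outlier duration range (ms) for the all-fixation
#'   dataset; kept short so an outlier still fits inside a packed trial.
#' @param n_participants number of participants trials are attributed to.
#' @param window_ms image presentation duration (ms).
#' @param image_onset_ms image onset relative to trial start (ms); the first
#'   second of each trial is the fixation cross.
#' @param seed default RNG seed carried by the config (overridable in the
#'   generator calls).
#' @return An object of class `latency_config`.
#' @export
latency_config <- function(dataset = c("dataset1", "dataset2"),
                           mu = 118.8, sigma = 25.07, tau = 72,
                           per_image_shift_sd = 15,
                           outlier_weight = NULL,
                           outlier_range = c(1500, 7800),
                           n_images = NULL,
                           first_fix_per_image = c(16L, 19L),
                           all_fix_per_image = c(542L, 794L),
                           total_first_fixations = NULL,
                           total_all_fixations = NULL,
                           all_mu = 95, all_sigma = 30, all_tau = 50,
                           all_outlier_weight = 0.01,
                           all_outlier_range = c(1500, 3000),
                           n_participants = 18L,
                           window_ms = 8000, image_onset_ms = 1000,
                           seed = NULL) {
  dataset <- match.arg(dataset)
  if (dataset == "dataset1") {
    n_images <- n_images %||% 44L
    total_first_fixations <- total_first_fixations %||% 782L
    total_all_fixations <- total_all_fixations %||% 29528L
    outlier_weight <- outlier_weight %||% 0.01
  } else {
    n_images <- n_images %||% 91L
    total_first_fixations <- total_first_fixations %||% 1593L
    total_all_fixations <- total_all_fixations %||% 60186L
    outlier_weight <- outlier_weight %||% 0.03
  }
  stopifnot(mu > 0, sigma > 0, tau > 0, all_mu > 0, all_sigma > 0,
            all_tau > 0, per_image_shift_sd >= 0,
            outlier_weight >= 0, outlier_weight < 1,
            all_outlier_weight >= 0, all_outlier_weight < 1,
            n_images >= 1, n_participants >= 1, window_ms > 0)
  if (outlier_range[1] < 1500 || all_outlier_range[1] < 1500) {
    stop("outlier ranges must start at or above the 1500 ms threshold")
  }
  if (total_first_fixations < n_images * first_fix_per_image[1] ||
      total_first_fixations > n_images * first_fix_per_image[2]) {
    stop("total_first_fixations infeasible for n_images and first_fix_per_image")
  }
  structure(list(
    dataset = dataset, mu = mu, sigma = sigma, tau = tau,
    per_image_shift_sd = per_image_shift_sd,
    outlier_weight = outlier_weight, outlier_range = outlier_range,
    n_images = as.integer(n_images),
    first_fix_per_image = as.integer(first_fix_per_image),
    all_fix_per_image = as.integer(all_fix_per_image),
    total_first_fixations = as.integer(total_first_fixations),
    total_all_fixations = as.integer(total_all_fixations),
    all_mu = all_mu, all_sigma = all_sigma, all_tau = all_tau,
    all_outlier_weight = all_outlier_weight,
    all_outlier_range = all_outlier_range,
    n_participants = as.integer(n_participants),
    window_ms = window_ms, image_onset_ms = image_onset_ms,
    seed = seed), class = "latency_config")
}

new_fixation_dataset <- function(records, trials, config_label) {
  records <- records[order(records$participant_id, records$trial_index,
                           records$fixation_index), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, trials = trials,
                 config_label = config_label),
            class = "fixation_dataset")
}

#' @export
print.fixation_dataset <- function(x, ...) {
  cat(sprintf("Fixation dataset (%s): %d records, %d trials, %d images\n",
              x$config_label, nrow(x$records), nrow(x$trials),
              length(unique(x$trials$image_id))))
  invisible(x)
}

## Number of extra outlier records needed so that, with `retained` records
## kept after exclusion, the pre-exclusion tail fraction equals `w`.
n_outliers_for <- function(retained, w) {
  if (w <= 0) return(0L)
  as.integer(round(retained * w / (1 - w)))
}

#' Generate a human-like first-fixation dataset
#'
#' Produces a trial-structured dataset whose extracted first-fixation
#' latencies reproduce the anatomy in the corresponding preset: exactly the
#' configured number of retained (post-exclusion) first fixations spread over
#' the images at 16-19 per image, per-image ex-Gaussian latencies with a
#' shifted location per image, plus extra long (> 1500 ms) records carrying
#' the configured pre-exclusion outlier mass.
#'
#' Each trial contains a fixation that straddles the image onset (begun on
#' the pre-trial fixation cross, hence excluded by the first-fixation rule)
#' followed by the first fixation fully inside the presentation window whose
#' duration is the trial's latency.
#'
#' @param config a [latency_config()].
#' @param seed RNG seed; falls back to `config$seed`.
#' @return A `fixation_dataset` with elements `records` (one row per
#'   fixation), `trials` (presentation windows) and `config_label`.
#' @export
generate_first_fixations <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "latency_config"))
  with_seed(seed, {
    cf <- config
    counts <- split_total(cf$n_images, cf$first_fix_per_image,
                          cf$total_first_fixations)
    ## extra outlier records go to images with slack below the per-image cap
    n_out <- n_outliers_for(cf$total_first_fixations, cf$outlier_weight)
    out_per_image <- integer(cf$n_images)
    if (n_out > 0) {
      slack <- which(counts < cf$first_fix_per_image[2])
      pick <- sample(slack, n_out, replace = length(slack) < n_out)
      tab <- table(pick)
      out_per_image[as.integer(names(tab))] <- as.integer(tab)
    }
    shifts <- stats::rnorm(cf$n_images, 0, cf$per_image_shift_sd)

    rec <- vector("list", cf$n_images)
    tri <- vector("list", cf$n_images)
    trial_counter <- integer(cf$n_participants)
    for (i in seq_len(cf$n_images)) {
      n_i <- counts[i] + out_per_image[i]
      mu_i <- max(cf$mu + shifts[i], 10)
      lat <- rexgauss_trunc(counts[i], mu_i, cf$sigma, cf$tau)
      if (out_per_image[i] > 0) {
        lat <- c(lat, stats::runif(out_per_image[i], cf$outlier_range[1],
                                   cf$outlier_range[2]))
      }
      lat <- sample(lat)
      ## participants: distinct while possible, then recycled
      parts <- if (n_i <= cf$n_participants) {
        sample.int(cf$n_participants, n_i)
      } else {
        c(sample.int(cf$n_participants),
          sample.int(cf$n_participants, n_i - cf$n_participants))
      }
      ## a participant can appear twice for one image; each occurrence must
      ## get its own trial index
      occ <- stats::ave(parts, parts, FUN = seq_along)
      tidx <- trial_counter[parts] + occ
      for (p in unique(parts)) {
        trial_counter[p] <- trial_counter[p] + sum(parts == p)
      }
      lead_on <- stats::runif(n_i, 400, 900)
      lead_off <- cf$image_onset_ms + stats::runif(n_i, 20, 80)
      first_on <- lead_off + stats::runif(n_i, 20, 50)
      first_off <- first_on + lat
      rec[[i]] <- data.frame(
        participant_id = rep(parts, 2L),
        image_id = i,
        trial_index = rep(tidx, 2L),
        fixation_index = rep(c(1L, 2L), each = n_i),
        onset_ms = c(lead_on, first_on),
        offset_ms = c(lead_off, first_off),
        x = stats::runif(2L * n_i, 0, 1680),
        y = stats::runif(2L * n_i, 0, 1050))
      tri[[i]] <- data.frame(
        participant_id = parts, trial_index = tidx, image_id = i,
        image_onset = cf$image_onset_ms,
        image_offset = cf$image_onset_ms + cf$window_ms)
    }
    records <- do.call(rbind, rec)
    records$duration_ms <- records$offset_ms - records$onset_ms
    new_fixation_dataset(records, do.call(rbind, tri),
                         paste0(cf$dataset, "_first"))
  })
}

#' Generate a human-like all-fixation dataset
#'
#' Builds full trials: for each image the retained fixation count is drawn
#' within the configured per-image band (summing exactly to the configured
#' total), split over the participants' trials, and packed sequentially into
#' the presentation window with short saccade gaps. The first fixation of
#' each trial follows the first-fixation ex-Gaussian; subsequent fixations
#' follow the shorter non-initial distribution. A configurable fraction of
#' trials additionally carries one long outlier fixation (> 1500 ms)
#' inserted at a random position.
#'
#' @inheritParams generate_first_fixations
#' @return A `fixation_dataset`.
#' @export
generate_all_fixations <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "latency_config"))
  with_seed(seed, {
    cf <- config
    counts <- split_total(cf$n_images, cf$all_fix_per_image,
                          cf$total_all_fixations)
    shifts <- stats::rnorm(cf$n_images, 0, cf$per_image_shift_sd)
    n_trials <- cf$n_images * cf$n_participants
    n_out <- n_outliers_for(cf$total_all_fixations, cf$all_outlier_weight)
    outlier_trial <- logical(n_trials)
    outlier_trial[sample.int(n_trials, min(n_out, n_trials))] <- TRUE

    usable <- cf$window_ms - 60   # onset jitter + end slack, ms
    rec <- vector("list", n_trials)
    tri <- vector("list", n_trials)
    t_id <- 0L
    for (i in seq_len(cf$n_images)) {
      mu_i <- max(cf$mu + shifts[i], 10)
      amu_i <- max(cf$all_mu + shifts[i], 10)
      ## split the image's count over its trials, weighted by capacity left
      ## after any outlier
      flags <- outlier_trial[t_id + seq_len(cf$n_participants)]
      out_dur <- ifelse(flags,
                        stats::runif(cf$n_participants,
                                     cf$all_outlier_range[1],
                                     cf$all_outlier_range[2]), 0)
      cap <- pmax(usable - out_dur, 500)
      k <- floor(counts[i] * cap / sum(cap))
      rem <- counts[i] - sum(k)
      if (rem > 0) {
        bump <- order(cap, decreasing = TRUE)[seq_len(rem)]
        k[bump] <- k[bump] + 1L
      }
      for (p in seq_len(cf$n_participants)) {
        t_id <- t_id + 1L
        kk <- k[p]
        if (kk < 1L) kk <- 1L
        ## crowded trials scan faster: shrink the non-initial duration
        ## location so the expected load sits at ~93% of the window (the
        ## count-duration coupling a fixed presentation window imposes)
        amu_t <- amu_i
        if (kk > 1L) {
          budget <- 0.93 * (usable - out_dur[p]) - 25 * kk -
            (mu_i + cf$tau) - (kk - 1L) * cf$all_tau
          amu_t <- max(15, min(amu_i, budget / (kk - 1L)))
        }
        tries <- 0L
        repeat {
          tries <- tries + 1L
          dur <- c(rexgauss_trunc(1, mu_i, cf$sigma, cf$tau),
                   if (kk > 1) rexgauss_trunc(kk - 1L, amu_t, cf$all_sigma,
                                              cf$all_tau))
          if (flags[p]) {
            pos <- sample.int(kk, 1)
            dur <- append(dur, out_dur[p], after = pos)
          }
          gaps <- stats::runif(length(dur), 15, 35)
          if (sum(dur) + sum(gaps) <= usable) break
          if (tries >= 50L) {
            ## deterministic fallback: compress the non-outlier durations
            keep <- if (flags[p]) seq_along(dur) != pos + 1L
                    else rep(TRUE, length(dur))
            excess <- sum(dur) + sum(gaps) - 0.995 * usable
            dur[keep] <- pmax(dur[keep] * (1 - excess / sum(dur[keep])), 5)
            if (sum(dur) + sum(gaps) <= usable) break
          }
        }
        onset0 <- cf$image_onset_ms + stats::runif(1, 5, 25)
        onsets <- onset0 + cumsum(c(0, (dur + gaps)[-length(dur)]))
        offsets <- onsets + dur
        rec[[t_id]] <- data.frame(
          participant_id = p, image_id = i, trial_index = i,
          fixation_index = seq_along(dur),
          onset_ms = onsets, offset_ms = offsets,
          x = stats::runif(length(dur), 0, 1680),
          y = stats::runif(length(dur), 0, 1050))
        tri[[t_id]] <- data.frame(
          participant_id = p, trial_index = i, image_id = i,
          image_onset = cf$image_onset_ms,
          image_offset = cf$image_onset_ms + cf$window_ms)
      }
    }
    records <- do.call(rbind, rec)
    records$duration_ms <- records$offset_ms - records$onset_ms
    new_fixation_dataset(records, do.call(rbind, tri),
                         paste0(cf$dataset, "_all"))
  })
}

#' Construct a synthetic saliency map
#'
#' Builds a nonnegative map as the pointwise maximum of isotropic Gaussian
#' bumps, scaled so the global maximum equals
#' `value_range * max(relative peak height)`. With the default
#' `value_range = 1e-9` the map has features of the order the LIF layer
#' expects.
#'
#' @param height,width map dimensions (units of the map grid).
#' @param peaks list of `list(loc = c(row, col), height = h)` entries with
#'   relative heights in (0, 1]; an empty list yields an all-zero map.
#' @param value_range scale of the map's maximum.
#' @param sigma Gaussian bump width (grid units).
#' @param seed unused by the deterministic construction, accepted for
#'   interface symmetry with the other generators.
#' @return A `saliency_map` object (list with `values`, `map_scale`,
#'   `value_range`).
#' @export
synthetic_saliency_map <- function(height, width, peaks,
                                   value_range = 1e-9,
                                   sigma = max(2, min(height, width) / 8),
                                   seed = NULL) {
  stopifnot(height >= 1, width >= 1, value_range > 0)
  vals <- matrix(0, height, width)
  if (length(peaks)) {
    r <- row(vals); c_ <- col(vals)
    for (p in peaks) {
      loc <- p$loc %||% p[[1]]
      h <- p$height %||% p[[2]]
      if (loc[1] < 1 || loc[1] > height || loc[2] < 1 || loc[2] > width) {
        stop("peak location outside the map grid")
      }
      bump <- h * exp(-((r - loc[1])^2 + (c_ - loc[2])^2) / (2 * sigma^2))
      vals <- pmax(vals, bump)
    }
  }
  new_saliency_map(vals * value_range, map_scale = 1,
                   value_range = value_range)
}

#' Render a synthetic pop-out search display
#'
#' Draws an RGB image of distractor items with a single pop-out item
#' differing in colour, intensity or orientation -- a minimal stand-in for
#' natural search scenes, sufficient to exercise the saliency front-end.
#'
#' @param height,width image dimensions in pixels (at least 64 recommended).
#' @param n_items total number of items (placed on a square grid).
#' @param feature dimension on which the pop-out differs.
#' @param seed RNG seed controlling item jitter and pop-out position.
#' @return List with `image` (H x W x 3 array in `[0, 1]`), `popout_center`
#'   (row, col) and `popout_radius` (pixels).
#' @export
synthetic_popout_image <- function(height = 128, width = 128, n_items = 16,
                                   feature = c("color", "intensity",
                                               "orientation"),
                                   seed = NULL) {
  feature <- match.arg(feature)
  with_seed(seed, {
    bg <- 0.45
    img <- array(bg, dim = c(height, width, 3))
    if (n_items < 1) {
      return(list(image = img, popout_center = NULL, popout_radius = NULL))
    }
    side <- ceiling(sqrt(n_items))
    cell_h <- height / side; cell_w <- width / side
    centers <- expand.grid(gr = seq_len(side), gc = seq_len(side))
    centers <- centers[seq_len(n_items), , drop = FALSE]
    cy <- (centers$gr - 0.5) * cell_h + stats::runif(n_items, -cell_h / 8,
                                                     cell_h / 8)
    cx <- (centers$gc - 0.5) * cell_w + stats::runif(n_items, -cell_w / 8,
                                                     cell_w / 8)
    pop <- sample.int(n_items, 1)
    rad <- 0.28 * min(cell_h, cell_w)
    r <- row(img[, , 1]); c_ <- col(img[, , 1])
    paint_disc <- function(img, y0, x0, radius, col) {
      m <- (r - y0)^2 + (c_ - x0)^2 <= radius^2
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[m] <- col[ch]; img[, , ch] <- plane
      }
      img
    }
    paint_bar <- function(img, y0, x0, len, wid, angle, col) {
      dy <- r - y0; dx <- c_ - x0
      u <- dx * cos(angle) + dy * sin(angle)
      v <- -dx * sin(angle) + dy * cos(angle)
      m <- abs(u) <= len / 2 & abs(v) <= wid / 2
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[m] <- col[ch]; img[, , ch] <- plane
      }
      img
    }
    for (j in seq_len(n_items)) {
      is_pop <- j == pop
      if (feature == "color") {
        col <- if (is_pop) c(0.95, 0.1, 0.1) else c(0.1, 0.75, 0.1)
        img <- paint_disc(img, cy[j], cx[j], rad, col)
      } else if (feature == "intensity") {
        col <- rep(if (is_pop) 1.0 else 0.55, 3)
        img <- paint_disc(img, cy[j], cx[j], rad, col)
      } else {
        ang <- if (is_pop) pi / 2 else 0
        img <- paint_bar(img, cy[j], cx[j], 2.6 * rad, 0.8 * rad, ang,
                         rep(0.9, 3))
      }
    }
    list(image = img, popout_center = c(cy[pop], cx[pop]),
         popout_radius = rad)
  })
}

#' Write / read fixation datasets as CSV
#'
#' The records table uses the canonical header
#' `participant_id,image_id,trial_index,fixation_index,onset_ms,offset_ms,duration_ms,x,y`;
#' trial presentation windows go to a companion `<file>.trials.csv`.
#'
#' @param dataset a `fixation_dataset`.
#' @param file records CSV path.
#' @param trials_file companion CSV path for the trial windows.
#' @return `file` invisibly (`write_fixations`); a `fixation_dataset`
#'   (`read_fixations`).
#' @export
write_fixations <- function(dataset, file,
                            trials_file = paste0(file, ".trials.csv")) {
  stopifnot(inherits(dataset, "fixation_dataset"))
  cols <- c("participant_id", "image_id", "trial_index", "fixation_index",
            "onset_ms", "offset_ms", "duration_ms", "x", "y")
  utils::write.csv(dataset$records[, cols], file, row.names = FALSE)
  utils::write.csv(dataset$trials, trials_file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fixations
#' @param config_label label stored on the reconstructed dataset.
#' @export
read_fixations <- function(file, trials_file = paste0(file, ".trials.csv"),
                           config_label = "loaded") {
  records <- utils::read.csv(file)
  trials <- utils::read.csv(trials_file)
  new_fixation_dataset(records, trials, config_label)
}
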