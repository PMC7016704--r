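#' Latency samples
#'
#' A labelled collection of positive latencies (ms) used by the comparison
#' statistics and the fitness functions.
#'
#' @param values numeric vector of latencies (ms), all positive.
#' @param label source tag, conventionally `"human"` or `"model"`.
#' @return An object of class `latency_sample`.
#' @export
latency_sample <- function(values, label = "sample") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("latencies must be positive and finite")
  }
  structure(list(values = values, n = length(values), label = label),
            class = "latency_sample")
}

#' @export
print.latency_sample <- function(x, ...) {
  cat(sprintf("Latency sample '%s': n = %d, mean = %.1f ms, sd = %.1f ms\n",
              x$label, x$n, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Extract first-fixation latencies from a dataset
#'
#' For every trial, the first fixation whose onset and offset both fall
#' inside the image presentation window contributes its duration; a fixation
#' begun before image onset (e.g. on the fixation cross) is skipped, and a
#' trial with no fully contained fixation contributes nothing.
#'
#' @param dataset a `fixation_dataset`.
#' @param label label of the returned sample.
#' @return A [latency_sample()] with one latency per qualifying trial.
#' @export
extract_first_fixations <- function(dataset, label = "human") {
  latency_sample(first_fix_df(dataset)$latency_ms, label = label)
}

## One row per qualifying trial: image_id and the first in-window fixation's
## duration.
first_fix_df <- function(dataset) {
  stopifnot(inherits(dataset, "fixation_dataset"))
  rec <- merge(dataset$records, dataset$trials,
               by = c("participant_id", "trial_index", "image_id"))
  ok <- rec$onset_ms >= rec$image_onset & rec$offset_ms <= rec$image_offset
  rec <- rec[ok, , drop = FALSE]
  key <- interaction(rec$participant_id, rec$trial_index, drop = TRUE)
  first <- rec[order(key, rec$onset_ms), , drop = FALSE]
  first <- first[!duplicated(interaction(first$participant_id,
                                         first$trial_index, drop = TRUE)), ,
                 drop = FALSE]
  data.frame(participant_id = first$participant_id,
             trial_index = first$trial_index, image_id = first$image_id,
             latency_ms = first$duration_ms)
}

#' Per-image latency samples from a fixation dataset
#'
#' Groups in-window fixation durations by image, either the first fixation
#' of each trial or all fixations, with the outlier threshold applied.
#'
#' @param dataset a `fixation_dataset`.
#' @param first_only use only each trial's first in-window fixation.
#' @param threshold_ms outlier exclusion threshold (`Inf` to keep all).
#' @return Named list (by image id) of numeric latency vectors.
#' @export
latencies_by_image <- function(dataset, first_only = TRUE,
                               threshold_ms = 1500) {
  if (first_only) {
    d <- first_fix_df(dataset)
  } else {
    rec <- merge(dataset$records, dataset$trials,
                 by = c("participant_id", "trial_index", "image_id"))
    ok <- rec$onset_ms >= rec$image_onset & rec$offset_ms <= rec$image_offset
    d <- data.frame(image_id = rec$image_id[ok],
                    latency_ms = rec$duration_ms[ok])
  }
  d <- d[d$latency_ms <= threshold_ms, , drop = FALSE]
  split(d$latency_ms, d$image_id)
}

#' Exclude outlier latencies
#'
#' Latencies strictly longer than the threshold are removed (a value exactly
#' at the threshold is retained); the number removed is reported via a
#' message and stored in the `n_removed` attribute. Idempotent.
#'
#' @param sample a [latency_sample()].
#' @param threshold_ms exclusion threshold, default 1500 ms.
#' @param quiet suppress the log message.
#' @return The filtered `latency_sample`.
#' @export
filter_outliers <- function(sample, threshold_ms = 1500, quiet = FALSE) {
  stopifnot(inherits(sample, "latency_sample"), threshold_ms > 0)
  keep <- sample$values <= threshold_ms
  removed <- sum(!keep)
  if (!quiet && removed > 0) {
    message(sprintf("filter_outliers: removed %d of %d latencies > %g ms",
                    removed, sample$n, threshold_ms))
  }
  if (all(!keep)) warning("all latencies excluded as outliers")
  out <- latency_sample(sample$values[keep], label = sample$label)
  attr(out, "n_removed") <- removed
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum of the absolute difference of the two empirical
#' CDFs; the p-value comes from the asymptotic two-sample Kolmogorov
#' distribution with effective sample size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b [latency_sample()]s or bare numeric vectors.
#' @return List with elements `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  av <- if (inherits(a, "latency_sample")) a$values else as.numeric(a)
  bv <- if (inherits(b, "latency_sample")) b$values else as.numeric(b)
  if (!length(av) || !length(bv)) stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(av, bv, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' One-sample z test with known sigma
#'
#' \eqn{z = (\bar x - \mu_0) / (\sigma_0 / \sqrt n)} with a two-sided
#' p-value from the standard normal. Used with the ground-truth mean and SD
#' as the reference, this is the z statistic entering the fitness functions.
#'
#' @param sample a [latency_sample()] or numeric vector.
#' @param mu0 reference mean (ms).
#' @param sigma0 reference SD (ms), must be positive.
#' @return List with elements `z` and `p`.
#' @export
z_test <- function(sample, mu0, sigma0) {
  v <- if (inherits(sample, "latency_sample")) sample$values
       else as.numeric(sample)
  if (!length(v)) stop("sample must be nonempty")
  if (sigma0 <= 0) stop("sigma0 must be positive")
  z <- (mean(v) - mu0) / (sigma0 / sqrt(length(v)))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare a model latency distribution with ground truth
#'
#' Bundles the two-sample KS comparison with the z test of the model mean
#' against the ground-truth mean (ground-truth SD as the known sigma) and
#' the samples' summary statistics.
#'
#' @param model model [latency_sample()] (censored runs must already be
#'   excluded; see [sim_to_sample()]).
#' @param truth ground-truth [latency_sample()].
#' @return An object of class `latency_comparison`: `D`, `p_ks`, `z`,
#'   `p_z`, `mean_model`, `sd_model`, `mean_truth`, `sd_truth`, `n_model`,
#'   `n_truth`.
#' @export
compare_distributions <- function(model, truth) {
  stopifnot(inherits(model, "latency_sample"),
            inherits(truth, "latency_sample"))
  ks <- ks_two_sample(model, truth)
  zt <- z_test(model, mean(truth$values), stats::sd(truth$values))
  structure(list(D = ks$D, p_ks = ks$p, z = zt$z, p_z = zt$p,
                 mean_model = mean(model$values),
                 sd_model = stats::sd(model$values),
                 mean_truth = mean(truth$values),
                 sd_truth = stats::sd(truth$values),
                 n_model = model$n, n_truth = truth$n),
            class = "latency_comparison")
}

#' @export
print.latency_comparison <- function(x, ...) {
  cat(sprintf("Model vs ground truth (n = %d vs %d)\n", x$n_model, x$n_truth))
  cat(sprintf("  model: mean %.1f ms, sd %.1f ms | truth: mean %.1f ms, sd %.1f ms\n",
              x$mean_model, x$sd_model, x$mean_truth, x$sd_truth))
  cat(sprintf("  KS: D = %.5f, p = %.4g | z = %.5f, p = %.4g\n",
              x$D, x$p_ks, x$z, x$p_z))
  invisible(x)
}

#' Convert simulation output to a latency sample
#'
#' Censored runs are dropped with a logged count; an all-censored simulation
#' is an error (the parameter set does not fire).
#'
#' @param sim a `saccade_sim` data.frame from [batch_simulate()].
#' @param label sample label.
#' @param quiet suppress the censoring message.
#' @return A [latency_sample()].
#' @export
sim_to_sample <- function(sim, label = "model", quiet = FALSE) {
  n_cens <- sum(sim$censored)
  if (n_cens == nrow(sim)) {
    stop("all simulation runs censored: parameter set does not fire")
  }
  if (!quiet && n_cens > 0) {
    message(sprintf("sim_to_sample: dropped %d censored of %d runs",
                    n_cens, nrow(sim)))
  }
  out <- latency_sample(sim$latency_ms[!sim$censored], label = label)
  attr(out, "n_censored") <- n_cens
  out
}

#' Within- and between-image variance decomposition
#'
#' Splits latency variability into the pooled within-image SD and the SD of
#' per-image mean latencies. For the deterministic model the within-image
#' component is exactly zero; for human-like data it is tens of
#' milliseconds -- the headline contrast of the analysis.
#'
#' @param saccades a `saccade_sim` data.frame or any data.frame with
#'   `image_id` and `latency_ms` columns (e.g. human latencies tagged by
#'   image).
#' @return List with `within_image_sd`, `between_image_sd`, `n_images`.
#' @export
variance_decomposition <- function(saccades) {
  d <- saccades[!(saccades$censored %||% FALSE) & !is.na(saccades$latency_ms), ,
                drop = FALSE]
  groups <- split(d$latency_ms, d$image_id)
  groups <- groups[lengths(groups) >= 1]
  if (length(groups) < 2) stop("need at least two images")
  if (!any(lengths(groups) >= 2)) {
    warning("no image has two or more runs; within-image SD undefined")
  }
  ## pooled within-image SD, weighting by degrees of freedom
  ss <- vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))
  df <- pmax(lengths(groups) - 1L, 0L)
  within <- if (sum(df) > 0) sqrt(sum(ss) / sum(df)) else NA_real_
  between <- stats::sd(vapply(groups, mean, numeric(1)))
  list(within_image_sd = within, between_image_sd = between,
       n_images = length(groups))
}
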