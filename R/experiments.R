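#' Generate a set of synthetic saliency maps
#'
#' One map per synthetic "image": a dominant peak of random height plus two
#' lower secondary peaks at random locations. Peak-height variation across
#' maps is what gives the deterministic model its between-image latency
#' spread.
#'
#' @param n number of maps.
#' @param height,width map dimensions.
#' @param peak_range range of the dominant peak's relative height.
#' @param value_range map scale (maximum of a height-1 peak).
#' @param seed master seed.
#' @return List of `saliency_map`s.
#' @export
synthetic_map_set <- function(n, height = 12, width = 16,
                              peak_range = c(0.55, 1), value_range = 1e-9,
                              seed = NULL) {
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    with_seed(seeds[[i]], {
      h1 <- stats::runif(1, peak_range[1], peak_range[2])
      locs <- cbind(sample.int(height, 3), sample.int(width, 3))
      peaks <- list(list(loc = locs[1, ], height = h1),
                    list(loc = locs[2, ], height = h1 * stats::runif(1, 0.3, 0.8)),
                    list(loc = locs[3, ], height = h1 * stats::runif(1, 0.2, 0.6)))
      synthetic_saliency_map(height, width, peaks, value_range = value_range)
    })
  })
}

#' Configuration of a standard experiment
#'
#' Encodes the four standard contrasts between model and human latency
#' distributions: (1) default parameters, one saccade per image, first
#' fixations of the 44-image dataset as ground truth; (2) GA and
#' Nelder-Mead optimisation of the same comparison; (3) ten saccades per
#' image, against the 44-image and then the 91-image first-fixation sets;
#' (4) per-image KS-sum fitness against the 91-image all-fixation samples.
#'
#' Generation/iteration budgets default to reduced values so a full
#' experiment sweep completes in minutes on one CPU; the full-scale budgets
#' (50 GA generations, `200 * dim` NM evaluations) are a configuration
#' change away.
#'
#' @param experiment_id 1, 2, 3 or 4.
#' @param seed master seed.
#' @param runs_per_image saccades per image (1 for experiments 1-2, 10 for
#'   3-4).
#' @param methods optimisers to run (empty for experiment 1).
#' @param fitness fitness variant.
#' @param ga a [ga_control()].
#' @param nm_maxit Nelder-Mead evaluation cap.
#' @param map_height,map_width synthetic map dimensions.
#' @param peak_range dominant-peak height range of the synthetic maps.
#' @param timeout_ms simulation horizon per run.
#' @param out_dir optional archive directory.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(experiment_id, seed = 1,
                              runs_per_image = if (experiment_id >= 3) 10 else 1,
                              methods = switch(as.character(experiment_id),
                                               "1" = character(0),
                                               "2" = c("ga", "nm"), "ga"),
                              fitness = if (experiment_id == 4) "per_image"
                                        else "sum",
                              ga = ga_control(max_generations =
                                c(1, 10, 6, 4)[experiment_id]),
                              nm_maxit = 150,
                              map_height = 12, map_width = 16,
                              peak_range = c(0.55, 1), timeout_ms = 2000,
                              out_dir = NULL) {
  stopifnot(experiment_id %in% 1:4)
  structure(list(experiment_id = as.integer(experiment_id), seed = seed,
                 runs_per_image = runs_per_image, methods = methods,
                 fitness = fitness, ga = ga, nm_maxit = nm_maxit,
                 map_height = map_height, map_width = map_width,
                 peak_range = peak_range, timeout_ms = timeout_ms,
                 out_dir = out_dir),
            class = "experiment_config")
}

## One sub-run: simulate (optionally after optimisation) and compare.
run_subrun <- function(cfg, dataset_label, truth, truth_by_image, maps,
                       per_image_truth = NULL, seed) {
  init <- default_params()
  fits <- list()
  best <- NULL
  for (m in cfg$methods) {
    f <- fit_saccade_model(truth, maps, method = m, fitness = cfg$fitness,
                           per_image_truth = per_image_truth,
                           runs_per_image = cfg$runs_per_image, init = init,
                           control = if (m == "ga") cfg$ga
                                     else list(maxit = cfg$nm_maxit),
                           seed = seed, timeout_ms = cfg$timeout_ms)
    fits[[m]] <- f
    fb <- f$result$trace$best_fitness[nrow(f$result$trace)]
    if (is.null(best) || fb < best$fitness_value) {
      best <- list(fit = f, fitness_value = fb)
    }
  }
  params <- if (is.null(best)) init else best$fit$best_params
  sim <- batch_simulate(maps, params, runs_per_image = cfg$runs_per_image,
                        seed = seed + 1L, timeout_ms = cfg$timeout_ms)
  model <- sim_to_sample(sim, quiet = TRUE)
  list(dataset = dataset_label,
       comparison = compare_distributions(model, truth),
       sim = sim, truth = truth, truth_by_image = truth_by_image,
       params = params, fits = fits,
       variance = if (cfg$runs_per_image >= 2) variance_decomposition(sim)
                  else NULL,
       distinct_counts = count_distinct_latencies(sim, by_image = TRUE))
}

#' Run one of the four standard experiments
#'
#' Generates the synthetic human dataset(s) and synthetic saliency maps,
#' runs the configured simulation/optimisation, and reports the KS/z
#' comparison, the variance decomposition and the per-image distinct
#' latency counts. All randomness derives from the config seed. When
#' `config$out_dir` is set, the simulated and ground-truth latencies are
#' archived as CSV so every statistic can be recomputed from disk (see
#' [report_from_archive()]).
#'
#' @param experiment_id 1, 2, 3 or 4.
#' @param seed master seed (ignored when `config` is given).
#' @param config an [experiment_config()]; built from `experiment_id` and
#'   `seed` when omitted.
#' @return An object of class `experiment_report`: list with `config` and
#'   `subruns` (each holding `comparison`, `sim`, `truth`, `params`,
#'   `fits`, `variance`, `distinct_counts`).
#' @export
run_experiment <- function(experiment_id, seed = 1, config = NULL) {
  cfg <- config %||% experiment_config(experiment_id, seed = seed)
  id <- cfg$experiment_id
  seeds <- derive_seeds(cfg$seed, 8)

  make_truth <- function(dataset, s) {
    dset <- generate_first_fixations(latency_config(dataset), seed = s)
    sample <- filter_outliers(extract_first_fixations(dset), quiet = TRUE)
    by_img <- latencies_by_image(dset, first_only = TRUE)
    list(dataset = dset, sample = sample, by_image = by_img)
  }

  subruns <- list()
  if (id %in% 1:3) {
    t1 <- make_truth("dataset1", seeds[[1]])
    maps44 <- synthetic_map_set(44, cfg$map_height, cfg$map_width,
                                cfg$peak_range, seed = seeds[[2]])
    subruns$dataset1 <- run_subrun(cfg, "dataset1", t1$sample, t1$by_image,
                                   maps44, seed = seeds[[3]][[1]])
    if (id == 3) {
      t2 <- make_truth("dataset2", seeds[[4]])
      maps91 <- synthetic_map_set(91, cfg$map_height, cfg$map_width,
                                  cfg$peak_range, seed = seeds[[5]])
      subruns$dataset2 <- run_subrun(cfg, "dataset2", t2$sample, t2$by_image,
                                     maps91, seed = seeds[[6]][[1]])
    }
  } else {
    dset <- generate_all_fixations(latency_config("dataset2"),
                                   seed = seeds[[1]])
    by_img <- latencies_by_image(dset, first_only = FALSE)
    by_img <- by_img[lengths(by_img) > 0]
    truth <- latency_sample(unlist(by_img, use.names = FALSE), "human")
    maps91 <- synthetic_map_set(length(by_img), cfg$map_height,
                                cfg$map_width, cfg$peak_range,
                                seed = seeds[[2]])
    subruns$dataset2_all <- run_subrun(cfg, "dataset2_all", truth, by_img,
                                       maps91, per_image_truth = by_img,
                                       seed = seeds[[3]][[1]])
  }

  rep <- structure(list(config = cfg, subruns = subruns),
                   class = "experiment_report")
  if (!is.null(cfg$out_dir)) archive_report(rep, cfg$out_dir)
  rep
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment %d report (%d sub-run%s)\n",
              x$config$experiment_id, length(x$subruns),
              if (length(x$subruns) > 1) "s" else ""))
  for (nm in names(x$subruns)) {
    s <- x$subruns[[nm]]
    cat(sprintf("-- %s (model n = %d):\n", nm, s$comparison$n_model))
    print(s$comparison)
    if (!is.null(s$variance)) {
      cat(sprintf("   within-image SD %.2f ms, between-image SD %.2f ms\n",
                  s$variance$within_image_sd, s$variance$between_image_sd))
    }
    cat(sprintf("   distinct latencies per image: median %g, max %g\n",
                stats::median(s$distinct_counts), max(s$distinct_counts)))
  }
  invisible(x)
}

#' Archive an experiment report as CSV files
#'
#' Writes, per sub-run, the simulated saccades, the ground-truth latencies
#' and the fitted parameters, so every reported statistic is recomputable
#' from disk.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
archive_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$subruns)) {
    s <- report$subruns[[nm]]
    utils::write.csv(s$sim, file.path(dir, paste0(nm, "_sim.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(latency_ms = s$truth$values),
                     file.path(dir, paste0(nm, "_truth.csv")),
                     row.names = FALSE)
    write_params(s$params, file.path(dir, paste0(nm, "_params.yaml")))
  }
  invisible(dir)
}

#' Recompute comparison statistics from an archived sub-run
#'
#' @param dir archive directory written by [archive_report()].
#' @param subrun sub-run name (e.g. `"dataset1"`).
#' @return A `latency_comparison` recomputed from the CSVs.
#' @export
report_from_archive <- function(dir, subrun) {
  sim <- utils::read.csv(file.path(dir, paste0(subrun, "_sim.csv")))
  truth <- utils::read.csv(file.path(dir, paste0(subrun, "_truth.csv")))
  compare_distributions(
    latency_sample(sim$latency_ms[!sim$censored], "model"),
    latency_sample(truth$latency_ms, "human"))
}

#' Write the report's standard figures
#'
#' Per sub-run: the model-vs-truth overlaid latency histogram and a
#' per-image strip plot of human and model latencies; plus one illustration
#' of noise added to a saliency map at increasing amplitudes.
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @return Character vector of the files written, invisibly.
#' @export
make_report_plots <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(report$subruns)) {
    s <- report$subruns[[nm]]
    model <- sim_to_sample(s$sim, quiet = TRUE)
    if (model$n == 0) stop("refusing to plot an empty model sample")
    f1 <- file.path(dir, paste0(nm, "_overlay.png"))
    grDevices::png(f1, width = 700, height = 500)
    plot_latency_overlay(model, s$truth,
                         main = sprintf("Experiment %d (%s)",
                                        report$config$experiment_id, nm))
    grDevices::dev.off()
    f2 <- file.path(dir, paste0(nm, "_by_image.png"))
    grDevices::png(f2, width = 900, height = 500)
    plot_latency_by_image(s$truth_by_image, s$sim)
    grDevices::dev.off()
    files <- c(files, f1, f2)
  }
  f3 <- file.path(dir, "noise_effect.png")
  grDevices::png(f3, width = 900, height = 320)
  plot_noise_effect(synthetic_map_set(1, report$config$map_height,
                                      report$config$map_width,
                                      seed = report$config$seed)[[1]])
  grDevices::dev.off()
  invisible(c(files, f3))
}

#' Strip plot of per-image latencies, human vs model
#'
#' @param truth_by_image named list of human latency vectors per image.
#' @param sim a `saccade_sim` data.frame.
#' @param max_images images shown (ordered by id).
#' @return `NULL`, invisibly.
#' @export
plot_latency_by_image <- function(truth_by_image, sim, max_images = 30) {
  ids <- utils::head(names(truth_by_image), max_images)
  ylim <- range(unlist(truth_by_image[ids]), sim$latency_ms, na.rm = TRUE)
  graphics::plot(NULL, xlim = c(0.5, length(ids) + 0.5), ylim = ylim,
                 xlab = "image", ylab = "latency (ms)",
                 main = "Per-image latencies: human (grey) vs model (red)")
  for (i in seq_along(ids)) {
    v <- truth_by_image[[ids[i]]]
    graphics::points(jitter(rep(i, length(v)), amount = 0.15), v, pch = 16,
                     cex = 0.5, col = grDevices::adjustcolor("grey40", 0.6))
    m <- sim$latency_ms[sim$image_id == as.integer(ids[i]) & !sim$censored]
    graphics::points(rep(i, length(m)), m, pch = 4, cex = 0.8,
                     col = "firebrick")
  }
  invisible(NULL)
}

#' Illustrate noise added to a saliency map
#'
#' Shows the map with uniform noise of increasing amplitude added, on a
#' common colour scale: amplitudes far below the map's feature scale leave
#' it visually (and dynamically) unchanged; amplitudes near the feature
#' scale drown the structure.
#'
#' @param map a `saliency_map`.
#' @param noise_ampls noise amplitudes (map units).
#' @param seed RNG seed.
#' @return `NULL`, invisibly.
#' @export
plot_noise_effect <- function(map, noise_ampls = c(0, 1e-11, 1e-9),
                              seed = 1) {
  op <- graphics::par(mfrow = c(1, length(noise_ampls)), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op))
  seeds <- derive_seeds(seed, length(noise_ampls))
  for (i in seq_along(noise_ampls)) {
    a <- noise_ampls[i]
    noisy <- map$values + with_seed(seeds[[i]],
      matrix(stats::runif(length(map$values), 0, a), nrow(map$values)))
    graphics::image(t(noisy)[, rev(seq_len(nrow(noisy)))], axes = FALSE,
                    main = sprintf("noise amplitude %g", a),
                    zlim = c(0, max(map$values) + max(noise_ampls)))
  }
  invisible(NULL)
}
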