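#' @export
print.saccade_fit <- function(x, ...) {
  cat("Saliency-LIF/WTA temporal fit\n")
  cat(sprintf("  method: %s, fitness: %s, stop: %s\n", toupper(x$method),
              x$fitness, x$stopping_reason))
  cat(sprintf("  ground truth: n = %d (mean %.1f ms, sd %.1f ms)\n",
              x$truth$n, mean(x$truth$values), stats::sd(x$truth$values)))
  if (!is.null(x$comparison)) {
    cat(sprintf("  best: D = %.5f (p = %.3g), z = %.5f (p = %.3g)\n",
                x$comparison$D, x$comparison$p_ks, x$comparison$z,
                x$comparison$p_z))
  }
  invisible(x)
}

#' Summary of a fitted saliency-LIF/WTA model
#'
#' @param object a `saccade_fit`.
#' @param ... unused.
#' @return A `summary.saccade_fit` object: fitted coefficients, the final
#'   model-vs-truth comparison, the fitness trace and the change relative to
#'   the initial parameters.
#' @export
summary.saccade_fit <- function(object, ...) {
  v0 <- param_vector(object$init)
  v1 <- coef(object)
  structure(list(fit = object, coef = v1, rel_change = v1 / v0 - 1,
                 comparison = object$comparison, trace = object$trace),
            class = "summary.saccade_fit")
}

#' @export
print.summary.saccade_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted parameters (relative change from initial):\n")
  tab <- cbind(estimate = x$coef, rel_change = x$rel_change)
  print(format(tab, digits = 4), quote = FALSE)
  if (!is.null(x$trace) && nrow(x$trace) > 1) {
    cat(sprintf("\nFitness trace: %.4g -> %.4g over %d generations\n",
                x$trace$best_fitness[1],
                x$trace$best_fitness[nrow(x$trace)], nrow(x$trace)))
  }
  invisible(x)
}

#' @export
coef.saccade_fit <- function(object, ...) param_vector(object$best_params)

#' Simulate latencies from a fitted model
#'
#' Draws `nsim` independent first saccades per training map under the
#' fitted parameters.
#'
#' @param object a `saccade_fit`.
#' @param nsim runs per map.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A `saccade_sim` data.frame.
#' @export
simulate.saccade_fit <- function(object, nsim = 1, seed = NULL, ...) {
  batch_simulate(object$maps, object$best_params, runs_per_image = nsim,
                 seed = seed, timeout_ms = object$timeout_ms)
}

#' Deterministic predicted latency per image
#'
#' The model's noise perturbs only initial values; switching the random
#' component off exposes the deterministic per-image latency the fitted
#' dynamics produce.
#'
#' @param object a `saccade_fit`.
#' @param newmaps optional list of `saliency_map`s (defaults to the
#'   training maps).
#' @param ... unused.
#' @return Named numeric vector of latencies (ms); `NA` for censored
#'   images.
#' @export
predict.saccade_fit <- function(object, newmaps = NULL, ...) {
  maps <- newmaps %||% object$maps
  p <- object$best_params
  nz <- p$noise
  nz$noise_ampl <- 0
  sim <- batch_simulate(maps, sal_params(p$lif, p$wta, nz),
                        runs_per_image = 1, seed = 1L,
                        timeout_ms = object$timeout_ms)
  stats::setNames(sim$latency_ms, sim$image_id)
}

#' Quantile residuals of a fitted model
#'
#' Differences between the model's latency quantiles and the ground-truth
#' quantiles at matched probabilities -- zero everywhere for a perfect
#' distributional fit.
#'
#' @param object a `saccade_fit`.
#' @param nsim runs per map for the model sample.
#' @param seed RNG seed.
#' @param ... unused.
#' @return Numeric vector of quantile differences (ms).
#' @export
residuals.saccade_fit <- function(object, nsim = object$runs_per_image,
                                  seed = NULL, ...) {
  model <- sim_to_sample(simulate(object, nsim = nsim, seed = seed),
                         quiet = TRUE)
  p <- stats::ppoints(model$n)
  stats::quantile(model$values, p, names = FALSE) -
    stats::quantile(object$truth$values, p, names = FALSE)
}

#' Plot model and ground-truth latency distributions
#'
#' Overlaid histograms (density scale) with kernel density curves, the
#' standard visual comparison of the simulated and human latency
#' distributions.
#'
#' @param x a `saccade_fit`.
#' @param nsim runs per map for the model sample.
#' @param seed RNG seed.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.saccade_fit <- function(x, nsim = x$runs_per_image, seed = NULL, ...) {
  model <- sim_to_sample(simulate(x, nsim = nsim, seed = seed), quiet = TRUE)
  plot_latency_overlay(model, x$truth, ...)
  invisible(x)
}

#' Overlaid latency histograms
#'
#' @param model,truth [latency_sample()]s.
#' @param breaks histogram breaks.
#' @param main plot title.
#' @param ... passed to [graphics::hist()].
#' @return `NULL`, invisibly.
#' @export
plot_latency_overlay <- function(model, truth, breaks = 30,
                                 main = "Latency distributions", ...) {
  if (model$n == 0 || truth$n == 0) stop("cannot plot an empty sample")
  rng <- range(model$values, truth$values)
  brk <- seq(rng[1], rng[2], length.out = breaks + 1)
  h1 <- graphics::hist(truth$values, breaks = brk, plot = FALSE)
  h2 <- graphics::hist(model$values, breaks = brk, plot = FALSE)
  ylim <- c(0, max(h1$density, h2$density))
  graphics::plot(h1, freq = FALSE, col = grDevices::adjustcolor("grey40", 0.5),
                 border = NA, xlab = "latency (ms)", main = main,
                 ylim = ylim, ...)
  graphics::plot(h2, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, add = TRUE)
  if (truth$n > 1) graphics::lines(stats::density(truth$values), lwd = 2,
                                   col = "grey20")
  if (model$n > 1) graphics::lines(stats::density(model$values), lwd = 2,
                                   col = "firebrick")
  graphics::legend("topright", c(truth$label, model$label), bty = "n",
                   fill = grDevices::adjustcolor(c("grey40", "firebrick"), 0.5))
  invisible(NULL)
}
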