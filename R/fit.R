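#' Genetic-algorithm settings
#'
#' The standard configuration: 40 contenders per generation, mutation of up
#' to 10\% per parameter with randomized direction and magnitude, the worst
#' 10 contenders reset to the initial parameters, at most 50 generations,
#' stopping early once the best contender's distribution is statistically
#' indistinguishable from the ground truth (both p-values above `alpha`).
#'
#' @param population contenders per generation.
#' @param mutation_max upper bound of the relative mutation magnitude.
#' @param reset_count contenders reset to the initial vector each
#'   generation; must be smaller than `population`.
#' @param max_generations generation cap.
#' @param alpha significance level of the stopping rule and of the z gate.
#' @param stop_on_fit disable to always run the full generation budget.
#' @param free optional logical vector (length 12) or character vector of
#'   [param_vector()] names marking which parameters mutate; the rest stay
#'   at their initial values.
#' @return List of class `ga_control`.
#' @export
ga_control <- function(population = 40, mutation_max = 0.10,
                       reset_count = 10, max_generations = 50,
                       alpha = 0.05, stop_on_fit = TRUE, free = NULL) {
  stopifnot(population >= 2, mutation_max >= 0, mutation_max < 1,
            reset_count >= 0, reset_count < population,
            max_generations >= 1)
  if (is.character(free)) free <- .param_vector_names %in% free
  if (!is.null(free)) stopifnot(is.logical(free), length(free) == 12)
  structure(list(population = population, mutation_max = mutation_max,
                 reset_count = reset_count,
                 max_generations = max_generations, alpha = alpha,
                 stop_on_fit = stop_on_fit, free = free),
            class = "ga_control")
}

## Multiplicative mutation: each free parameter scaled by (1 + u * m) with
## m ~ U(0, mutation_max) and u a random sign. Relative mutation is the
## natural reading when parameters span ten orders of magnitude.
mutate_vector <- function(v, mutation_max, free) {
  m <- stats::runif(length(v), 0, mutation_max)
  u <- sample(c(-1, 1), length(v), replace = TRUE)
  out <- v * (1 + u * m)
  if (!is.null(free)) out[!free] <- v[!free]
  out
}

#' Mutation-only genetic algorithm over the 12-dimensional parameter space
#'
#' Per generation: all contenders are evaluated (the retained elite keeps
#' its recorded evaluation), ranked by the chosen fitness, the single best
#' is carried over unchanged, the worst `reset_count` are reset to the
#' initial vector, and the remainder are mutated multiplicatively. There is
#' no crossover. The search space is unbounded; candidates that cannot fire
#' earn a penalty of 1e6. Each evaluation uses a fresh seed derived from the
#' master seed, recorded in the trace for replay.
#'
#' @param initial `sal_params` bundle to start from (and to reset to).
#' @param truth ground-truth [latency_sample()].
#' @param maps list of `saliency_map`s.
#' @param fitness `"sum"` (`D + |z|`), `"gate"` (z-gate-then-KS ranking) or
#'   `"per_image"` (sum of per-image KS statistics).
#' @param per_image_truth named list of per-image ground-truth samples,
#'   required for `fitness = "per_image"`.
#' @param runs_per_image simulated saccades per map per evaluation.
#' @param control a [ga_control()].
#' @param seed master seed.
#' @param timeout_ms simulation horizon per run.
#' @return An `optimization_result`: `best_params`, `best_vector`,
#'   `fitness`, per-generation `trace`, `stopping_reason`, `comparison`
#'   (evaluation of the best vector), `n_evaluations`.
#' @export
ga_optimize <- function(initial, truth, maps,
                        fitness = c("sum", "gate", "per_image"),
                        per_image_truth = NULL, runs_per_image = 1,
                        control = ga_control(), seed = NULL,
                        timeout_ms = 2000) {
  fitness <- match.arg(fitness)
  stopifnot(inherits(initial, "sal_params"), inherits(truth, "latency_sample"),
            inherits(control, "ga_control"))
  if (fitness == "per_image" && is.null(per_image_truth)) {
    stop("per_image fitness requires per_image_truth")
  }
  v0 <- param_vector(initial)
  np <- control$population
  pit <- if (!is.null(per_image_truth)) {
    lapply(per_image_truth, function(s)
      if (inherits(s, "latency_sample")) s$values else as.numeric(s))
  } else NULL

  scalar_fit <- function(ev) {
    switch(fitness,
           sum = ev$fitness_sum,
           per_image = if (ev$ok) ev$fitness_per_image else .NONFIRING_PENALTY,
           gate = gate_score(ev$D, ev$p_z, ev$z))
  }

  master <- derive_seeds(seed, 3 + control$max_generations)
  pop <- matrix(rep(v0, np), nrow = np, byrow = TRUE,
                dimnames = list(NULL, names(v0)))
  with_seed(master[[1]], {
    for (i in 2:np) pop[i, ] <- mutate_vector(v0, control$mutation_max,
                                              control$free)
  })

  elite_idx <- NA_integer_
  elite_ev <- NULL       # recorded evaluation of the carried-over elite
  trace <- vector("list", control$max_generations)
  n_eval <- 0L
  stopping <- "max_iter"
  gen_done <- 0L

  for (gen in seq_len(control$max_generations)) {
    seeds <- derive_seeds(master[[3 + gen]], np)
    evs <- vector("list", np)
    for (i in seq_len(np)) {
      if (!is.na(elite_idx) && i == elite_idx) {
        evs[[i]] <- elite_ev     # elitism: keep the recorded evaluation
      } else {
        evs[[i]] <- eval_candidate(pop[i, ], initial, maps, truth,
                                   runs_per_image, seeds[[i]], timeout_ms,
                                   per_image_truth = pit)
        n_eval <- n_eval + 1L
      }
    }
    fit <- vapply(evs, scalar_fit, numeric(1))
    ord <- if (fitness == "gate") {
      rank_z_gate(vapply(evs, function(e) e$D %||% NA_real_, numeric(1)),
                  vapply(evs, function(e) e$z %||% NA_real_, numeric(1)),
                  vapply(evs, function(e) e$p_z %||% NA_real_, numeric(1)),
                  control$alpha)
    } else {
      order(fit)
    }
    best <- ord[1]
    bev <- evs[[best]]
    trace[[gen]] <- data.frame(generation = gen, best_fitness = fit[best],
                               best_D = bev$D, best_z = bev$z,
                               best_p_ks = bev$p_ks, best_p_z = bev$p_z,
                               t(pop[best, ]))
    gen_done <- gen
    if (control$stop_on_fit && bev$ok &&
        !is.na(bev$p_ks) && !is.na(bev$p_z) &&
        bev$p_ks > control$alpha && bev$p_z > control$alpha) {
      stopping <- "statistical_indistinguishability"
      elite_idx <- 1L
      pop <- rbind(pop[best, , drop = FALSE], pop[-best, , drop = FALSE])
      elite_ev <- bev
      break
    }
    if (gen == control$max_generations) {
      elite_ev <- bev
      pop <- rbind(pop[best, , drop = FALSE], pop[-best, , drop = FALSE])
      elite_idx <- 1L
      break
    }
    ## next generation: elite first, worst reset_count reset to the initial
    ## vector, the remainder mutated
    newpop <- pop
    newpop[1, ] <- pop[best, ]
    worst <- utils::tail(ord, control$reset_count)
    mid <- setdiff(ord[-1], worst)
    with_seed(seeds[[np]], {
      k <- 1L
      for (i in mid) {
        k <- k + 1L
        newpop[k, ] <- mutate_vector(pop[i, ], control$mutation_max,
                                     control$free)
      }
      for (i in seq_along(worst)) newpop[k + i, ] <- v0
    })
    pop <- newpop
    elite_idx <- 1L
    elite_ev <- bev
  }

  best_vector <- pop[1, ]
  best_params <- set_param_vector(initial, best_vector, validate = FALSE)
  structure(list(best_params = best_params, best_vector = best_vector,
                 fitness = fitness,
                 trace = do.call(rbind, trace[seq_len(gen_done)]),
                 stopping_reason = stopping, comparison = elite_ev$cmp,
                 final_eval = elite_ev, n_evaluations = n_eval,
                 method = "ga", initial = initial),
            class = "optimization_result")
}

#' Nelder-Mead optimisation of the parameter vector
#'
#' Downhill simplex search (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5 -- the coefficients of [stats::optim()]'s Nelder-Mead) from
#' the initial bundle, with an iteration cap of `200 * dim` and a relative
#' tolerance of 1e-4, mirroring the reference implementation's default stop
#' criteria. Parameters are scaled by their initial magnitudes
#' (`parscale`), which the simplex needs when coordinates span ten orders
#' of magnitude. The stochastic fitness is evaluated under common random
#' numbers (one evaluation seed), making the objective deterministic for
#' the simplex.
#'
#' @inheritParams ga_optimize
#' @param fitness `"sum"` or `"per_image"` (a scalar objective is required).
#' @param maxit iteration cap; defaults to `200 * 12`.
#' @param reltol relative convergence tolerance.
#' @param free optional mask of parameters to optimise, as in
#'   [ga_control()].
#' @return An `optimization_result` (trace holds the evaluation count and
#'   final value).
#' @export
nm_optimize <- function(initial, truth, maps, fitness = c("sum", "per_image"),
                        per_image_truth = NULL, runs_per_image = 1,
                        seed = NULL, timeout_ms = 2000,
                        maxit = 200 * 12, reltol = 1e-4, free = NULL) {
  fitness <- match.arg(fitness)
  stopifnot(inherits(initial, "sal_params"), inherits(truth, "latency_sample"))
  if (fitness == "per_image" && is.null(per_image_truth)) {
    stop("per_image fitness requires per_image_truth")
  }
  if (is.character(free)) free <- .param_vector_names %in% free
  v0 <- param_vector(initial)
  pit <- if (!is.null(per_image_truth)) {
    lapply(per_image_truth, function(s)
      if (inherits(s, "latency_sample")) s$values else as.numeric(s))
  } else NULL
  eval_seed <- derive_seeds(seed, 1)[[1]]
  n_eval <- 0L

  idx <- if (is.null(free)) seq_along(v0) else which(free)
  obj <- function(x) {
    v <- v0
    v[idx] <- x
    n_eval <<- n_eval + 1L
    ev <- eval_candidate(v, initial, maps, truth, runs_per_image,
                         eval_seed, timeout_ms, per_image_truth = pit)
    switch(fitness, sum = ev$fitness_sum,
           per_image = if (ev$ok) ev$fitness_per_image else .NONFIRING_PENALTY)
  }
  ps <- pmax(abs(v0[idx]), 1e-300)
  opt <- stats::optim(v0[idx], obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol,
                                     parscale = ps))
  best_vector <- v0
  best_vector[idx] <- opt$par
  final <- eval_candidate(best_vector, initial, maps, truth, runs_per_image,
                          eval_seed, timeout_ms, per_image_truth = pit)
  structure(list(best_params = set_param_vector(initial, best_vector,
                                                validate = FALSE),
                 best_vector = best_vector, fitness = fitness,
                 trace = data.frame(generation = NA_integer_,
                                    best_fitness = opt$value,
                                    best_D = final$D, best_z = final$z,
                                    best_p_ks = final$p_ks,
                                    best_p_z = final$p_z),
                 stopping_reason = if (opt$convergence == 0) "tolerance"
                                   else "max_iter",
                 comparison = final$cmp, final_eval = final,
                 n_evaluations = n_eval, method = "nm", initial = initial),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Optimization (%s, fitness '%s'): %d evaluations, stop: %s\n",
              toupper(x$method), x$fitness, x$n_evaluations,
              x$stopping_reason))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Fit the LIF/WTA model's parameters to a latency distribution
#'
#' The central fitting interface: searches the twelve-dimensional
#' LIF/WTA/noise parameter space so that first-saccade latencies simulated
#' on `maps` match the ground-truth latency sample, using either the
#' mutation-only genetic algorithm or Nelder-Mead, with a KS/z-based
#' fitness. Always starts from the supplied (default) parameter bundle.
#'
#' @param truth ground-truth [latency_sample()] (e.g. from
#'   [extract_first_fixations()] and [filter_outliers()]).
#' @param maps list of `saliency_map`s the model runs on.
#' @param method `"ga"` or `"nm"`.
#' @param fitness `"sum"`, `"gate"` (GA only) or `"per_image"`.
#' @param per_image_truth named list of per-image samples for
#'   `fitness = "per_image"`.
#' @param runs_per_image simulated saccades per map per evaluation.
#' @param init starting (and reset) parameter bundle.
#' @param control a [ga_control()] for `method = "ga"`; for `"nm"`, a list
#'   with optional `maxit`, `reltol`, `free`.
#' @param seed master seed for the whole fit.
#' @param timeout_ms simulation horizon per run.
#' @return An object of class `saccade_fit`; see [coef.saccade_fit()],
#'   [simulate.saccade_fit()], [predict.saccade_fit()],
#'   [plot.saccade_fit()].
#' @examples
#' maps <- lapply(1:6, function(i)
#'   synthetic_saliency_map(12, 16, list(list(loc = c(6, 8),
#'                                            height = 0.8 + 0.03 * i))))
#' truth <- latency_sample(rexgauss(60, 126, 40, 65), "human")
#' fit <- fit_saccade_model(truth, maps, method = "ga",
#'                          control = ga_control(population = 8,
#'                                               max_generations = 2),
#'                          seed = 1)
#' coef(fit)
#' @export
fit_saccade_model <- function(truth, maps, method = c("ga", "nm"),
                              fitness = c("sum", "gate", "per_image"),
                              per_image_truth = NULL, runs_per_image = 1,
                              init = default_params(), control = NULL,
                              seed = NULL, timeout_ms = 2000) {
  method <- match.arg(method)
  fitness <- match.arg(fitness)
  cl <- match.call()
  if (method == "ga") {
    control <- control %||% ga_control()
    res <- ga_optimize(init, truth, maps, fitness = fitness,
                       per_image_truth = per_image_truth,
                       runs_per_image = runs_per_image, control = control,
                       seed = seed, timeout_ms = timeout_ms)
  } else {
    if (fitness == "gate") stop("the z-gate ranking is GA-only")
    control <- control %||% list()
    res <- nm_optimize(init, truth, maps, fitness = fitness,
                       per_image_truth = per_image_truth,
                       runs_per_image = runs_per_image, seed = seed,
                       timeout_ms = timeout_ms,
                       maxit = control$maxit %||% (200 * 12),
                       reltol = control$reltol %||% 1e-4,
                       free = control$free)
  }
  structure(list(call = cl, method = method, fitness = fitness,
                 init = init, result = res,
                 best_params = res$best_params,
                 comparison = res$comparison, trace = res$trace,
                 stopping_reason = res$stopping_reason,
                 truth = truth, maps = maps,
                 runs_per_image = runs_per_image, seed = seed,
                 timeout_ms = timeout_ms),
            class = "saccade_fit")
}
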