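## Fitness machinery shared by the GA and Nelder-Mead drivers. A candidate
## is a 12-vector in param_vector() order; evaluation simulates the
## configured number of saccades and scores the resulting latency sample
## against the ground truth. Candidates that cannot fire (or are not
## physically valid) receive a large penalty rather than an error, since
## the search space is unbounded.

.NONFIRING_PENALTY <- 1e6

## Evaluate one candidate: simulate and compute all statistics the fitness
## variants need. Returns penalty sentinel fields when the candidate fails.
eval_candidate <- function(v, base, maps, truth, runs_per_image = 1,
                           seed = NULL, timeout_ms = 2000,
                           per_image_truth = NULL,
                           penalty = .NONFIRING_PENALTY) {
  bundle <- set_param_vector(base, v, validate = FALSE)
  fail <- list(ok = FALSE, fitness_sum = penalty, fitness_per_image = penalty,
               D = NA_real_, z = NA_real_, p_ks = NA_real_, p_z = NA_real_,
               cmp = NULL, sim = NULL)
  if (!params_valid(bundle)) return(fail)
  sim <- batch_simulate(maps, bundle, runs_per_image = runs_per_image,
                        seed = seed, timeout_ms = timeout_ms)
  if (all(sim$censored)) return(fail)
  model <- sim_to_sample(sim, quiet = TRUE)
  cmp <- compare_distributions(model, truth)
  fpi <- if (!is.null(per_image_truth)) {
    per_image_ks_sum(sim, per_image_truth)
  } else NA_real_
  list(ok = TRUE, fitness_sum = cmp$D + abs(cmp$z), fitness_per_image = fpi,
       D = cmp$D, z = cmp$z, p_ks = cmp$p_ks, p_z = cmp$p_z,
       cmp = cmp, sim = sim)
}

per_image_ks_sum <- function(sim, per_image_truth) {
  total <- 0
  for (id in names(per_image_truth)) {
    d <- sim[sim$image_id == as.integer(id) & !sim$censored, , drop = FALSE]
    if (nrow(d) == 0) next  # image with no surviving runs contributes the max
    total <- total + ks_two_sample(d$latency_ms,
                                   per_image_truth[[id]])$D
  }
  total
}

#' Combined KS + z fitness of a parameter vector
#'
#' Simulates `runs_per_image` saccades per map under the candidate
#' parameters and returns `D + |z|` against the ground-truth sample. A
#' candidate that is physically invalid or produces no spike on any map
#' receives the non-firing penalty (1e6) instead of an error.
#'
#' @param v numeric vector of length 12 in [param_vector()] order, or a
#'   `sal_params` bundle.
#' @param truth ground-truth [latency_sample()].
#' @param maps list of `saliency_map`s to simulate on.
#' @param base `sal_params` bundle supplying the non-optimised constants.
#' @param runs_per_image simulated saccades per map.
#' @param seed evaluation seed.
#' @param timeout_ms simulation horizon per run.
#' @return Scalar fitness (smaller is better).
#' @export
fitness_sum_ks_z <- function(v, truth, maps, base = default_params(),
                             runs_per_image = 1, seed = NULL,
                             timeout_ms = 2000) {
  if (inherits(v, "sal_params")) v <- param_vector(v)
  eval_candidate(v, base, maps, truth, runs_per_image, seed,
                 timeout_ms)$fitness_sum
}

#' Per-image KS-sum fitness
#'
#' The fitness used when the optimiser must match each image's own latency
#' distribution: the sum over images of the KS statistic between the
#' candidate's runs on that image and the image's ground-truth sample.
#' Additive over disjoint image sets; for a single image it reduces to the
#' plain `D`.
#'
#' @inheritParams fitness_sum_ks_z
#' @param per_image_truth named list (by image id) of ground-truth
#'   [latency_sample()]s or numeric vectors.
#' @param runs_per_image simulated saccades per map (10 in the standard
#'   setup).
#' @export
fitness_per_image_ks <- function(v, per_image_truth, maps,
                                 base = default_params(),
                                 runs_per_image = 10, seed = NULL,
                                 timeout_ms = 2000) {
  if (inherits(v, "sal_params")) v <- param_vector(v)
  stopifnot(length(per_image_truth) >= 1)
  truth_all <- latency_sample(
    unlist(lapply(per_image_truth, function(s) {
      if (inherits(s, "latency_sample")) s$values else as.numeric(s)
    }), use.names = FALSE), label = "human")
  eval_candidate(v, base, maps, truth_all, runs_per_image, seed,
                 timeout_ms, per_image_truth = lapply(per_image_truth,
                   function(s) if (inherits(s, "latency_sample")) s$values
                               else as.numeric(s)))$fitness_per_image
}

#' Rank contenders with the z-gate-then-KS rule
#'
#' Contenders passing the z test (`p_z >= alpha`) are ranked first by
#' ascending `D`; the failing contenders are appended, ranked by ascending
#' `|z|`. Every passer precedes every non-passer.
#'
#' @param D KS statistics of the contenders.
#' @param z z statistics.
#' @param p_z z-test p-values.
#' @param alpha gate threshold (0.05).
#' @return Integer permutation ordering the contenders best-first.
#' @export
rank_z_gate <- function(D, z, p_z, alpha = 0.05) {
  stopifnot(length(D) == length(z), length(z) == length(p_z))
  pass <- !is.na(p_z) & p_z >= alpha
  c(which(pass)[order(D[pass])],
    which(!pass)[order(abs(z[!pass]), na.last = TRUE)])
}

## Scalar surrogate consistent with the gate ordering: passers score their
## D (< 1), non-passers score an offset |z| so they always rank behind.
gate_score <- function(D, p_z, z, alpha = 0.05) {
  ifelse(!is.na(p_z) & p_z >= alpha, D,
         1e3 + ifelse(is.na(z), .NONFIRING_PENALTY, abs(z)))
}
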