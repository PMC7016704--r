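## Small shared optimisation fixture: a few maps and a synthetic truth.
opt_maps <- synthetic_map_set(8, 8, 10, seed = 50)
opt_truth <- latency_sample(rexgauss(80, 126, 30, 65), "human")

test_that("mutation is multiplicative, sign-symmetric and maskable", {
  v <- param_vector(defaults)
  set.seed(1)
  m <- saclif:::mutate_vector(v, 0.10, NULL)
  expect_true(all(abs(m / v - 1) <= 0.10))
  expect_true(any(m > v) && any(m < v))
  free <- saclif:::.param_vector_names == "lif.Ginput"
  m2 <- saclif:::mutate_vector(v, 0.10, free)
  expect_identical(m2[!free], v[!free])
  expect_false(m2[["lif.Ginput"]] == v[["lif.Ginput"]])
  ## identity limit: zero mutation leaves the vector untouched
  expect_identical(saclif:::mutate_vector(v, 0, NULL), v)
})

test_that("combined fitness honours its penalty and determinism contracts", {
  v <- param_vector(defaults)
  f1 <- fitness_sum_ks_z(v, opt_truth, opt_maps, defaults, seed = 4)
  f2 <- fitness_sum_ks_z(v, opt_truth, opt_maps, defaults, seed = 4)
  expect_identical(f1, f2)
  expect_lt(f1, 1e6)
  ## a non-firing candidate (all-zero maps cannot drive spikes) is
  ## penalised, not an error
  zero_maps <- list(synthetic_saliency_map(6, 6, list()))
  vz <- v
  vz[["noise.noise_ampl"]] <- 0
  vz[["noise.noise_const"]] <- 0
  expect_equal(fitness_sum_ks_z(vz, opt_truth, zero_maps, defaults, seed = 1),
               1e6)
  ## physically invalid candidates are penalised too
  vneg <- v
  vneg[["noise.map_range"]] <- -1e-9
  expect_equal(fitness_sum_ks_z(vneg, opt_truth, opt_maps, defaults,
                                seed = 1), 1e6)
})

test_that("the z gate ranks every passer ahead of every non-passer", {
  D <- c(0.4, 0.1, 0.3, 0.2)
  z <- c(5, 0.5, -3, 1)
  p_z <- c(0.01, 0.6, 0.02, 0.4)
  r <- rank_z_gate(D, z, p_z)
  expect_identical(r, c(2L, 4L, 3L, 1L))  # passers by D, then by |z|
  ## all pass: pure D ordering
  expect_identical(rank_z_gate(D, z, rep(0.5, 4)), order(D))
  ## none pass: pure |z| ordering
  expect_identical(rank_z_gate(D, z, rep(0.01, 4)), order(abs(z)))
})

test_that("per-image KS fitness is additive and reduces to D", {
  sim <- data.frame(image_id = rep(1:2, each = 3), run_id = 1:3,
                    latency_ms = c(100, 110, 120, 200, 210, 220),
                    censored = FALSE)
  t1 <- list("1" = c(100, 110, 130))
  t2 <- list("2" = c(205, 215, 225))
  s1 <- saclif:::per_image_ks_sum(sim, t1)
  s2 <- saclif:::per_image_ks_sum(sim, t2)
  both <- saclif:::per_image_ks_sum(sim, c(t1, t2))
  expect_equal(both, s1 + s2)
  expect_equal(s1, ks_two_sample(c(100, 110, 120), c(100, 110, 130))$D)
})

test_that("the GA respects elitism, resets and its stopping rules", {
  ctrl <- ga_control(population = 10, reset_count = 3, max_generations = 5,
                     stop_on_fit = FALSE)
  r <- ga_optimize(defaults, opt_truth, opt_maps, fitness = "sum",
                   control = ctrl, seed = 2)
  expect_s3_class(r, "optimization_result")
  expect_identical(nrow(r$trace), 5L)
  ## retained-best fitness never increases
  expect_true(all(diff(r$trace$best_fitness) <= 1e-12))
  expect_identical(r$stopping_reason, "max_iter")
  ## the best is never worse than the start under the same evaluation seed
  expect_lte(r$trace$best_fitness[5], r$trace$best_fitness[1])
  ## zero mutation and no resets: the population cannot change, so the
  ## best parameter vector stays the initial one
  ctrl0 <- ga_control(population = 6, mutation_max = 0, reset_count = 0,
                      max_generations = 3, stop_on_fit = FALSE)
  r0 <- ga_optimize(defaults, opt_truth, opt_maps, control = ctrl0, seed = 3)
  expect_identical(unname(r0$best_vector), unname(param_vector(defaults)))
})

test_that("GA reproducibility: same master seed, same result", {
  ctrl <- ga_control(population = 8, reset_count = 2, max_generations = 3,
                     stop_on_fit = FALSE)
  r1 <- ga_optimize(defaults, opt_truth, opt_maps, control = ctrl, seed = 11)
  r2 <- ga_optimize(defaults, opt_truth, opt_maps, control = ctrl, seed = 11)
  expect_identical(r1$best_vector, r2$best_vector)
  expect_identical(r1$trace, r2$trace)
})

test_that("Nelder-Mead never ends worse than its start and is deterministic", {
  f0 <- fitness_sum_ks_z(param_vector(defaults), opt_truth, opt_maps,
                         defaults, seed = saclif:::derive_seeds(21, 1)[[1]])
  free_names <- c("lif.Ginput", "lif.Vthresh")
  r <- nm_optimize(defaults, opt_truth, opt_maps, maxit = 60, seed = 21,
                   free = free_names)
  expect_lte(r$trace$best_fitness, f0)
  r2 <- nm_optimize(defaults, opt_truth, opt_maps, maxit = 60, seed = 21,
                    free = free_names)
  expect_identical(r$best_vector, r2$best_vector)
  ## untouched coordinates stay at their initial values
  free <- saclif:::.param_vector_names %in% free_names
  expect_identical(r$best_vector[!free], param_vector(defaults)[!free])
})

test_that("fit_saccade_model returns a well-formed model object", {
  fit <- fit_saccade_model(opt_truth, opt_maps, method = "ga",
                           control = ga_control(population = 8,
                                                reset_count = 2,
                                                max_generations = 3,
                                                stop_on_fit = FALSE),
                           seed = 5)
  expect_s3_class(fit, "saccade_fit")
  expect_length(coef(fit), 12)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(nrow(sim), 16L)
  pred <- predict(fit)
  expect_length(pred, 8)
  res <- residuals(fit, nsim = 2, seed = 1)
  expect_true(all(is.finite(res)))
  s <- summary(fit)
  expect_s3_class(s, "summary.saccade_fit")
  expect_output(print(s), "Fitted parameters")
  expect_error(fit_saccade_model(opt_truth, opt_maps, method = "nm",
                                 fitness = "gate"), "GA-only")
  ## plot method draws without error
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(fit, nsim = 2, seed = 1))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
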