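#' Initialise the neuron field from a saliency map
#'
#' Builds the simulation state: every map location gets one LIF unit whose
#' input current is
#' \deqn{I(x) = G_{input}\,(S(x) + c + a\,U(x)),}
#' where \eqn{S} is the map re-expressed on the `map_range` scale, \eqn{c}
#' the constant noise, \eqn{a} the random-noise amplitude and
#' \eqn{U(x) \sim \mathrm{Uniform}(0,1)} drawn once per location at
#' initialisation. The noise is *not* redrawn during integration: it
#' perturbs the model's initial values, not its dynamics. Membrane
#' potentials start at `Eleak`.
#'
#' @param map a `saliency_map`.
#' @param lif a [lif_params()] bundle.
#' @param noise a [noise_params()] bundle.
#' @param seed RNG seed for the per-location uniform draw.
#' @return An object of class `neuron_field_state`: list with matrices `V`
#'   and `I`, logical matrix `fired`, and time `t` (ms).
#' @export
init_input_current <- function(map, lif, noise, seed = NULL) {
  stopifnot(inherits(map, "saliency_map"), inherits(lif, "lif_params"),
            inherits(noise, "noise_params"))
  S <- map$values * (noise$map_range / map$value_range)
  U <- with_seed(seed, matrix(stats::runif(length(S)), nrow(S), ncol(S)))
  I <- lif$Ginput * (S + noise$noise_const + noise$noise_ampl * U)
  structure(list(V = matrix(lif$Eleak, nrow(S), ncol(S)), I = I,
                 fired = matrix(FALSE, nrow(S), ncol(S)), t = 0),
            class = "neuron_field_state")
}

#' One Euler step of the LIF field
#'
#' Reference (R-level) implementation of the membrane update
#' \deqn{V \leftarrow V + \frac{dt}{C}\big(I - G_{leak}(V - E_{leak})
#'  - G_{exc}(V - E_{exc}) - G_{inh}(V - E_{inh})\big).}
#' Units whose updated potential strictly exceeds `Vthresh` are flagged as
#' fired and reset to `Eleak`. The compiled simulation loop in
#' [first_spike()] applies the identical update; this function exists for
#' single-step reasoning, oracles and cross-checks.
#'
#' @param state a `neuron_field_state`.
#' @param params a [lif_params()] bundle.
#' @param Gexc_field,Ginh_field conductance fields (matrix or scalar) of the
#'   excitatory and inhibitory inputs at this step.
#' @param literal_dtC if `TRUE`, multiply by `dt * C` instead of dividing by
#'   `C` -- the printed form of the update, dimensionally inconsistent but
#'   selectable for sensitivity checks.
#' @return The advanced `neuron_field_state` (time moved by `dt`).
#' @export
euler_step <- function(state, params, Gexc_field = 0, Ginh_field = 0,
                       literal_dtC = FALSE) {
  stopifnot(inherits(state, "neuron_field_state"),
            inherits(params, "lif_params"))
  p <- params
  fac <- if (literal_dtC) p$dt * p$C else p$dt / p$C
  V <- state$V + fac * (state$I - p$Gleak * (state$V - p$Eleak) -
                          Gexc_field * (state$V - p$Eexc) -
                          Ginh_field * (state$V - p$Einh))
  if (!all(is.finite(V))) {
    stop(sprintf(paste0("numerical instability: non-finite membrane ",
                        "potential (dt*Gleak/C = %.3g; reduce dt or the ",
                        "conductances)"), p$dt * p$Gleak / p$C))
  }
  fired <- V > p$Vthresh
  V[fired] <- p$Eleak
  state$V <- V
  state$fired <- fired
  state$t <- state$t + p$dt * 1000
  state
}

#' Closed-form threshold-crossing time of a leaky integrator
#'
#' For a single neuron with constant input current `I`, no synaptic
#' conductances and `V(0) = Eleak`, the membrane approaches
#' `Eleak + I / Gleak` exponentially with time constant `C / Gleak`; the
#' threshold is crossed at
#' \deqn{t^* = -\frac{C}{G_{leak}}\,
#'   \log\!\left(1 - \frac{(V_{thresh} - E_{leak})\,G_{leak}}{I}\right).}
#' Serves as the independent oracle for the step-based integrator; on the
#' `dt` grid the simulated spike lands within one step of `t*`.
#'
#' @param I input current (A).
#' @param params a [lif_params()] bundle.
#' @return Crossing time in seconds (`Inf` if the neuron cannot reach
#'   threshold).
#' @export
lif_crossing_time <- function(I, params) {
  p <- params
  vth <- p$Vthresh - p$Eleak
  if (p$Gleak == 0) {
    return(if (I > 0) vth * p$C / I else Inf)
  }
  x <- vth * p$Gleak / I
  if (!is.finite(x) || x >= 1 || I <= 0) return(Inf)
  -(p$C / p$Gleak) * log(1 - x)
}

#' Simulate the first winner-take-all spike for one map
#'
#' Runs the saliency-driven LIF field; each of its spikes delivers a
#' one-step excitatory conductance pulse (`lif$Gexc`, reversal `lif$Eexc`)
#' to the corresponding WTA unit, and the first WTA unit to cross the shared
#' threshold defines the simulated saccade: its latency (ms, spike step
#' times `dt`) and the winning location. With zero noise the winner is the
#' argmax of the map and the latency is exactly reproducible across seeds.
#' If no WTA unit fires within `timeout_ms` the run is censored (a result,
#' not an error).
#'
#' @param map a `saliency_map`.
#' @param lif,wta,noise parameter bundles; see [lif_params()],
#'   [wta_params()], [noise_params()].
#' @param timeout_ms simulation horizon in ms.
#' @param seed RNG seed for the initialisation noise.
#' @param image_id,run_id identifiers carried into the result.
#' @return An object of class `simulated_saccade`: list with `latency_ms`
#'   (NA when censored), `censored`, `winner` (row, col on the map grid),
#'   `winner_image` (image pixels, via `map_scale`), `image_id`, `run_id`,
#'   `seed`.
#' @export
first_spike <- function(map, lif = default_params()$lif,
                        wta = default_params()$wta,
                        noise = default_params()$noise,
                        timeout_ms = 2000, seed = NULL,
                        image_id = NA_integer_, run_id = 1L) {
  stopifnot(inherits(map, "saliency_map"), timeout_ms > 0)
  state <- init_input_current(map, lif, noise, seed)
  max_steps <- ceiling(timeout_ms / 1000 / lif$dt)

  censored <- FALSE
  res <- NULL
  ## analytic shortcut: with no synaptic input on the saliency field and a
  ## sub-critical Euler factor, a unit whose asymptote stays at or below
  ## threshold can never fire, so an under-driven map is censored outright
  a <- lif$dt * lif$Gleak / lif$C
  if (lif$Ginh == 0 && a <= 1 &&
      ((lif$Gleak > 0 && max(state$I) <= (lif$Vthresh - lif$Eleak) * lif$Gleak) ||
         (lif$Gleak == 0 && max(state$I) <= 0))) {
    censored <- TRUE
  } else {
    res <- first_spike_cpp(as.numeric(state$I), nrow(state$I), ncol(state$I),
                           lif$dt, lif$Eleak, lif$Eexc, lif$Einh,
                           lif$Gleak, lif$Gexc, lif$Ginh,
                           lif$Vthresh, lif$C, wta$C, wta$Gleak, max_steps)
    censored <- res$censored
  }
  if (censored) {
    out <- list(latency_ms = NA_real_, censored = TRUE, winner = NULL,
                winner_image = NULL, image_id = image_id, run_id = run_id,
                seed = seed, timeout_ms = timeout_ms)
  } else {
    winner <- c(row = res$winner_row, col = res$winner_col)
    out <- list(latency_ms = res$step * lif$dt * 1000, censored = FALSE,
                winner = winner,
                winner_image = (winner - 0.5) * map$map_scale,
                image_id = image_id, run_id = run_id, seed = seed,
                timeout_ms = timeout_ms)
  }
  structure(out, class = "simulated_saccade")
}

#' @export
print.simulated_saccade <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Simulated saccade: censored at %g ms (no spike)\n",
                x$timeout_ms))
  } else {
    cat(sprintf("Simulated saccade: latency %.1f ms, winner (%d, %d)\n",
                x$latency_ms, x$winner[1], x$winner[2]))
  }
  invisible(x)
}

#' Simulate independent first saccades over a set of maps
#'
#' Each run is a fresh [first_spike()] call with its own derived seed: no
#' state is carried between runs and no inhibition of return is applied, so
#' every saccade is an independent "first" fixation.
#'
#' @param maps list of `saliency_map` objects.
#' @param params a `sal_params` bundle.
#' @param runs_per_image independent runs per map.
#' @param seed master seed; all per-run seeds derive from it.
#' @param timeout_ms simulation horizon per run.
#' @param image_ids identifiers for the maps.
#' @return A data.frame of class `saccade_sim` with columns `image_id`,
#'   `run_id`, `latency_ms`, `censored`, `winner_row`, `winner_col`, `seed`.
#' @export
batch_simulate <- function(maps, params = default_params(),
                           runs_per_image = 1, seed = NULL,
                           timeout_ms = 2000,
                           image_ids = seq_along(maps)) {
  stopifnot(runs_per_image >= 1, inherits(params, "sal_params"))
  if (inherits(maps, "saliency_map")) maps <- list(maps)
  n <- length(maps) * runs_per_image
  seeds <- derive_seeds(seed, n)
  image_id <- rep(image_ids, each = runs_per_image)
  run_id <- rep(seq_len(runs_per_image), length(maps))
  latency <- rep(NA_real_, n)
  censored <- logical(n)
  wrow <- rep(NA_integer_, n)
  wcol <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_along(maps)) {
    for (r in seq_len(runs_per_image)) {
      k <- k + 1L
      s <- first_spike(maps[[i]], params$lif, params$wta, params$noise,
                       timeout_ms = timeout_ms, seed = seeds[[k]],
                       image_id = image_ids[i], run_id = r)
      censored[k] <- s$censored
      if (!s$censored) {
        latency[k] <- s$latency_ms
        wrow[k] <- s$winner[[1]]
        wcol[k] <- s$winner[[2]]
      }
    }
  }
  structure(data.frame(image_id = image_id, run_id = run_id,
                       latency_ms = latency, censored = censored,
                       winner_row = wrow, winner_col = wcol,
                       seed = vapply(seeds, function(s) s %||% NA_integer_,
                                     numeric(1))),
            class = c("saccade_sim", "data.frame"))
}

#' Count distinct latency values per image
#'
#' The model's key temporal signature: with zero noise every run on a given
#' image yields the same latency (one distinct value); with noise far below
#' the map's feature scale, at most two values appear, as the threshold
#' crossing shifts by at most one integration step.
#'
#' @param saccades a `saccade_sim` data.frame (or any data.frame with
#'   `image_id`, `latency_ms`, `censored`).
#' @param by_image if `TRUE`, return a named vector of counts per image;
#'   otherwise `saccades` must contain a single image.
#' @return Integer count(s) of distinct non-censored latencies.
#' @export
count_distinct_latencies <- function(saccades, by_image = FALSE) {
  if (NROW(saccades) == 0) stop("no saccades supplied")
  if (by_image) {
    return(vapply(split(saccades, saccades$image_id), function(d) {
      length(unique(d$latency_ms[!d$censored]))
    }, integer(1)))
  }
  if (length(unique(saccades$image_id)) > 1) {
    stop("saccades span multiple images; use by_image = TRUE")
  }
  length(unique(saccades$latency_ms[!saccades$censored]))
}
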