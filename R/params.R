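#' Membrane parameters of the saliency-driven LIF field
#'
#' Constructs and validates the constants of the leaky integrate-and-fire
#' (LIF) layer that reads the saliency map. The membrane potential of every
#' unit evolves as
#' \deqn{V \leftarrow V + \frac{dt}{C}\left(I - G_{leak}(V - E_{leak})
#'   - G_{exc}(V - E_{exc}) - G_{inh}(V - E_{inh})\right)}
#' and the unit fires when \eqn{V > V_{thresh}} (strict), after which it is
#' reset to \eqn{E_{leak}}.
#'
#' @param dt integration time step in seconds.
#' @param Eleak,Eexc,Einh leak / excitatory / inhibitory reversal potentials
#'   (V).
#' @param Gleak,Gexc,Ginh conductances (S). `Gexc` doubles as the coupling
#'   pulse a saliency-field spike delivers to its winner-take-all unit.
#' @param GinhDecay decay time constant of the inhibitory conductance (s);
#'   inert before the first spike but carried for completeness.
#' @param Ginput input conductance converting saliency-map units to amperes.
#' @param Vthresh firing threshold (V); must exceed `Eleak`.
#' @param C membrane capacitance (F).
#' @return An object of class `lif_params` (a validated named list).
#' @seealso [wta_params()], [noise_params()], [default_params()]
#' @export
lif_params <- function(dt = 1e-4, Eleak = 0, Eexc = 0.1, Einh = -0.02,
                       Gleak = 1e-8, Gexc = 1e-6, Ginh = 0, GinhDecay = 1,
                       Ginput = 0.05, Vthresh = 1e-3, C = 1e-9) {
  p <- list(dt = dt, Eleak = Eleak, Eexc = Eexc, Einh = Einh, Gleak = Gleak,
            Gexc = Gexc, Ginh = Ginh, GinhDecay = GinhDecay, Ginput = Ginput,
            Vthresh = Vthresh, C = C)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                   logical(1)))
  if (dt <= 0) stop("dt must be positive")
  if (C <= 0) stop("C must be positive")
  if (any(c(Gleak, Gexc, Ginh, Ginput) < 0)) {
    stop("conductances Gleak, Gexc, Ginh, Ginput must be nonnegative")
  }
  if (Vthresh <= Eleak) stop("Vthresh must exceed Eleak")
  structure(p, class = "lif_params")
}

#' Membrane parameters of the winner-take-all layer
#'
#' The WTA layer is a second LIF field, one unit per saliency-field unit,
#' excited by the spikes of its corresponding saliency-field neuron. The
#' first WTA unit to cross the (shared) firing threshold defines the
#' simulated saccade. Only the capacitance, leak conductance and global
#' inhibition are layer-specific; the global inhibition fires only *after*
#' the first spike and is therefore inert in this analysis.
#'
#' @param C WTA membrane capacitance (F).
#' @param Gleak WTA leak conductance (S).
#' @param Ginh WTA global inhibitory conductance (S); retained but inert
#'   before the first spike.
#' @return An object of class `wta_params`.
#' @export
wta_params <- function(C = 5e-8, Gleak = 1e-8, Ginh = 1e-2) {
  p <- list(C = C, Gleak = Gleak, Ginh = Ginh)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                   logical(1)))
  if (C <= 0) stop("C must be positive")
  if (Gleak < 0 || Ginh < 0) stop("conductances must be nonnegative")
  structure(p, class = "wta_params")
}

#' Noise and map-range parameters
#'
#' The three scalars that, together with the LIF and WTA constants, complete
#' the twelve-dimensional parameter vector the optimisers search over.
#' `noise_ampl` scales a uniform random perturbation drawn once per run and
#' per location at initialisation; `noise_const` is a deterministic offset;
#' both are added directly to the saliency map, which typically has features
#' of order 1e-9. `map_range` rescales the map so that its nominal output
#' range changes without regenerating it.
#'
#' @param noise_ampl amplitude of random noise (map units), nonnegative.
#' @param noise_const constant noise offset (map units), nonnegative.
#' @param map_range output range of the saliency map (map units), positive.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(noise_ampl = 1e-17, noise_const = 1e-14,
                         map_range = 1e-9) {
  p <- list(noise_ampl = noise_ampl, noise_const = noise_const,
            map_range = map_range)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                   logical(1)))
  if (noise_ampl < 0 || noise_const < 0) stop("noise amplitudes must be >= 0")
  if (map_range <= 0) stop("map_range must be positive")
  structure(p, class = "noise_params")
}

#' Bundle LIF, WTA and noise parameters
#'
#' @param lif a [lif_params()] object.
#' @param wta a [wta_params()] object.
#' @param noise a [noise_params()] object.
#' @return An object of class `sal_params` with elements `lif`, `wta`,
#'   `noise`.
#' @export
sal_params <- function(lif = lif_params(), wta = wta_params(),
                       noise = noise_params()) {
  stopifnot(inherits(lif, "lif_params"), inherits(wta, "wta_params"),
            inherits(noise, "noise_params"))
  structure(list(lif = lif, wta = wta, noise = noise), class = "sal_params")
}

#' Load the canonical default parameter bundle
#'
#' Reads the versioned defaults file shipped with the package (or any file in
#' the same YAML schema). All simulations and optimisations start from these
#' values unless told otherwise.
#'
#' @param file path to a YAML parameter file; defaults to the shipped
#'   `default_params.yaml`.
#' @return A `sal_params` bundle.
#' @export
default_params <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.saclif_cache$defaults)) return(.saclif_cache$defaults)
    file <- system.file("extdata", "default_params.yaml", package = "saclif")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  if (!nzchar(file) || !file.exists(file)) stop("parameter file not found")
  y <- yaml::read_yaml(file)
  out <- sal_params(lif = do.call(lif_params, y$lif),
                    wta = do.call(wta_params, y$wta),
                    noise = do.call(noise_params, y$noise))
  if (cache) .saclif_cache$defaults <- out
  out
}

.saclif_cache <- new.env(parent = emptyenv())

#' Write a parameter bundle to a YAML file
#'
#' Uses the same schema as the shipped defaults file, so optimised parameter
#' sets can be re-loaded with [default_params()].
#'
#' @param params a `sal_params` bundle.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_params <- function(params, file) {
  stopifnot(inherits(params, "sal_params"))
  yaml::write_yaml(lapply(params, unclass), file)
  invisible(file)
}

## Names of the 12 free parameters, in canonical vector order:
## LIF Eexc, Einh, Gleak, Ginput, Vthresh, C; WTA C, Gleak, Ginh;
## noise noise_ampl, noise_const, map_range.
.param_vector_names <- c(
  "lif.Eexc", "lif.Einh", "lif.Gleak", "lif.Ginput", "lif.Vthresh", "lif.C",
  "wta.C", "wta.Gleak", "wta.Ginh",
  "noise.noise_ampl", "noise.noise_const", "noise.map_range")

#' Map a parameter bundle to the 12-dimensional search vector
#'
#' The optimisers operate on an ordered vector of the twelve free scalars:
#' the LIF reversal potentials for excitatory and inhibitory channels, leak
#' conductance, input conductance, firing threshold and capacitance; the WTA
#' capacitance, leak conductance and inhibitory conductance; and the three
#' noise parameters. The mapping is bijective given a base bundle holding the
#' non-optimised constants (`dt`, `Eleak`, `Gexc`, `Ginh`, `GinhDecay`).
#'
#' @param params a `sal_params` bundle.
#' @return Named numeric vector of length 12.
#' @seealso [set_param_vector()]
#' @export
param_vector <- function(params) {
  stopifnot(inherits(params, "sal_params"))
  v <- c(params$lif$Eexc, params$lif$Einh, params$lif$Gleak,
         params$lif$Ginput, params$lif$Vthresh, params$lif$C,
         params$wta$C, params$wta$Gleak, params$wta$Ginh,
         params$noise$noise_ampl, params$noise$noise_const,
         params$noise$map_range)
  names(v) <- .param_vector_names
  v
}

#' Rebuild a parameter bundle from a search vector
#'
#' @param params base `sal_params` bundle supplying the non-optimised
#'   constants.
#' @param v numeric vector of length 12 in the order of [param_vector()].
#' @param validate if `FALSE`, skip the constructors' validity checks and
#'   return a raw bundle (the optimisers explore an unbounded space and must
#'   be able to *evaluate* invalid regions, which then earn a penalty).
#' @return A `sal_params` bundle.
#' @export
set_param_vector <- function(params, v, validate = TRUE) {
  stopifnot(inherits(params, "sal_params"), is.numeric(v), length(v) == 12)
  l <- unclass(params$lif)
  w <- unclass(params$wta)
  n <- unclass(params$noise)
  l$Eexc <- v[[1]]; l$Einh <- v[[2]]; l$Gleak <- v[[3]]
  l$Ginput <- v[[4]]; l$Vthresh <- v[[5]]; l$C <- v[[6]]
  w$C <- v[[7]]; w$Gleak <- v[[8]]; w$Ginh <- v[[9]]
  n$noise_ampl <- v[[10]]; n$noise_const <- v[[11]]; n$map_range <- v[[12]]
  if (validate) {
    sal_params(do.call(lif_params, l), do.call(wta_params, w),
               do.call(noise_params, n))
  } else {
    structure(list(lif = structure(l, class = "lif_params"),
                   wta = structure(w, class = "wta_params"),
                   noise = structure(n, class = "noise_params")),
              class = "sal_params")
  }
}

#' Is a raw parameter bundle physically valid?
#'
#' Used by the optimisers to decide whether a candidate can be simulated at
#' all; invalid candidates receive the non-firing penalty without touching
#' the integrator.
#'
#' @param params a `sal_params` bundle (possibly built with
#'   `validate = FALSE`).
#' @return `TRUE` or `FALSE`.
#' @keywords internal
params_valid <- function(params) {
  l <- params$lif; w <- params$wta; n <- params$noise
  all(is.finite(unlist(lapply(params, unclass)))) &&
    l$dt > 0 && l$C > 0 && w$C > 0 &&
    l$Gleak >= 0 && l$Gexc >= 0 && l$Ginh >= 0 && l$Ginput >= 0 &&
    w$Gleak >= 0 && w$Ginh >= 0 &&
    l$Vthresh > l$Eleak &&
    n$noise_ampl >= 0 && n$noise_const >= 0 && n$map_range > 0
}

#' @export
print.sal_params <- function(x, ...) {
  cat("LIF/WTA/noise parameter bundle\n")
  v <- param_vector(x)
  cat(sprintf("  %-18s %.6g\n", names(v), v), sep = "")
  cat(sprintf("  (fixed: dt = %g s, Eleak = %g V, Gexc = %g S, GinhDecay = %g s)\n",
              x$lif$dt, x$lif$Eleak, x$lif$Gexc, x$lif$GinhDecay))
  invisible(x)
}
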