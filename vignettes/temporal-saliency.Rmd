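---
title: "Temporal accuracy of a saliency-driven LIF/WTA fixation model: methods"
author: "saclif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal accuracy of a saliency-driven LIF/WTA fixation model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the synthetic-data generator, the fitting
procedure and the numerical choices behind `saclif`. The package asks a
narrow question about the classic bottom-up saliency architecture: when a
winner-take-all (WTA) network of leaky integrate-and-fire (LIF) neurons is
driven by a saliency map, can the *timing* of its first spike reproduce the
distribution of human first-fixation latencies, for any setting of its
parameters? The package provides the machinery to pose that question
quantitatively: a saliency front-end, a two-layer spiking simulator, a
calibrated generator of human-like fixation data, distribution statistics,
and two optimisers over the model's twelve free parameters.

## The model

### Saliency front-end

`compute_saliency()` implements the standard centre-surround recipe. An RGB
image is decomposed into an intensity channel (the channel mean), red-green
and blue-yellow opponency built from broadly tuned colour channels — with
the two poles of each axis kept as separate rectified channels, so a lone
red item among green distractors produces a single-peak feature map that
the normalisation stage can promote — and four orientation-energy channels
(quadrature Gabor pairs at 0°, 45°, 90°, 135°). Each channel is expanded
into a 9-level dyadic Gaussian pyramid (levels smaller than a smoothing or
Gabor kernel fall back to bilinear decimation or zero orientation energy,
so small images remain well-defined);
centre-surround feature maps are rectified absolute differences between
centre scales {2, 3, 4} and surrounds offset by {3, 4}, resampled to 1/16 of
the image resolution. Feature maps are weighted by `normalize_map()` — the
max-based \((M-\bar m)^2\) operator, where \(\bar m\) is the mean of the
non-global local maxima — summed into per-channel conspicuity maps, and
averaged with equal weights. We chose the max-based normalisation over the
iterative difference-of-Gaussians variant because it is simpler, fully
deterministic, and sufficient to express the one property the temporal layer
cares about (promotion of maps with a unique dominant peak); the operator is
a function argument, so the choice is visible and replaceable.

All features are contrast-based, so the map is invariant to a constant added
to every channel. The finished map is rescaled linearly so that its maximum
equals `map_range` (default \(10^{-9}\)) — the saliency scale the temporal
layer expects, and itself one of the twelve optimisable parameters. The
front-end is deterministic; all stochasticity enters at simulation time.

Because the temporal layer only reads the map, the experiments default to
*synthetic* maps (`synthetic_saliency_map()`, `synthetic_map_set()`):
pointwise-maxima of Gaussian bumps whose dominant-peak heights vary across
images. This keeps the orchestration fast and makes the one map property
that drives latencies — peak height — an explicit knob. Natural images can
be substituted at any point via `compute_saliency()`.

### LIF field and WTA competition

`first_spike()` simulates two coupled LIF fields on the map grid. Membrane
potentials follow the Euler update

\[
V \leftarrow V + \frac{dt}{C}\Big(I - G_{leak}(V-E_{leak})
 - G_{exc}(V-E_{exc}) - G_{inh}(V-E_{inh})\Big),
\]

with a strict spiking condition \(V > V_{thresh}\) followed by a reset to
\(E_{leak}\). The printed form of this update in the source material
multiplies by \(dt \cdot C\) rather than \(dt / C\); dimensional analysis
(volts per step = amperes × seconds / farads) requires division, so the
package integrates with \(dt/C\) and exposes the literal form as
`euler_step(..., literal_dtC = TRUE)` for sensitivity checks only.

The saliency-driven field receives a constant input current fixed at
initialisation:

\[ I(x) = G_{input}\,\big(S(x) + c + a\,U(x)\big), \qquad U(x) \sim
\mathrm{Uniform}(0,1), \]

with `noise_const` \(c\) and `noise_ampl` \(a\) in map units. The noise is
drawn once per run and location and **never redrawn during integration**:
it perturbs the model's initial values, not its dynamics. This is the crux
of the temporal analysis — a noise source outside the integration loop
cannot turn a deterministic threshold crossing into a latency
*distribution*. An optional per-step intrinsic-noise mode is deliberately
absent from the default path; probing it would change the model class.

Each spike of the saliency field delivers a one-step excitatory conductance
pulse (`Gexc`, reversal `Eexc`) to the corresponding WTA unit. The first
WTA unit to cross the shared threshold ends the run: its crossing step
defines the latency (`step × dt × 1000` ms) and its location the predicted
fixation. Global WTA inhibition and the inhibitory decay constant
`GinhDecay` act only *after* a spike, so for a first-fixation analysis they
are carried but inert. Runs with no WTA spike inside the timeout (default
2000 ms) are *censored* — a recorded outcome, not an error, because
non-firing parameter sets are legitimate points the optimisers must be able
to visit.

### Parameters

The twelve optimised scalars, in `param_vector()` order:

| name | meaning | default | unit |
|---|---|---|---|
| `lif.Eexc` | excitatory reversal | 0.1 | V |
| `lif.Einh` | inhibitory reversal | -0.02 | V |
| `lif.Gleak` | leak conductance | 1e-8 | S |
| `lif.Ginput` | map-to-current conversion | 0.05 | S per map unit |
| `lif.Vthresh` | firing threshold | 1e-3 | V |
| `lif.C` | membrane capacitance | 1e-9 | F |
| `wta.C` | WTA capacitance | 5e-8 | F |
| `wta.Gleak` | WTA leak | 1e-8 | S |
| `wta.Ginh` | WTA global inhibition (inert pre-spike) | 1e-2 | S |
| `noise.noise_ampl` | random-noise amplitude | 1e-17 | map units |
| `noise.noise_const` | constant noise | 1e-14 | map units |
| `noise.map_range` | saliency output range | 1e-9 | map units |

Fixed constants: `dt` (1e-4 s), `Eleak` (0 V), `Gexc` (1e-6 S, the
layer-coupling pulse), `GinhDecay` (1 s). The defaults live in a versioned
YAML file (`inst/extdata/default_params.yaml`); all code paths read
parameters from bundles, never from constants in code. The noise defaults
(1e-17, 1e-14) and the map scale (order 1e-9) are the published ones; the
membrane constants follow the conventions of the classic toolbox
implementation, with the input conductance and coupling pulse chosen once
so that default-model latencies fall on the saccadic scale (roughly 130–600
ms across dominant-peak heights 0.35–1, matching the reported default-model
mean of ~150 ms). The time step deserves a note: the source table prints
"1 × 10⁻³ ms", literally one microsecond; we adopt the toolbox convention
of 0.1 ms and leave `dt` configurable so the literal reading can be tested.

With these dynamics, the latency on a single-peak map has a closed-form
skeleton: the winning unit's inter-spike interval is the leaky-integrator
crossing time \(t^* = -(C/G_{leak})\log(1 - (V_{thresh}-E_{leak})
G_{leak}/I)\), and the WTA unit needs a fixed number of pulses, so latency
is a step function of peak saliency. `lif_crossing_time()` exposes \(t^*\)
and serves as the independent oracle for the integrator: simulated
single-neuron spike times must land within one `dt` of it.

Two consequences of this structure are the package's headline executable
claims. With zero noise the run is fully deterministic — one latency per
image, identical across seeds. With noise far below the map's feature
scale (the best-fitting values: amplitude 1e-14 and constant 1e-11 against
features of order 1e-9), the crossing step can shift by at most one grid
cell, so at most **two** distinct latencies appear per image over any
number of runs. Model latency variance is therefore *image-driven*:
between-image SD is substantial, within-image SD is (near) zero, whereas
human data show tens of milliseconds of within-image spread.

## The synthetic-human generator

The original eye-tracking corpus is not deposited, so
`generate_first_fixations()` / `generate_all_fixations()` emulate its
published anatomy rather than its raw records. The documented facts are:
two dataset configurations (44 images / 782 first fixations, 91 images /
1593 first fixations, 60,186 fixations in total), 16–19 first fixations per
image, 542–794 fixations per image overall (mean 661), a post-exclusion
first-fixation mean of 190.8 ms with SD 77.7 ms, a positively skewed shape
overall and per image, exclusion of fixations longer than 1500 ms, and
outlier shares of 1% and 3% for the two configurations.

Design choices, in the order they bind:

* **Latency family.** Per-image first-fixation latencies are ex-Gaussian —
  the conventional parametric family for skewed response times — plus a
  uniform long-tail outlier component on [1500, 7800] ms. The published
  statistics pin the family's first two moments, not its shape, so the
  third degree of freedom (the exponential share \(\tau\)) was solved
  against the three documented constraints jointly: mean
  \(\mu + \tau = 190.8\), variance \(\sigma^2 + \tau^2 +
  \sigma_{img}^2 = 77.7^2\), and positive *sample* skewness in at least 90%
  of per-image samples of size 16–19. The solved defaults are \(\mu =
  118.8\), \(\sigma = 25.07\), \(\tau = 72\) ms — a \(\tau\) on the high
  side of the RT literature's typical 50–100 ms band, as the per-image
  skewness constraint demands.
* **Between-image variation.** Image identity shifts \(\mu\) by a normal
  deviate with SD 15 ms (\(\sigma_{img}\)). The published per-image panels
  show distinct distributions but quantify no magnitude; 15 ms is a
  realistic, single, documented choice.
* **Counts are exact.** The published totals are *post-exclusion*, so the
  generator emits exactly 782 (or 1593) retained records — per-image counts
  drawn uniformly from {16,…,19} and nudged to the printed total — plus
  extra outlier records (>1500 ms) sized so the pre-exclusion tail fraction
  equals the configured 1% or 3%. Applying `filter_outliers()` to the
  extracted sample therefore reproduces both the printed counts and the
  printed exclusion shares. The source text leaves open whether the 1%/3%
  refer to first fixations or to all fixations; the generator reads them as
  first-fixation shares and exposes the all-fixation tail weight as its own
  configuration knob (default 1%), since 3% of 60,186 long outliers cannot
  physically fit into 8-second presentation windows at the printed
  per-trial fixation counts.
* **Trial structure.** Each trial opens with a fixation begun on the
  pre-image fixation cross (straddling image onset), so the extraction rule
  — first fixation whose onset *and* offset fall inside the presentation
  window — is exercised, not vacuous. The all-fixation generator packs each
  trial sequentially with 15–35 ms inter-fixation gaps inside the 8000 ms
  window; non-initial fixation durations use a shorter ex-Gaussian
  (\(\mu=95, \sigma=30, \tau=50\); later fixations in search are brief,
  and ~40 fixations must fit per trial). A fixed window imposes a negative
  coupling between fixation count and duration — a trial holding 45
  fixations cannot average 200 ms each — so crowded trials shrink the
  non-initial duration location until the expected load sits at ~93% of
  the window, and a draw that still overflows is resampled, with a
  deterministic compression fallback. Outlier fixations in full trials are
  drawn from [1500, 3000] ms so they still fit.
* **What is not emulated.** Saccade kinematics and event detection,
  participant-level correlation structure (participants are labels, not
  random effects), spatial fixation positions (coordinates are uniform
  noise), the count-report task, and any IOR-driven sequential dependency.
  Passing tests therefore certify the *distributional anatomy* the temporal
  analysis consumes — counts, moments, skew, tail, per-image structure —
  not oculomotor realism.

## Statistics

`ks_two_sample()` is the two-sample Kolmogorov–Smirnov statistic with the
asymptotic p-value at effective size \(n_a n_b/(n_a+n_b)\) (delegated to
`stats::ks.test(exact = FALSE)`; a brute-force ECDF enumeration over pooled
breakpoints is kept in the test suite as an independent oracle). Exact
small-sample p-values are out of scope; at the sample sizes of all
experiments the asymptotic form is adequate. `z_test()` is the one-sample
z with known sigma: the model sample's mean against the ground-truth mean,
with the ground-truth SD as sigma. The source names only the statistic's
software function; this one-sample reading is the natural use of that
function here, and the helper is a plain exported function so a pooled
two-sample variant can be swapped in. SD agreement is reported
descriptively (in `latency_comparison` objects), not tested — only the
mean-based z enters the fitness.

`variance_decomposition()` splits latencies into the pooled within-image SD
(degree-of-freedom-weighted) and the SD of per-image means — the two
numbers that carry the headline finding.

## Fitting

`fit_saccade_model()` wraps two optimisers over the unbounded
12-dimensional space, both always starting from the defaults bundle.

**Genetic algorithm** (`ga_optimize()`): 40 contenders, mutation-only —
each parameter independently scaled by \(1 + u \cdot m\) with \(m \sim
U(0, 0.10)\) and a random sign \(u\) — the worst 10 reset to the initial
vector each generation, at most 50 generations, stopping early when the
best contender is statistically indistinguishable from the truth (both
p-values above 0.05). Choices the procedure description leaves open, and
how we resolved them: mutation is *multiplicative* because the coordinates
span ten orders of magnitude (an additive "up to 10%" has no common
meaning across them); there is no crossover (none is described); we keep
the single best contender unchanged between generations (elitism) and
carry its recorded evaluation rather than re-evaluating it, which makes
the reported best-fitness trace well-defined and non-increasing under a
stochastic fitness; each other evaluation gets a fresh seed derived from
the master seed, logged for replay. Candidates that cannot fire — or that
wander into physically invalid coordinates (negative conductances, a
non-positive map range) — score a penalty of \(10^6\), far above any
attainable \(D + |z|\).

Three fitness variants: `sum` (\(D + |z|\), the two statistics summed
without weights — the description prints a bare "+"), `gate` (contenders
failing the z test at 0.05 are ranked behind all passers; passers sort by
ascending \(D\), failers by ascending \(|z|\); the scalar surrogate for the
elite bookkeeping scores passers by \(D\) and failers by \(10^3 + |z|\)),
and `per_image` (the sum over images of per-image KS statistics, used with
10 runs per image and all-fixation ground truth).

**Nelder–Mead** (`nm_optimize()`): the downhill simplex with the reference
default stop criteria — iteration cap \(200 \times\) dimension, tolerance
\(10^{-4}\) — via `stats::optim(method = "Nelder-Mead")`, whose
reflection/expansion/contraction/shrink coefficients (1, 2, 0.5, 0.5) are
the standard ones. Two adaptations matter on this space: coordinates are
scaled by their initial magnitudes (`parscale`), without which a simplex
spanning \(10^{-17}\) to \(10^{-1}\) degenerates immediately; and the
stochastic fitness is evaluated under common random numbers (one evaluation
seed for the whole search), because a simplex cannot contract against
re-sampled noise. The GA, in contrast, uses fresh seeds — selection
tolerates noise and common numbers would let it overfit one noise draw.

## Numerical choices and degenerate inputs

* Spiking is strict (\(V > V_{thresh}\)); simultaneous WTA crossings on
  the same step are resolved by the larger membrane potential, then by
  row-major location order — deterministic and documented.
* Zero-noise winners equal the map argmax; maps with tied maxima fall back
  to the same deterministic tie-break.
* An under-driven saliency field (asymptote at or below threshold,
  \(\max I \le (V_{thresh}-E_{leak})G_{leak}\), valid when the Euler factor
  \(dt\,G_{leak}/C \le 1\) and the field receives no synaptic input) is
  censored analytically without running the loop — the common failure mode
  of mutated candidates, detected in O(map size).
* Non-finite membrane potentials (e.g. an unstable \(dt\,G/C\)) raise an
  error naming the offending parameter scale, in both the R and compiled
  integrators; the compiled loop checks every step.
* The integrator is implemented twice on purpose: an exported, vectorised
  R `euler_step()` as the readable reference, and a compiled loop inside
  `first_spike()` for speed. A test drives a full two-layer simulation
  through both and requires identical spike steps and winners.
* All randomness flows through explicit seeds; master seeds derive child
  seeds (kept inside the 32-bit range), and every generator is
  bit-reproducible under a fixed seed.

## Problem sizes

The packaged experiment defaults are scaled to interactive use on one CPU:
synthetic maps of 12 × 16 cells (latency depends on peak height only, so
map size buys nothing but cost), 10 GA generations for the optimisation
experiment, 6 and 4 for the larger ones, and 150 Nelder–Mead evaluations;
a full sweep of the four experiments completes in minutes. The published
procedure's full budgets (50 generations, \(200 \times 12\) NM
evaluations, population 40) are reachable by passing a different
`ga_control()` / `nm_maxit` — nothing in the code depends on the reduced
defaults. Sample-size contracts are never scaled: experiment 1 compares 44
model saccades with 782 human latencies, experiment 3 uses 440 and 910,
experiment 4 trains against 60,186 all-fixation durations.

## Known limitations

* The temporal layer reads only the map's peak height per image; richer
  map structure (multiple near-ties, spatial extent) influences the winner
  but barely the latency. This is a property of the model class under
  study, not of the implementation — but it means synthetic-map experiments
  need explicit peak-height variation to produce between-image spread.
* The z-gate fitness defines ranking, not a metric; its scalar surrogate
  is only order-faithful, so gate-fitness traces are comparable within a
  run, not across variants.
* The asymptotic KS p-value is conservative for heavily tied samples
  (latencies live on the `dt` grid); the statistic \(D\) itself is exact.
* The generator's participants are exchangeable labels; analyses that need
  participant-level random effects would need a richer generator.
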