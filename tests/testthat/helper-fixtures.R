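## Shared fixtures built in code at test time.

defaults <- saclif::default_params()

## A small single-peak map on the canonical 1e-9 scale.
peak_map <- function(height = 12, width = 16, loc = c(6, 8), h = 1,
                     value_range = 1e-9) {
  synthetic_saliency_map(height, width, list(list(loc = loc, height = h)),
                         value_range = value_range)
}

zero_noise <- noise_params(noise_ampl = 0, noise_const = 0, map_range = 1e-9)

## Brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
## sample point and take the largest absolute difference. Independent of
## ks_two_sample's implementation.
ks_brute <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(xs, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

## Tiny hand-built fixation dataset: image shown 1000-9000 ms.
tiny_dataset <- function() {
  records <- data.frame(
    participant_id = c(1L, 1L, 2L, 3L, 3L),
    image_id = 1L,
    trial_index = c(1L, 1L, 1L, 1L, 1L),
    fixation_index = c(1L, 2L, 1L, 1L, 2L),
    onset_ms = c(800, 1100, 1200, 8600, 8900),
    offset_ms = c(1050, 1400, 1400, 9100, 9300),
    x = 0, y = 0)
  records$duration_ms <- records$offset_ms - records$onset_ms
  trials <- data.frame(participant_id = 1:3, trial_index = 1L, image_id = 1L,
                       image_onset = 1000, image_offset = 9000)
  saclif:::new_fixation_dataset(records, trials, "tiny")
}

sample_skewness <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
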