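Package: saclif
Title: Temporal Accuracy of Saliency-Driven Integrate-and-Fire Fixation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting tools for the temporal side of the classic
    saliency-map + leaky integrate-and-fire (LIF) / winner-take-all (WTA) model
    of fixation generation. Produces bottom-up saliency maps from images
    (centre-surround intensity, colour-opponency and orientation channels),
    drives a two-layer LIF/WTA spiking field from a saliency map to obtain
    first-fixation latencies, and fits the twelve LIF/WTA/noise parameters to a
    target latency distribution with a mutation-only genetic algorithm or
    Nelder-Mead, using Kolmogorov-Smirnov and z statistics as the fitness.
    Includes a calibrated generator of human-like first-fixation datasets
    (ex-Gaussian latencies with a long outlier tail) and orchestration for the
    four standard experiments contrasting model and human latency
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
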