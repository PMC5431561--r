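Package: shotspike
Title: Exact Firing-Time Statistics of Leaky Integrate-and-Fire Neurons
    Driven by Inhibitory Shot Noise
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact stationary firing statistics for leaky integrate-and-fire
    neurons receiving Poissonian trains of instantaneous inhibitory
    post-synaptic potentials with general amplitude distributions (delta,
    exponential, uniform, truncated Gaussian), together with either a DC
    excitatory drive or exponentially distributed excitatory kicks.
    Implements the bilateral-Laplace-transform generating-function method
    for the stationary rate, the first two first-passage moments and the
    coefficient of variation, the spike-triggered rate and spike-train
    power spectrum, and the interspike-interval density by inverse Fourier
    transform on a numerically controlled contour.  Includes the Gaussian
    diffusion-approximation baseline, an exact event-driven simulator for
    single neurons and heterogeneous sparse inhibitory networks, and a
    self-consistent mean-field solver for population-averaged rate and
    coefficient of variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
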