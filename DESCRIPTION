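Package: crstim
Title: Plastic Hodgkin-Huxley Ring Networks Under Coordinated Reset and Sham Multichannel Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation testbed for desynchronizing multichannel neurostimulation.
    Implements a one-dimensional ring of Hodgkin-Huxley neurons coupled through a
    Mexican-hat connectivity template with event-based spike-timing-dependent
    plasticity (STDP), seven spatio-temporally patterned stimulation protocols
    (purely periodic, correlated and uncorrelated noisy multichannel stimulation,
    three coordinated-reset variants, and a no-stimulation control), and the
    complete analysis suite used to classify acute and long-lasting anti-kindling
    effects: average signed connectivity, sorted connectivity matrices, Kuramoto
    order parameters at network and subpopulation level, acute stimulation and
    after-effects, stimulus-locked cross-trial phase distributions, resetting
    indices, and exact rank-sum comparisons across simulation samples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    jsonlite,
    yaml,
    generics,
    withr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
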