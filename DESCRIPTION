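Package: breathscan
Title: DNA Breathing Dynamics and Free-Energy-Landscape Scanning of Promoter Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mesoscopic simulation and analysis of protein-DNA binding-site
    search on promoter sequences. Implements an extended Peyrard-Bishop-Dauxois
    model of DNA base-pair opening (Morse on-site potential with a Gaussian
    solvent barrier, anharmonic stacking) coupled to a Brownian particle that
    slides along the chain and interacts with open regions. Langevin
    trajectories are integrated with a fourth-order stochastic Runge-Kutta
    scheme, reduced by principal component analysis, discretized into a
    conformational Markov network, and decomposed into basins of attraction
    and macrostates of the free energy landscape. Detected sites are
    characterized by occupancy, free energy relative to nonspecific sliding
    states, and entropy, enabling transcription-start-site-like soft spots to
    be located from sequence alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
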