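Package: ipwalk
Title: Mean Path Length Invariance for Random Walks in Open Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test the mean-path-length invariance property of random
    walks (the Cauchy mean-chord result and its diffusive generalization,
    <L> = pi*S/P in two dimensions) for trajectories entering a virtual
    circular medium from an open environment. Provides trajectory file I/O and
    rigid-motion placement on a boundary source circle, exact polyline-to-disk
    clipping into boundary-to-boundary entry events, Monte Carlo ensembles of
    synthetic walkers with configurable step-length distributions, radial
    trajectory-density profiles in equal-area annuli, entrance-angle
    (Lambertian) diagnostics, and mean-free-path estimation from
    one-dimensional projections of movement paths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
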