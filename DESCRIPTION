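Package: peakwalk
Title: Discovery Times of Evolutionary Random Walks on Broad-Peak Fitness
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the time scale of evolutionary innovation:
    how long a monomorphic population performing an evolutionary random walk in
    sequence space needs to discover a target set of genotypes. Implements the
    one-dimensional birth-death projection of the walk onto Hamming distance
    from a target center, exact expected hitting times via tridiagonal solves
    and a forward-sum recurrence (with log-space arithmetic for exponentially
    large times), finite-horizon success probabilities, a classifier for the
    polynomial-versus-exponential dichotomy in sequence length, seeded
    Monte-Carlo simulators of the walk in the full sequence space and in the
    projected chain, rugged-landscape approximation operators (threshold and
    plateau), parallel-search combinatorics, uniformly random multi-peak
    landscapes, and the regeneration process that breaks the exponential
    barrier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
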