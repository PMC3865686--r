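Package: goodsgraph
Title: Diffusible Public Goods and the Evolution of Cooperation on Weighted Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models microbial public-goods dilemmas in which a diffusible
    resource (e.g., invertase-hydrolyzed monosaccharides in yeast colonies)
    is produced at a cost by cooperator cells and shared over a weighted
    graph describing colony geometry. Computes exact stationary public-goods
    fields by sparse linear solves, producer/neighbour retention fractions
    phi0 and phi1 (including analytic closed forms via random-walk
    generating functions, lattice Green's function integrals and the
    arithmetic-geometric mean), identity-by-descent probabilities, and the
    critical benefit-to-cost ratio b/c > 1/(phi0+phi1) with decay and
    social-multiplier extensions. Includes a fast Death-Birth Monte Carlo
    engine for cooperator/defector fixation probabilities, an exact
    absorbing-chain solver for complete graphs, and a worked biophysical
    estimate of the diffusion parameter lambda for S. cerevisiae.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
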