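Package: contactdyn
Title: Contact-Cluster and Relaxation-Timescale Analysis of Protein MD Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies inter-residue contacts in molecular dynamics ensembles
    (shortest heavy-atom distance below a cutoff for a minimum fraction of
    frames), partitions the contact distances into correlated contact clusters
    by Leiden community detection of the correlation matrix under the constant
    Potts model, fits ensemble-averaged nonequilibrium responses with a
    maximum-entropy regularized multiexponential expansion on a log-spaced
    timescale grid, and decomposes the resulting dynamical content by cluster.
    Includes a synthetic-data module that generates ensembles with planted
    correlation structure, planted relaxation spectra and toy atomic
    structures, so that every stage of the pipeline can be validated against
    ground truth without MD trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
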