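Package: corticonn
Title: Comparative Analysis of Mammalian Cortical Connectomes
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating the existence of cortico-cortical
    connections to physical distance and cytoarchitectonic similarity
    across mammalian species, predicting the laminar origin of
    connections (NSG%) from cytoarchitectonic gradients versus the
    rostrocaudal axis with out-of-sample support-vector regression,
    and characterizing the clique-based structural network core and
    its communication efficiency under shortest-path and random-walk
    models.  Includes tri-state (present/absent/unknown) connectome
    I/O, a synthetic-cortex generator with known ground truth,
    energy-distance and Kolmogorov-Smirnov permutation tests, and
    degree-preserving directed null models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
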