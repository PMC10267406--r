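Package: boolpath
Title: Boolean Modeling and Perturbation Analysis of Molecular Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analyzing Boolean models of molecular
    pathway maps. Reads and writes logical models as plain-text rules and
    SBML-qual, reduces process-description reaction graphs to activity-flow
    Boolean networks and infers the logical functions, computes topological
    statistics (degrees, feedback loops, betweenness and stress centrality),
    executes synchronous, asynchronous and continuous-time stochastic Boolean
    dynamics, finds attractors by exhaustive enumeration, SAT encoding,
    strongly-connected-component decomposition, heuristic restarts and
    asynchronous random walks, and quantifies knockout/overexpression
    sensitivity with similarity- and identity-based attractor distances to
    prioritize intervention targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    xml2,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
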