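Package: agavenet
Title: Microbial Interaction Networks from Abundance Tables via Sparse
    Generalized Lotka-Volterra Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring directed, signed microbial interaction
    networks from genus-level abundance tables and for characterising the
    resulting networks against random-graph null models. Includes a
    generalized Lotka-Volterra community simulator with a multinomial
    sequencing model emulating a balanced two-soil, two-season survey
    design; count-table processing (rarefaction, taxonomy-confidence and
    relative-abundance filters, genus aggregation, alpha diversity);
    balanced two-way ANOVA from raw data or printed cell summaries;
    functional-guild abundance profiles; consensus network inference by
    forward-selection sparse regression over sample orderings; network
    property reports (density, clustering, diameter, modularity, hubs,
    motif census, power-law degree fits); and Erdos-Renyi ensembles for
    empirical significance of network features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    vegan,
    pracma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
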