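Package: volescape
Title: Multi-Scale Habitat Connectivity and Occupancy Analysis for Grey-Sided Voles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking grey-sided vole (Myodes rufocanus)
    occurrence to boreal forest structure at three spatial scales: microhabitat
    (ordinal ground-structure inventories modelled with binomial-logit mixed
    models under all-subsets AICc selection and full model averaging), local
    (focal patch area of >60-year-old forest), and landscape (graph-based
    habitat connectivity via the integral index of connectivity with its
    intra/flux/connector decomposition, and Euclidean plus least-cost-path
    distances from sampling plots to stone-field network components).
    Includes exact nonparametric tests, quadratic discriminant analysis with
    leave-one-out validation, readers and writers for ESRI ASCII grids and
    Conefor node/connection files, and a seeded synthetic-landscape generator
    so the full analysis runs without access to field or GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
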