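Package: debranch
Title: Model-Guided Debranching of Metabolic Flux in Engineered E. coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling toolkit for designing
    "debranching" interventions in heterologous terpenoid production strains.
    Provides a compact genome-scale-model data structure with SBML/JSON
    readers and writers, heterologous pathway extension from tab-separated
    reaction tables, expression-scaled enzyme-capacity (Vmax) bounds built
    from kcat and transcript abundance, flux-ratio and grouped
    precursor-consumption constraints, flux balance analysis on a built-in
    bounded-variable simplex solver, parsimonious baseline flux, flux
    variability analysis, hit-and-run flux sampling, Michaelis-Menten
    branch-point screening of competing precursor consumers, graded gene
    knockdown and overexpression sweeps, and comparative flux analytics
    (FVA-interval Jaccard, sampling volcano, metabolite flux-sums). A
    synthetic toy network with planted ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
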