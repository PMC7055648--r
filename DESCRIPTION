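Package: mesoconn
Title: Mesoscale Functional Connectivity Networks from Single-Cell Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds and analyses whole-brain mesoscale functional networks
    from multi-subject single-cell calcium fluorescence recordings. Provides
    a multistage spatially constrained parcellation of aligned cell clouds,
    signed Fisher-z functional connectivity with Fourier phase-randomized
    surrogate nulls, single-layer and multilayer signed modularity
    maximization under a uniform null model (Louvain optimization,
    weight-distribution resolution sampling, hierarchical consensus
    clustering of coassignment matrices), node flexibility and
    participation-coefficient hub metrics, z-Rand partition similarity,
    geometric connectivity profiling, Mantel tests, and intersubject
    similarity reports. A synthetic-data generator with planted spatial,
    modular, and flexibility structure makes the whole pipeline testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
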