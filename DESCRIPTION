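Package: wolbdyn
Title: Wolbachia Infection-Frequency Dynamics Under Cytoplasmic Incompatibility
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-generation recursions for host populations segregating
    for two maternally inherited Wolbachia variants (a CI-inducing strain and
    a non-CI mutualist) together with uninfected cytoplasm. Provides
    equilibrium and invasion analysis (stable and unstable infection
    frequencies, Fisherian versus bistable classification), inference of
    relative fecundity from observed frequency changes, field-survey
    statistics (exact binomial confidence intervals, G-tests of
    heterogeneity, line-bootstrap maternal-transmission estimates), joint
    tracking of mitochondrial haplotypes to illustrate cytoplasmic
    hitchhiking, a one-dimensional deme-lattice simulator contrasting
    bistable and Fisherian spatial spread, and synthetic survey and
    isofemale-line data generators for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
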