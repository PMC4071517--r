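Package: kinMMRR
Title: Model-Averaged Multiple Matrix Regression for Individual-Based
    Landscape Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based tests for isolation by distance, isolation by
    environment and isolation by community from dominant binary markers
    (AFLP-style presence/absence scores). Estimates pairwise kinship
    coefficients under Hardy-Weinberg equilibrium, builds geographic,
    environmental (per-variable and PCA-combined) and community (Jaccard)
    distance matrices, screens them for collinearity by variance inflation
    factors, fits all submodels of the multiple matrix regression and
    averages coefficients by AICc weight with unconditional standard errors,
    and assesses significance by Mantel-style permutation of the kinship
    matrix with Benjamini-Hochberg false-discovery-rate control. Includes a
    synthetic-data generator with controllable spatial, environmental and
    community effects so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, vegan, jsonlite, optparse, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
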