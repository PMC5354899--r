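Package: pathflow
Title: Mechanistic Signaling Circuit Activity Analysis from Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models signaling pathways as directed graphs with activation and
    inhibition edges, decomposes them into receptor-to-effector circuits, and
    propagates normalized gene expression values through the circuits to
    estimate per-sample signaling activity at the circuit, effector-circuit
    and cell-function levels. Includes two-group differential activation
    testing with false discovery rate control, Kaplan-Meier survival
    stratification by extreme activity deciles, integration of deleterious
    variants as gene integrity factors, and simulation tools to calibrate the
    specificity and sensitivity of the whole pipeline on synthetic pathways
    and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
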