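Package: metacosm
Title: Time-Series Metagenome Dynamics of Disturbed Soil Microcosms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-course shotgun-metagenome studies of
    disturbed (e.g. pollutant-amended) soil microcosms. Implements marker-gene
    based genome-equivalent normalization of functional abundances (gyrB plus
    universal single-copy genes), KEGG-pathway abundance aggregation and
    filtering, log2 variation-profile scoring with k-means clustering selected
    by the Calinski-Harabasz index, Shannon-Wiener diversity and
    correlation-distance sample clustering, best-hit assignment filters for
    BLAST tabular output, an all-against-all gene-pool distance (D2) from
    best-hit bit-score sums, and detection of phage-host bloom asynchrony
    (kill-the-winner signal). A synthetic-data module generates count tables
    with the statistical structure the analyses assume, so every stage is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ape,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
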