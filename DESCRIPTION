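Package: stexpat
Title: Recurrent Spatial-Temporal Expression Patterns on an Anatomical Grid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes spatial-temporal gene expression energies on a
    rectangular grid of developing-brain substructures (20 anterior-posterior
    segments by 4 dorsal-ventral layers) into demarcated expressed regions,
    7-bit global expression state vectors, and recurrent local expression
    patterns. Expressed regions are delineated per gene and time point by a
    stability-based threshold sweep over the sorted distinct energy values:
    the component structure with the longest valid interval of thresholds is
    selected and binarized at its lower (or upper) bound. Global expression is
    called when the largest connected expressed component exceeds half of the
    substructures with valid data, justified by a random-matrix null model.
    Recurrent local patterns are obtained by clustering overlapping expressed
    components via a Jaccard overlap graph. Downstream statistics include
    hypergeometric gene-set enrichment with Benjamini-Hochberg correction,
    temporal occurrence distributions of regional pattern groups, and
    co-expression-group selection with a two-sample Kolmogorov-Smirnov
    comparison. A seeded synthetic-field generator with planted patterns,
    planted global states, noise and missing cells supports end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
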