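Package: pemriver
Title: Water Quality Indices, Ecological and Human Health Risk, and Source
    Apportionment for Metal(loid)-Affected Rivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computation chain for assessing dissolved potentially ecotoxic
    metal(loid) (PEM) contamination in river systems affected by mining.
    Implements regulatory water-quality indices (heavy metal evaluation index,
    pollution load index, weighted water quality index, CCME water quality
    index), the Hakanson potential ecological risk index, US-EPA style
    quantitative human health risk assessment (chronic daily dose, hazard
    quotient/index, excess lifetime cancer risk), detection-limit censoring
    policies, and multivariate source apportionment (KMO and Bartlett
    diagnostics, varimax-rotated principal components, average-linkage
    clustering). Ships a fully worked river fixture and a seedable synthetic
    river generator with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
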