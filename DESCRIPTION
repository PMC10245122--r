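Package: hicevo
Title: Comparative Evolutionary Analysis of 3D Genome Organization from Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing 3D genome organization across mammalian
    species from binned Hi-C contact matrices. Implements Knight-Ruiz style
    matrix balancing, observed/expected and quantile normalization, two-step
    A/B compartment calling with a 20-kb A-B index, K-means grouping of
    cross-species compartment states, insulation-score TAD boundary detection
    with a TAD-strength statistic, promoter-enhancer interaction (PEI) calling
    against a domain-aware background with aggregate peak analysis, and
    cross-species conservation classifiers for boundaries, TADs and PEIs via
    reciprocal homology maps. Includes conserved-rank expression scaling,
    a transcription-factor pair inference framework, permutation and Fisher
    enrichment tests, and a synthetic multi-species Hi-C generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
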