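Package: vartier
Title: Integrative Annotation Scoring and Tiering of GWAS Risk Variants
Version: 1.0.0
Authors@R: person("Vartier", "Maintainers", email = "maintainers@vartier.dev",
    role = c("aut", "cre"))
Description: Prioritizes candidate functional variants at GWAS risk loci by
    combining fine-mapping posterior probabilities, massively parallel
    reporter assay (MPRA) allelic activity, chromatin state, open chromatin,
    CTCF binding, long-range chromatin contacts, 3D-structure disruption
    scores and summary-based Mendelian randomization into a per-variant
    0/1/2 annotation score, a cross-cell-line consensus, and a Tier 1/2/3
    assignment. Nominates effector genes from multi-source evidence with
    staged fallbacks, and provides permutation-based variant-set and
    transcription-factor count enrichment tests. Ships a synthetic-data
    generator with planted causal variants so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
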