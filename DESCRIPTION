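Package: neoexome
Title: Somatic Variant Filtering, Mutational Signatures and Clinical
    Endpoints for Neoadjuvant Breast Cancer Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of the molecular and clinical
    analysis pipeline of a single-arm phase II neoadjuvant breast
    cancer study. Provides threshold-based somatic SNV and INDEL
    filtering with a complete per-record audit, consensus functional
    impact classification from six in-silico predictor verdicts,
    callable-genome mutation burden in two counting modes, refitting of
    96-context trinucleotide mutation catalogs against a reference
    signature matrix with minimum-contribution pruning, gene-set
    over-representation by the EASE (modified Fisher) test, a simplified
    diagnostic-to-residual clone tracker based on binomial mixture
    clustering of variant allele frequencies, and the trial's clinical
    endpoint and single-stage binomial design statistics. A synthetic
    data generator with known ground truth makes every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    fgsea,
    pracma,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
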