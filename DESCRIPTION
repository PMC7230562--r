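Package: melscreen
Title: Germline Variant Prioritization and Rare-Variant Aggregation for
    Hereditary Melanoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a multi-stage germline variant
    prioritization cascade for pedigree-structured whole-exome cohorts
    (quality gate, sibling-aware sharing criteria, broad/stringent annotation
    selection, allele-frequency and gene-level exclusions), case/control
    carrier-frequency screening with rarity classification and
    autosomal-dominant consistency filtering, and region-based rare-variant
    aggregation tests (burden, SKAT, SKAT-O) implemented from first
    principles with quadratic-form tail probabilities (Imhof/Davies
    inversion, Liu moment matching) and a permutation oracle. Includes a
    deterministic synthetic annotated-VCF cohort generator emulating a
    multiple-primary-melanoma study design for end-to-end validation and
    statistical calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
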