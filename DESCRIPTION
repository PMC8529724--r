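Package: xenoScreen
Title: Drug-Response Analysis for Matched Patient-Derived Xenograft and 3D
    Culture Models
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies preclinical drug response in matched patient-derived
    xenograft (PDX) and patient-derived 3D culture (PD3D) tumor models.
    Computes caliper-based tumor volumes, doubling times and treated-versus-
    control (T/C) ratios in vivo; fits four-parameter-logistic dose-response
    curves and reports viability at the maximal plasma concentration (Cmax)
    in vitro; maps both readouts onto a four-level ordinal response scale
    and scores cross-platform concordance; implements single-sample and
    two-group gene set enrichment analysis (ssGSEA/GSEA) from scratch;
    selects predictive biomarkers by Welch contrasts and ROC-based cutoffs
    matched across sample types; and evaluates drug-combination synergy by
    Bliss excess and gain over best monotherapy. A seeded synthetic-data
    generator emits every input format with known ground truth for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    SummarizedExperiment,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Pharmacogenomics, GeneSetEnrichment, DoseResponse
RoxygenNote: 7.3.3
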