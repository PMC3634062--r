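Package: platcon
Title: Cross-Platform Transcriptome Concordance and Co-Expression Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing bulk transcriptome profiles of the same
    samples measured on two platforms (RNA-Seq FPKM and microarray
    intensities): detection filtering, expression-level binning,
    replicate and cross-platform concordance statistics, hierarchical
    clustering and k-means/PCA ordination of tissues, Shannon-entropy
    tissue specificity, paralog-pair correlation analysis against a
    random-pair null, per-platform co-expression networks with Fisher
    transformation and edge normalization, a mixed-platform bootstrap
    null for network similarity, and per-gene expression-conservation
    (EC) scores with empirical significance. Includes a synthetic-data
    generator producing paired two-platform expression tables with
    known latent modules, tissue groups, paralog cross-hybridization,
    microarray saturation and low-count RNA-Seq artifacts, so every
    stage of the pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
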