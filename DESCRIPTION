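Package: sticatlas
Title: Molecular Subtyping and Aneuploidy Profiling of Tubal Precancerous Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis toolkit for spatially profiled ovarian
    cancer precursor lesions (serous tubal intraepithelial carcinomas, STIC).
    Provides consensus non-negative matrix factorization for molecular
    subtype discovery from area-of-interest (AOI) expression profiles,
    reference-panel arm-level aneuploidy Z-scoring and circular binary
    segmentation of RealSeqS-style locus counts with focal amplification
    calls and an aneuploidy index, moderated-t differential expression with
    preranked gene-set enrichment, cytoband-level RNA-DNA integration,
    molecular distance scoring against reference centroids, and the
    contingency-table association statistics used for clinicopathological
    characterization. A seeded synthetic-cohort generator emulating the
    structure of such studies makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    cluster,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    mclust,
    Matrix,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
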