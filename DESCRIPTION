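Package: ssrclone
Title: SSR Fingerprinting and Clonal Duplicate Detection in Polyploid
    Germplasm Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying genotypes and flagging clonal duplicates
    in polyploid germplasm collections scored with simple sequence repeat
    (SSR, microsatellite) markers in binary presence/absence format. Provides
    allele-frequency estimation for dosage-ambiguous polysomic genotypes
    (uniform-split and EM with partial selfing), per-locus diversity and
    informativeness statistics (Nei's gene diversity with finite-sample
    correction, polymorphism information content), banding-pattern
    discriminating power with greedy minimal marker-panel selection,
    Jaccard dissimilarity with neighbor-joining clustering, locus-level
    bootstrap support and Newick export, threshold-based duplicate flagging
    with per-locus verification and ROC evaluation, and a hexaploid
    genotype simulator with clonal structure and genotyping noise for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
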