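Package: mitocn
Title: Mitochondrial DNA Copy-Number Quantification and Cohort Statistics
Version: 0.1.0
Authors@R: person("mitocn", "maintainers", email = "mitocn@example.org",
    role = c("aut", "cre"))
Description: Relative mitochondrial DNA (mtDNA) copy-number estimation from
    qPCR delta-delta-Ct plate data and from whole-genome sequencing coverage
    ratios, with plate/batch/concentration correction, rank-based inverse
    normal transformation, haploid genetic-relatedness matrices and PCA from
    mtDNA variants, haplogroup one-vs-rest association, and the cohort
    statistics used in multi-generation trauma epidemiology (PCL-C scoring,
    Fisher exact enrichment, parent-child inheritance models, blood-count
    confounder screens, minimal-detectable-effect power analysis). Includes a
    pedigree-structured synthetic cohort generator so every stage is testable
    without access to restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, VariantAnnotation,
    BiocGenerics, SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
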