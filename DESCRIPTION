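Package: larvatlas
Title: Comparative Single-Cell Atlas Analysis for Marine Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative single-cell transcriptomics of
    marine invertebrate larvae. Provides cell and gene quality control,
    library-size normalization, variable-gene selection and PCA for UMI count
    matrices; an iterative cluster-merging algorithm that combines
    over-clustered partitions until all remaining clusters are separated by a
    minimum number of differentially expressed genes (Wilcoxon rank-sum);
    cell-type-level phylostratigraphy with the transcriptome age index (TAI)
    and hypergeometric phylostratum enrichment of marker genes; cross-species
    cell-type alignment scores based on mutual nearest cross-species neighbors
    through a (possibly many-to-many) ortholog map; and neuropeptide-precursor
    candidate discovery by secretome restriction and basic-residue
    cleavage-site scanning. Seeded synthetic-data generators with planted
    ground truth allow every stage to be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Biostrings,
    methods,
    igraph,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
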