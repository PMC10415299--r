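Package: scratchcn
Title: Copy-Number Transition-Point Fingerprinting and Clonal Analysis of
    Multi-Metastasis Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the clonal relationships of
    spatially and temporally separated tumor samples from shallow
    whole-genome copy-number profiles.  Implements tumor-purity
    estimation from phased haplotype B-allele frequencies in allelically
    imbalanced anchor regions, a penalized purity/ploidy grid fit,
    greedy copy-number segmentation on a fixed bin grid, extraction of
    copy-number transition points, the SCRATCH hierarchical clustering
    of samples on copy numbers at transition points with silhouette
    model selection, dendrogram congruence testing (Baker's Gamma and a
    maximum-agreement-subtree congruence index with permutation nulls),
    a ternary androgen-receptor activity score from expression counts,
    cancer-cell-fraction computation for structural-variant breakpoints,
    and clonal-mutation overlap statistics.  A clone-tree simulator
    generates fully specified synthetic cohorts (binned read counts,
    phased SNPs, mutation sets, expression) with planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    ape,
    limma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
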