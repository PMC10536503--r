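Package: carriergwas
Title: Pedigree-Informed Carrier-Augmented GWAS for Recessive Disease in Closed Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of putatively recessive
    disease in closed breeding populations such as purebred dogs. Implements
    pedigree construction and additive-relationship (kinship) computation by the
    tabular method, pedigree-based carrier classification and relative exclusion,
    common-ancestor tracing, PLINK-style PED/MAP genotype input with quality
    control, method-of-moments identity-by-descent (PIHAT) estimation, mutual
    k-nearest-neighbour relationship networks, GCTA-style genetic relationship
    matrices and mixed-linear-model association with Storey q-values computed
    genome-wide and per chromosome, Gabriel-style haplotype-block detection with
    EM haplotype-frequency estimation and haplotype regression, AI-REML variance
    components with likelihood-ratio tests, and the observed-to-liability-scale
    heritability transformation for ascertained case-control samples. Includes a
    gene-dropping simulator of multi-generation breed pedigrees with blockwise
    linkage disequilibrium and a planted recessive risk locus, so the full
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
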