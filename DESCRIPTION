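Package: sageqtl
Title: Cis-eQTL and Alternative-Polyadenylation QTL Mapping for Tag-Based
    Expression Sequencing
Version: 0.1.0
Authors@R:
    person("sageqtl", "developers", email = "sageqtl@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping cis-acting expression quantitative trait
    loci (cis-eQTLs) from tag-based 3'-end expression sequencing
    (SAGE/DeepSAGE) count data.  Implements tag presence and
    CATG-anchor-SNP filtering, quantile normalization, per-sample GC
    content estimation, principal-component confounder removal on the
    sample correlation matrix, Spearman rank association within a cis
    window with permutation-based tag-level false discovery rate control,
    detection and classification of genotype-dependent alternative
    polyadenylation switches (opposite-direction regulation of two tags
    of one gene), allele-swap polyadenylation-signal motif scanning with
    linkage-disequilibrium proxy expansion, and square-root-of-n weighted
    Z-score meta-analysis across sequencing-based eQTL datasets.  A
    synthetic-data generator reproduces the statistical structure such
    data exhibit (negative-binomial tag counts, library-size variation,
    dominant hemoglobin-like tags, a latent GC confounder loading on the
    first principal component, LD-blocked genotypes, planted eQTL and
    APA effects) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
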