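# sageqtl

Cis-eQTL and alternative-polyadenylation QTL mapping for tag-based
3'-end expression sequencing (SAGE/DeepSAGE).

## The problem

Tag-based expression sequencing counts one 21-bp tag ("CATG" + 17 nt,
anchored at the transcript's 3'-most NlaIII site) per transcript 3'
end. This makes it well suited to two questions that probe the
regulatory consequences of genetic variation in a cohort:

1. **cis-eQTLs** — which SNPs are associated with the abundance of a
   nearby tag (within 250 kb of the tag midpoint)? Tested with a
   Spearman rank correlation, with tag-level FDR controlled at 0.05
   against a sample-label-permutation null, after quantile
   normalization and optional removal of leading expression principal
   components (computed from the sample correlation matrix), which
   absorb technical/physiological confounders such as sample GC
   content.
2. **APA-QTLs** — which SNPs act as a *switch* between alternative
   polyadenylation sites? Because distinct tags of one gene mark
   distinct 3' ends, a SNP that raises one tag and lowers another tag
   of the same gene (opposite signed z) indicates a 3'-UTR
   shortening/lengthening switch. Pairs are called either strictly
   (both tags FDR-significant, each p < 1e-7) or permissively (one
   significant tag, and the difference between the two correlations
   significant at 1e-7 by the Fisher r-to-z test
   `(atanh(r1) - atanh(r2)) / sqrt(2/(n-3))`).

Candidate causal variants are sought by expanding each APA SNP to its
LD proxies (r² ≥ 0.8) inside the gene and scanning the ±5 nt
strand-specific context for allele swaps that create or destroy one of
the 13 polyadenylation-signal motifs (AATAAA strongest) within 30 nt
upstream of an annotated polyA site. Datasets are combined with the
square-root-of-n weighted Z method, `z_meta = Σ√nᵢ·zᵢ / √Σnᵢ`.

A first-class synthetic-data generator reproduces the structure such
cohorts exhibit (94 samples, LD-blocked genotypes, negative-binomial
counts, dominating hemoglobin-like tags, a latent GC factor on PC1,
planted eQTL/APA effects with a truth ledger), so the whole pipeline is
testable offline.

## Worked example

```r
library(sageqtl)

cfg  <- simulation_config(seed = 42, n_genes = 60, n_snps = 200,
                          tags_per_gene = c(2L, 3L))
ds   <- simulate_dataset(cfg)
ac   <- analysis_config()
expr <- quantile_normalize(filter_tags(ds$counts, config = ac))
res  <- permutation_fdr(ds$genotypes, expr, config = ac, seed = 1)
res$fdr_result
#> $p_threshold        0.0001206109
#> $n_real_significant 71
#> $mean_null_significant 1.4
#> $fdr                0.01971831
```

71 of the tags carry an FDR-significant cis-eQTL at the chosen p
threshold; on average 1.4 null features pass it per permutation, an
achieved FDR of about 2%. The per-feature best associations look like:

```r
head(res$best[res$best$significant, ], 3)
#>       snp_id     feature_id        rho            p         z
#> 748 snp00010 tag_gene0004_1  0.8141284 1.942613e-23  9.975936
#> 750 snp00010 tag_gene0004_3 -0.7796670 2.095396e-20 -9.257365
#> 838 snp00011 tag_gene0005_1  0.7427733 1.037418e-17  8.569715
```

Note gene0004: the same locus drives one of its tags *up* (z ≈ +10) and
another *down* (z ≈ −9.3) — the APA switch signature. The detector
confirms it:

```r
t2g <- tags_to_genes(expr$features, ds$annotation)
ev  <- detect_opposite_strict(res$records, t2g, ac)
ev[1, c("gene_id", "snp_id", "tag_up", "tag_down", "z_up", "z_down", "diff_p")]
#>    gene_id   snp_id         tag_up       tag_down     z_up    z_down       diff_p
#> 1 gene0004 snp00006 tag_gene0004_1 tag_gene0004_3 9.329104 -8.834214 3.034815e-43
```

(27 unique genes carry strict events in this run; 30 switches were
planted.) Finally, the motif scanner reproduces a published-style
allele swap from its hexamers alone — a non-canonical AATGAA turned
into canonical AATAAA, 15 nt upstream of a polyA site:

```r
swap_signal_call("AATGAA", "AATAAA", 15L)$event
#> "formation"        # predicted effect: 3'-UTR shortening
```

## Command line

```sh
Rscript inst/scripts/sageqtl simulate  --config cfg.json --out DIR --seed 5
Rscript inst/scripts/sageqtl normalize --counts DIR/counts.tsv --out expr.tsv
Rscript inst/scripts/sageqtl map-eqtl  --geno DIR/genotypes.tsv --expr expr.tsv \
                                       --perms 10 --fdr 0.05 --seed 1 --out eqtls.tsv
```

Subcommands: `simulate`, `normalize`, `pca`, `map-eqtl`, `apa`,
`polyasignal`, `meta`, `annotate-tags`.

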