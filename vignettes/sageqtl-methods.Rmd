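---
title: "Methods: tag-based cis-eQTL and alternative-polyadenylation QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based cis-eQTL and alternative-polyadenylation QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sageqtl)
```

## The problem

Tag-based 3'-end expression sequencing (SAGE/DeepSAGE) counts one 21-bp
tag ("CATG" + 17 nt, anchored at the transcript's 3'-most NlaIII site)
per transcript 3' end. Because distinct tags of one gene mark distinct
polyadenylation sites, a SNP that *raises* one tag while *lowering*
another tag of the same gene behaves like a switch between transcript
isoforms with different 3'-UTRs — a genotype-dependent alternative
polyadenylation (APA) event. `sageqtl` implements the full analysis
path: tag filtering and normalization, principal-component confounder
removal, cis-window Spearman association with permutation-based
tag-level FDR control, opposite-direction APA detection and
classification, allele-swap polyadenylation-signal motif scanning, and
weighted Z-score meta-analysis across sequencing-based datasets. A
synthetic-data generator reproduces the statistical structure such
cohorts exhibit, so every stage is testable without access to any
cohort.

## The association model

For each SNP--feature pair on the same chromosome with
$|pos_{SNP} - \lfloor (start+end)/2 \rfloor| \le 250\,\mathrm{kb}$
(the window boundary is inclusive; 250 kb is the conventional span of a
linkage region), the alt-allele dosage $g \in \{0,1,2\}$ is tested
against expression by the tie-corrected Spearman rank correlation
$\rho$, i.e. the Pearson correlation of average ranks. The two-sided
p-value uses the $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, $t \sim t_{n-2}$, and the signed
normal deviate is $z = \mathrm{sign}(\rho)\,\Phi^{-1}(1 - p/2)$,
expressed with respect to the assessed (alt) allele. p-values are
floored at the smallest positive double so $z$ stays finite.

Because Spearman's statistic depends only on ranks, any strictly
monotone transform of expression (for instance $\log_2(x+1)$) leaves
$\rho$ unchanged; this is asserted by tests rather than assumed.

### Tag-level FDR

Feature-level multiple-testing control uses each feature's minimum
p-value over its cis SNPs, compared against a permutation null: the
expression matrix's sample labels are shuffled (one shuffle per
permutation, shared by all features), which breaks genotype--expression
links while preserving LD structure and the expression covariance. With
10 permutations,

$$\mathrm{FDR}(t) = \frac{\frac{1}{B}\sum_b \#\{\text{null features with } p_{min} \le t\}}{\#\{\text{real features with } p_{min} \le t\}},$$

and the chosen threshold is the largest observed $t$ with
$\mathrm{FDR}(t) \le 0.05$. When no threshold qualifies, nothing is
flagged.

## Normalization and confounder removal

* **Presence filter.** A tag is kept when its count is non-zero in
  *strictly more than* 90% of samples; "present" means count > 0 (raw
  counts, before normalization).
* **CATG-anchor SNPs.** A SNP inside the strand-aware 4-bp CATG anchor
  of a tag can relocate the tag; such tags are removed and the
  transcripts containing them are flagged for exclusion from
  transcript-level summaries.
* **Quantile normalization** forces every sample onto the across-sample
  mean of sorted vectors. Tied values receive the mean of the reference
  values their ranks span; consequently the sorted-vector identity is
  exact only for tie-free data — with ties the tie policy takes
  precedence (the same behaviour as `limma::normalizeQuantiles`).
* **PCA.** After $\log_2(x+1)$, centering and scaling per tag, PCA is
  performed on the *sample* correlation matrix (eigendecomposition of
  the $n \times n$ Pearson correlation of samples, matching the
  "eigenvector coefficients" convention), with each component's sign
  fixed so its largest-magnitude coefficient is positive. Leading
  components track technical and physiological variability — in the
  synthetic data, a latent per-sample GC factor loads on PC1 with
  $|r| > 0.9$. Residualizing each feature on the first $k$ components
  (ordinary least squares with intercept) leaves residuals orthogonal
  to the removed components and is idempotent. The number of components
  to remove is a configuration parameter (`n_pcs_remove`); no universal
  default is asserted, and `sweep_pc_removal()` maps eQTL yield against
  $k$ so users can pick the argmax for their data.

## APA detection

Within each (SNP, gene) group of tested tags:

* **Strict mode** requires at least two FDR-significant tags with
  opposite $z$ signs, each with association $p < 10^{-7}$ (the
  threshold is applied per tag; configurable).
* **Permissive mode** requires only one FDR-significant tag; it is
  paired with every other *tested* tag of the same gene and SNP, and an
  event is emitted when the signs are opposite and the difference
  between the two correlations is significant at $10^{-7}$.

The differential correlation test uses the Fisher transform
$z_i = \operatorname{atanh}(\rho_i)$ and the two-sample statistic
$(z_1 - z_2)/\sqrt{2/(n-3)}$ with a two-sided normal p-value. Treating
the correlations as independent is conservative here; a
dependent-correlations variant (Steiger's shared-variable form, which
additionally needs the correlation between the two expression vectors)
is available via `analysis_config(diffcorr_method = "dependent")`. The
$1/(n-3)$ variance is the standard approximation and is documented as
approximate for rank correlations.

Events are classified against transcript models: both tags in one
annotated 3'-UTR interval → `same_3utr_apa`; both in one terminal exon
→ `same_last_exon_apa`; otherwise `different_last_exon` (alternative
last exons / splicing); a tag outside exon models is `unresolved`.

As a negative control, `permutation_null_check()` shuffles the
expression labels, takes the same number of top feature--SNP hits
(ranked by minimum p; default 50) as the real analysis investigated,
and reruns permissive detection: on null data, zero events are expected
at the $10^{-7}$ threshold across 10 runs.

`proximal_distal_ratio()` supports the read-coverage validation route:
counts in the proximal and distal 3'-UTR regions are normalized by
region length and their per-sample ratio is associated with dosage by
Spearman; the ratio is undefined (and excluded pairwise) when the
distal density is zero.

## PolyA-signal motif scanning

The motif catalog is the 13-signal list AATAAA, ATTAAA, TATAAA, AGTAAA,
AAGAAA, AATATA, AATACA, CATAAA, GATAA, AATGAA, TTTAAA, ACTAAA, AATAGA,
ranked AATAAA (canonical, strongest) > ATTAAA > all others. GATAA is a
5-mer in the printed list where every other entry is a hexamer — almost
certainly a typo for GATAAA; it is implemented exactly as printed, with
`analysis_config(fix_gataa = TRUE)` switching to GATAAA.

For each query SNP, LD proxies ($r^2 \ge 0.8$ as squared Pearson dosage
correlation, within 250 kb) located inside the cis-regulated gene are
scanned: the strand-specific context ±5 nt around the SNP is extracted
(reverse-complemented with complemented alleles for minus-strand
genes), and every motif frame overlapping the SNP is compared between
the reference and alternative contexts. A motif present — or strictly
stronger by canonical rank — in the alternative context is a
*formation*; present in the reference but absent or weaker in the
alternative, a *disruption*. A canonical-rank strengthening (e.g.
AGTAAA → AATAAA) counts as formation even though both alleles match
some motif, since the published examples are exactly such cases. The
motif only counts as a true signal when its 3' end lies within 30 nt
*upstream* of a polyA site on the transcribed strand (distance measured
motif-3'-end → cleavage site; events never fire when the motif is
downstream of the site). The predicted 3'-UTR effect is *shortening*
when a formed signal is proximal to a more distal annotated site, or
when a disrupted distal signal forces a proximal site;
`confirm_tag_ratio()` checks the prediction against per-sample
proximal/distal tag-count ratios (pseudocount-stabilized).

With the default flank of 5 nt, every hexamer frame in the 11-nt
context necessarily overlaps the SNP; for larger flanks only
SNP-overlapping frames are compared, so pre-existing motifs elsewhere
in the window can never produce a call.

## Meta-analysis

Signed z-scores are first harmonized to one assessed allele per SNP
(records assessing the other allele are negated; irreconcilable allele
sets are dropped; strand-ambiguous A/T and C/G SNPs are flagged and
excluded from combination by default, a case the combination rule
itself cannot resolve). The combined statistic is the
square-root-of-n-weighted Z:

$$z_{meta} = \frac{\sum_i \sqrt{n_i}\, z_i}{\sqrt{\sum_i n_i}},$$

which reduces to the unweighted Stouffer combination for equal $n$.
FDR control for the meta pass reuses the permutation machinery with
fresh, independent label shuffles per dataset in each permutation,
combined with the same weights, which keeps the null honest across
platforms.

## The synthetic-data generator

The generator's defaults describe the cohort structure this kind of
study reports: 94 samples; biallelic SNPs in LD blocks of 5
(block-shared latent haplotypes with a 0.5% per-allele flip rate,
giving within-block $r^2 \approx 0.9$); per-SNP MAF in [0.1, 0.5];
negative-binomial tag counts (dispersion 0.2; the paper-style tag data
are overdispersed counts and NB with a log link is the standard choice)
around
$\exp(b_t + \beta(g - \bar g) + \gamma\, G_s\, \ell_t + L_s)$ with
log-normal baselines, a per-sample log library-size factor of SD 0.5
(heavy library-size variation), three dominating hemoglobin-like tags
(baseline $4 \times 10^4$ counts, emulating HBA1/HBA2/HBB dominance),
and a latent standard-normal GC factor $G_s$ whose per-tag loading
$\ell_t$ is the centered GC fraction of the tag's own sequence, scaled
by $\gamma = 2$ — chosen once so that PC1 of the normalized expression
tracks the GC factor (the confounder structure the PCA stage must
remove; $|r| > 0.9$ in practice, comfortably above the stated
$|r| > 0.5$ property). Planted cis-eQTLs shift one tag of a gene by
$\beta = 1.5$ per alt allele (the worked-example effect size); planted
APA switches give the proximal tag $+|\beta|$ and the distal tag
$-|\beta|$ for the same SNP, i.e. the alt allele favours the proximal
site. Genes sit on one synthetic chromosome in fixed 8-kb footprints
(two exons; tags in the 3'-UTR portion of the terminal exon, proximal →
distal in transcription order, one polyA site at each tag's 3' end);
minus-strand genes are included so strand-aware extraction is
exercised; LINE/SINE/LTR intervals occupy intergenic gaps with a few
intergenic tags inside them. All internal coordinates are 0-based
half-open; conversion happens only at the I/O boundary (GFF3 and VCF
are 1-based, BED is 0-based half-open).

The genome simulator writes a background sequence scrubbed of all 13
motifs on both strands by rejection resampling, then plants formation
SNPs (a non-canonical hexamer whose alternative allele yields AATAAA,
10–28 nt upstream of a proximal polyA site of a multi-site gene) and
disruption SNPs (AATAAA → AAAAAA upstream of a distal site).

What a green test does *not* establish: the generator has no population
structure beyond simple LD blocks, no read-level errors or mapping
ambiguity, no correlated gene networks, and tag sequences are
independent of the genome sequence; real cohort effect sizes span a
spectrum rather than one planted value, so the recovery sensitivities
reported by the acceptance script characterize the stated
worked-example world, not any real cohort's yield. Recovery
denominators count planted tags/pairs that survive the presence filter:
a tag the stated pipeline removes before testing cannot be recovered by
it.

## Numerical choices and degenerate inputs

* Spearman p-values are floored at `.Machine$double.xmin`; perfect
  monotone associations therefore get a finite, very large $|z|$.
* Zero-variance dosage or expression vectors yield NA records; features
  with zero variance after $\log_2$ are dropped with a warning.
* Missing dosages are dropped pairwise; a minimum of 10 non-missing
  pairs (configurable) is required per test.
* The MAF filter (default 0.05) is applied before testing, logged, and
  can be disabled (`maf_min = 0`).
* PCA eigenvalues are clipped at zero; component signs are fixed by the
  largest-magnitude coefficient.
* FDR thresholds are chosen among observed minimum p-values only; with
  an empty qualifying set the threshold is 0 (nothing significant).
* Quantile normalization of a single sample is the identity, with a
  warning.

## Known limitations

Trans-eQTL mapping, conditional/secondary signals, read alignment,
imputation and microarray preprocessing are out of scope. The
cleavage-site (CA dinucleotide) route for causal polyA SNPs is reported
only as position overlap, reflecting that signal-motif changes — not
cleavage-site changes — are where the evidence concentrates. Replication
across datasets requires shared SNP and feature id spaces or a caller-
supplied mapping.
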