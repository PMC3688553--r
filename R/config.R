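#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated list.
#' Defaults follow the conventions of tag-based blood eQTL studies: a
#' 250 kb cis window around the feature midpoint, tag-level FDR controlled
#' at 0.05 with 10 sample-label permutations, a tag presence requirement of
#' strictly more than 90% of samples, a differential-correlation threshold
#' of 1e-7 for permissive opposite-direction (APA) calls, LD proxies at
#' r-squared >= 0.8, polyadenylation-signal motifs accepted only within
#' 30 nt upstream of an annotated polyA site, a 5 nt strand-specific
#' context flank around each SNP, and exclusion of the 20 most abundant
#' tags from per-sample GC estimates.
#'
#' @param cis_window_bp cis window half-width in bp (SNP to feature midpoint).
#' @param fdr target false discovery rate for tag-level significance.
#' @param n_permutations number of sample-label permutations for the null.
#' @param presence_fraction a tag must be non-zero in strictly more than
#'   this fraction of samples to be kept.
#' @param diffcorr_p_threshold p-value threshold for the differential
#'   correlation test in permissive APA detection.
#' @param strict_p_threshold per-tag association p-value required of both
#'   tags in strict APA mode.
#' @param ld_r2_min minimum r-squared for LD proxy expansion.
#' @param ld_window_bp maximum distance between query and proxy SNP.
#' @param motif_max_dist_nt maximum distance (nt) from a motif 3' end to a
#'   polyA site for the motif to count as a true polyadenylation signal.
#' @param context_flank_nt flank (nt) extracted on each side of a SNP for
#'   motif scanning.
#' @param gc_exclude_top number of most abundant tags excluded per sample
#'   before GC content estimation.
#' @param maf_min minor allele frequency filter applied before association
#'   testing; set to 0 to disable.
#' @param n_pcs_remove number of leading principal components residualized
#'   out of the expression matrix (0 = no correction).
#' @param log2_pseudocount pseudocount used by [log2_center_scale()].
#' @param min_samples minimum number of non-missing sample pairs required
#'   to test an association.
#' @param fix_gataa treat the 5-mer catalog entry GATAA as GATAAA.
#' @param diffcorr_method "independent" (default) or "dependent" form of
#'   the Fisher r-to-z differential correlation test.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cis_window_bp = 250000L,
                            fdr = 0.05,
                            n_permutations = 10L,
                            presence_fraction = 0.90,
                            diffcorr_p_threshold = 1e-7,
                            strict_p_threshold = 1e-7,
                            ld_r2_min = 0.8,
                            ld_window_bp = 250000L,
                            motif_max_dist_nt = 30L,
                            context_flank_nt = 5L,
                            gc_exclude_top = 20L,
                            maf_min = 0.05,
                            n_pcs_remove = 0L,
                            log2_pseudocount = 1,
                            min_samples = 10L,
                            fix_gataa = FALSE,
                            diffcorr_method = c("independent", "dependent")) {
  cfg <- list(
    cis_window_bp = as.integer(cis_window_bp),
    fdr = fdr,
    n_permutations = as.integer(n_permutations),
    presence_fraction = presence_fraction,
    diffcorr_p_threshold = diffcorr_p_threshold,
    strict_p_threshold = strict_p_threshold,
    ld_r2_min = ld_r2_min,
    ld_window_bp = as.integer(ld_window_bp),
    motif_max_dist_nt = as.integer(motif_max_dist_nt),
    context_flank_nt = as.integer(context_flank_nt),
    gc_exclude_top = as.integer(gc_exclude_top),
    maf_min = maf_min,
    n_pcs_remove = as.integer(n_pcs_remove),
    log2_pseudocount = log2_pseudocount,
    min_samples = as.integer(min_samples),
    fix_gataa = isTRUE(fix_gataa),
    diffcorr_method = match.arg(diffcorr_method)
  )
  stopifnot(
    cfg$cis_window_bp >= 0,
    cfg$fdr > 0, cfg$fdr < 1,
    cfg$n_permutations >= 1,
    cfg$presence_fraction >= 0, cfg$presence_fraction <= 1,
    cfg$diffcorr_p_threshold > 0, cfg$diffcorr_p_threshold <= 1,
    cfg$ld_r2_min >= 0, cfg$ld_r2_min <= 1,
    cfg$motif_max_dist_nt >= 1,
    cfg$context_flank_nt >= 1,
    cfg$gc_exclude_top >= 0,
    cfg$maf_min >= 0, cfg$maf_min < 0.5,
    cfg$n_pcs_remove >= 0,
    cfg$log2_pseudocount >= 0,
    cfg$min_samples >= 4
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  Defaults describe a
#' DeepSAGE-like blood cohort: 94 samples, biallelic SNPs in LD blocks,
#' negative-binomial tag counts with heavy library-size variation, a
#' handful of dominating hemoglobin-like tags, a latent per-sample GC
#' factor loading on the first expression principal component, planted
#' cis-eQTL effects around |beta| = 1.5 on the log scale, and planted
#' alternative-polyadenylation switches (two tags of one gene with
#' opposite allelic effects).
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes on the synthetic chromosome.
#' @param tags_per_gene integer range `c(min, max)` of tags per gene.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param ld_block_size number of consecutive SNPs sharing a latent
#'   haplotype (1 = independent SNPs).
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson limit).
#' @param library_size_log_sd standard deviation of the per-sample log
#'   library-size factor.
#' @param n_dominant_tags number of hemoglobin-like dominating tags.
#' @param gc_factor_sd scale of the latent per-sample GC confounder.
#' @param eqtl_effect_sizes effect sizes (per-allele shift of latent
#'   log-expression) sampled for planted eQTLs.
#' @param eqtl_fraction fraction of genes receiving a planted cis-eQTL.
#' @param apa_switch_fraction fraction of multi-tag genes receiving a
#'   planted APA switch (opposite effects on proximal/distal tags).
#' @param n_polya_formation,n_polya_disruption planted polyA-signal
#'   formation / disruption SNPs for the sequence simulator.
#' @param seed integer seed controlling all randomness of the generator.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 94L,
                              n_genes = 100L,
                              tags_per_gene = c(1L, 3L),
                              n_snps = 300L,
                              maf_range = c(0.1, 0.5),
                              ld_block_size = 5L,
                              nb_dispersion = 0.2,
                              library_size_log_sd = 0.5,
                              n_dominant_tags = 3L,
                              gc_factor_sd = 2,
                              eqtl_effect_sizes = c(1.5),
                              eqtl_fraction = 0.3,
                              apa_switch_fraction = 0.5,
                              n_polya_formation = 2L,
                              n_polya_disruption = 1L,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    tags_per_gene = as.integer(tags_per_gene),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size),
    nb_dispersion = as.numeric(nb_dispersion),
    library_size_log_sd = as.numeric(library_size_log_sd),
    n_dominant_tags = as.integer(n_dominant_tags),
    gc_factor_sd = as.numeric(gc_factor_sd),
    eqtl_effect_sizes = as.numeric(eqtl_effect_sizes),
    eqtl_fraction = as.numeric(eqtl_fraction),
    apa_switch_fraction = as.numeric(apa_switch_fraction),
    n_polya_formation = as.integer(n_polya_formation),
    n_polya_disruption = as.integer(n_polya_disruption),
    seed = as.integer(seed)
  )
  if (cfg$n_samples < 1 || cfg$n_genes < 1 || cfg$n_snps < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (length(cfg$tags_per_gene) != 2L || any(cfg$tags_per_gene < 1L) ||
      cfg$tags_per_gene[1] > cfg$tags_per_gene[2])
    stop("tags_per_gene must be an increasing integer range >= 1",
         call. = FALSE)
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (cfg$ld_block_size < 1) stop("ld_block_size must be >= 1", call. = FALSE)
  if (cfg$nb_dispersion < 0 || cfg$library_size_log_sd < 0 ||
      cfg$gc_factor_sd < 0)
    stop("scale parameters must be non-negative", call. = FALSE)
  for (f in c("eqtl_fraction", "apa_switch_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be a fraction in [0,1]", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

# derive a reproducible sub-seed for a named simulation stage, kept < 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 11L, annotation = 101L, counts = 1009L,
               sequences = 10007L, permutation = 20011L, meta = 30011L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
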