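# Genotype-dependent alternative polyadenylation (APA) switches: SNPs
# that increase one tag of a gene while decreasing another act like a
# switch between transcripts with different 3' ends.

#' Map tag features to genes by containment
#'
#' @param features data.frame with `id`, `chrom`, `start`, `end`.
#' @param annotation a [genome_annotation()].
#' @return Named character vector feature id -> gene id (NA when
#'   intergenic).
#' @export
tags_to_genes <- function(features, annotation) {
  g <- annotation$genes
  mid <- floor((features$start + features$end) / 2)
  out <- rep(NA_character_, nrow(features))
  for (i in seq_len(nrow(features))) {
    gi <- which(g$chrom == features$chrom[i] & g$start <= mid[i] &
                  mid[i] < g$end)
    if (length(gi)) out[i] <- g$gene_id[gi[1]]
  }
  stats::setNames(out, features$id)
}

#' Difference between two correlation coefficients
#'
#' Fisher r-to-z test for the difference between two correlations
#' estimated on the same n samples.  The default `independent` form uses
#' the statistic `(atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))` with a
#' two-sided normal p-value.  The `dependent` form (Steiger's test for
#' correlations sharing one variable, here the genotype) additionally
#' needs `r12`, the correlation between the two expression vectors.
#'
#' @param rho_1,rho_2 correlation coefficients, |rho| < 1.
#' @param n sample size (> 3).
#' @param method "independent" (default) or "dependent".
#' @param r12 correlation between the two outcome vectors (dependent
#'   form only).
#' @return Two-sided p-value.
#' @export
diff_correlation_test <- function(rho_1, rho_2, n,
                                  method = c("independent", "dependent"),
                                  r12 = NULL) {
  method <- match.arg(method)
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(rho_1, rho_2)) >= 1)) stop("|rho| must be < 1")
  z1 <- atanh(rho_1); z2 <- atanh(rho_2)
  if (method == "independent") {
    stat <- (z1 - z2) / sqrt(2 / (n - 3))
  } else {
    if (is.null(r12)) stop("dependent form requires r12")
    rm2 <- (rho_1^2 + rho_2^2) / 2
    f <- min((1 - r12) / (2 * (1 - rm2)), 1)
    h <- (1 - f * rm2) / (1 - rm2)
    stat <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  }
  max(2 * stats::pnorm(abs(stat), lower.tail = FALSE),
      .Machine$double.xmin)
}

# build APA events from a record table: one row per opposite-sign tag
# pair of a gene sharing a SNP
build_events <- function(pairs_df, mode) {
  if (!nrow(pairs_df))
    return(data.frame(gene_id = character(), snp_id = character(),
                      tag_up = character(), tag_down = character(),
                      rho_up = numeric(), rho_down = numeric(),
                      z_up = numeric(), z_down = numeric(),
                      diff_p = numeric(), mode = character(),
                      stringsAsFactors = FALSE))
  pairs_df$mode <- mode
  pairs_df
}

apa_scan <- function(records, tag2gene, config, strict) {
  rec <- records
  rec$gene_id <- unname(tag2gene[rec$feature_id])
  rec <- rec[!is.na(rec$gene_id) & !is.na(rec$z), , drop = FALSE]
  out <- list()
  for (key in unique(paste(rec$snp_id, rec$gene_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    grp <- rec[rec$snp_id == parts[1] & rec$gene_id == parts[2], ,
               drop = FALSE]
    if (nrow(grp) < 2) next
    n <- grp$n_used[1]
    if (strict) {
      cand <- grp[grp$significant %in% TRUE &
                    grp$p < config$strict_p_threshold, , drop = FALSE]
      if (nrow(cand) < 2) next
      up <- cand[cand$z > 0, , drop = FALSE]
      dn <- cand[cand$z < 0, , drop = FALSE]
      for (i in seq_len(nrow(up))) for (j in seq_len(nrow(dn))) {
        dp <- diff_correlation_test(up$rho[i], dn$rho[j], n,
                                    method = config$diffcorr_method)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = parts[2], snp_id = parts[1],
          tag_up = up$feature_id[i], tag_down = dn$feature_id[j],
          rho_up = up$rho[i], rho_down = dn$rho[j],
          z_up = up$z[i], z_down = dn$z[j], diff_p = dp,
          stringsAsFactors = FALSE)
      }
    } else {
      sig <- grp[grp$significant %in% TRUE, , drop = FALSE]
      if (!nrow(sig)) next
      for (i in seq_len(nrow(sig))) {
        partners <- grp[grp$feature_id != sig$feature_id[i] &
                          sign(grp$z) == -sign(sig$z[i]), , drop = FALSE]
        for (j in seq_len(nrow(partners))) {
          dp <- diff_correlation_test(sig$rho[i], partners$rho[j], n,
                                      method = config$diffcorr_method)
          if (dp >= config$diffcorr_p_threshold) next
          a <- sig[i, ]; b <- partners[j, ]
          if (a$z < 0) { tmp <- a; a <- b; b <- tmp }
          out[[length(out) + 1L]] <- data.frame(
            gene_id = parts[2], snp_id = parts[1],
            tag_up = a$feature_id, tag_down = b$feature_id,
            rho_up = a$rho, rho_down = b$rho,
            z_up = a$z, z_down = b$z, diff_p = dp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  ev <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame()
  build_events(ev, if (strict) "strict" else "permissive")
}

#' Strict opposite-direction APA detection
#'
#' Emits an event for each SNP with at least two FDR-significant tags in
#' one gene showing opposite z signs, both passing the strict per-tag
#' p-value threshold (default 1e-7).
#'
#' @param records eQTL records carrying `significant` flags (e.g.
#'   `permutation_fdr(...)$records`).
#' @param tag2gene named feature-to-gene map from [tags_to_genes()].
#' @param config an [analysis_config()].
#' @return data.frame of APA events (`mode = "strict"`).
#' @export
detect_opposite_strict <- function(records, tag2gene,
                                   config = analysis_config()) {
  apa_scan(records, tag2gene, config, strict = TRUE)
}

#' Permissive opposite-direction APA detection
#'
#' Requires only one FDR-significant tag per gene; each is paired with
#' every other tested tag of the same gene and SNP, and an event is
#' emitted when the signs are opposite and the differential correlation
#' test is below `diffcorr_p_threshold` (default 1e-7).
#'
#' @inheritParams detect_opposite_strict
#' @return data.frame of APA events (`mode = "permissive"`).
#' @export
detect_opposite_permissive <- function(records, tag2gene,
                                       config = analysis_config()) {
  apa_scan(records, tag2gene, config, strict = FALSE)
}

#' Classify an APA event against transcript models
#'
#' Both tags in one annotated 3'-UTR means a polyadenylation-site
#' switch (`same_3utr_apa`); both in one terminal exon (but not one
#' UTR interval) is `same_last_exon_apa`; tags in exons of different
#' terminal exons indicate alternative last exons / splicing
#' (`different_last_exon`); a tag outside exon models gives
#' `unresolved`.
#'
#' @param event one row of the event table from the detect functions.
#' @param features feature coordinates data.frame (`id`, `chrom`,
#'   `start`, `end`).
#' @param annotation a [genome_annotation()].
#' @return classification string.
#' @export
classify_event <- function(event, features, annotation) {
  locate <- function(tag_id) {
    f <- features[features$id == tag_id, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    mid <- floor((f$start + f$end) / 2)
    u <- annotation$utr3
    utr <- which(u$chrom == f$chrom & u$start <= mid & mid < u$end)
    e <- annotation$exons
    ex <- which(e$chrom == f$chrom & e$start <= mid & mid < e$end)
    # terminal exon = max rank within its transcript
    last <- vapply(ex, function(i) {
      et <- e[e$transcript_id == e$transcript_id[i], ]
      e$rank[i] == max(et$rank)
    }, logical(1))
    list(utr = utr, exon = ex, last_exon = ex[last])
  }
  a <- locate(event$tag_up); b <- locate(event$tag_down)
  if (is.null(a) || is.null(b)) return("unresolved")
  if (length(intersect(a$utr, b$utr))) return("same_3utr_apa")
  if (length(intersect(a$last_exon, b$last_exon)))
    return("same_last_exon_apa")
  if (!length(a$exon) || !length(b$exon)) {
    warning("tag outside exon models: classification unresolved")
    return("unresolved")
  }
  if (length(a$last_exon) && length(b$last_exon))
    return("different_last_exon")
  "different_last_exon"
}

#' Permutation robustness check for APA detection
#'
#' Shuffles the expression sample labels, reruns the cis scan, takes the
#' same number of top features (ranked by minimum p) as were
#' investigated in the real analysis, and runs permissive detection on
#' them.  On null data no SNP should affect two tags of one gene in a
#' significantly different way at the 1e-7 differential correlation
#' threshold.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expr expression matrix as used for mapping.
#' @param features feature coordinates.
#' @param tag2gene named feature-to-gene map.
#' @param config an [analysis_config()].
#' @param n_runs number of shuffled runs (default 10).
#' @param n_top number of top features treated as "hits" per run.
#' @param seed integer seed.
#' @return integer vector of event counts, one per run.
#' @export
permutation_null_check <- function(genotypes, expr, features, tag2gene,
                                   config = analysis_config(),
                                   n_runs = 10L, n_top = 50L, seed = 1L) {
  prep <- prepare_assoc(genotypes, expr, features, config)
  prep$pairs$snp_idx_local <- match(prep$pairs$snp_id, prep$snps$id)
  set.seed(stage_seed(seed, "permutation"))
  n <- length(prep$samples)
  counts <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    perm <- sample.int(n)
    a <- assoc_all_pairs(prep, perm = perm)
    p <- p_from_rho(a$rho, a$n)
    z <- sign(a$rho) * stats::qnorm(p / 2, lower.tail = FALSE)
    rec <- data.frame(snp_id = prep$pairs$snp_id,
                      feature_id = prep$pairs$feature_id,
                      n_used = a$n, rho = a$rho, p = p, z = z,
                      stringsAsFactors = FALSE)
    rec <- rec[!is.na(rec$rho), , drop = FALSE]
    best <- rec[order(rec$p), , drop = FALSE]
    best <- best[!duplicated(best$feature_id), , drop = FALSE]
    top_feats <- utils::head(best$feature_id, n_top)
    top_pairs <- paste(utils::head(best$snp_id, n_top), top_feats)
    rec$significant <- paste(rec$snp_id, rec$feature_id) %in% top_pairs
    ev <- detect_opposite_permissive(rec, tag2gene, config)
    counts[r] <- nrow(ev)
  }
  counts
}

#' Proximal/distal region density ratio
#'
#' Length-normalized tag-count densities in a proximal and a distal
#' 3'-UTR region, and their per-sample ratio.  The ratio is flagged
#' undefined when the distal density is zero.
#'
#' @param counts a [tag_counts()].
#' @param chrom chromosome of both regions.
#' @param proximal_region,distal_region numeric `c(start, end)` 0-based
#'   half-open intervals; must be disjoint.
#' @return data.frame with `sample_id`, `proximal_density`,
#'   `distal_density`, `ratio`, `defined`.
#' @export
proximal_distal_ratio <- function(counts, chrom, proximal_region,
                                  distal_region) {
  stopifnot(inherits(counts, "tag_counts"))
  if (max(proximal_region[1], distal_region[1]) <
      min(proximal_region[2], distal_region[2]))
    stop("proximal and distal regions must be disjoint")
  mid <- floor((counts$tags$start + counts$tags$end) / 2)
  in_region <- function(reg)
    which(counts$tags$chrom == chrom & mid >= reg[1] & mid < reg[2])
  pi <- in_region(proximal_region); di <- in_region(distal_region)
  psum <- if (length(pi)) rowSums(counts$counts[, pi, drop = FALSE]) else 0
  dsum <- if (length(di)) rowSums(counts$counts[, di, drop = FALSE]) else 0
  pd <- psum / (proximal_region[2] - proximal_region[1])
  dd <- dsum / (distal_region[2] - distal_region[1])
  data.frame(sample_id = counts$sample_ids,
             proximal_density = pd, distal_density = dd,
             ratio = ifelse(dd > 0, pd / dd, NA_real_),
             defined = dd > 0, stringsAsFactors = FALSE)
}

#' Associate a proximal/distal ratio with genotype
#'
#' Spearman correlation between per-sample ratios and dosage, dropping
#' samples with an undefined ratio pairwise.
#'
#' @param ratios output of [proximal_distal_ratio()].
#' @param dosage named (or aligned) dosage vector.
#' @return list with `rho` and `p`.
#' @export
ratio_genotype_assoc <- function(ratios, dosage) {
  if (!is.null(names(dosage))) dosage <- dosage[ratios$sample_id]
  a <- spearman_assoc(dosage, ratios$ratio, min_samples = 4L)
  list(rho = a$rho, p = a$p)
}
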