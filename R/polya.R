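# Allele-swap polyadenylation-signal scanning.
#
# A polyadenylation signal is a hexameric motif (canonical AATAAA,
# ATTAAA, or one of the weaker non-canonical variants) located 10-30 nt
# upstream of the cleavage site.  A SNP can create a signal (formation:
# the alternative allele turns a non-canonical or absent motif into a
# canonical one) or destroy one (disruption).  Candidate causal SNPs are
# expanded through LD proxies before scanning.

#' Polyadenylation-signal motif catalog
#'
#' The 13 canonical and non-canonical signals, ranked by strength:
#' AATAAA (rank 1) > ATTAAA (rank 2) > all others (rank 3).  The entry
#' GATAA is a 5-mer as conventionally listed; `fix_gataa = TRUE`
#' replaces it with GATAAA.
#'
#' @param fix_gataa treat GATAA as the hexamer GATAAA.
#' @return list with `motifs` (character vector) and `canonical_rank`.
#' @export
polya_motif_catalog <- function(fix_gataa = FALSE) {
  motifs <- c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
              "AATACA", "CATAAA", "GATAA", "AATGAA", "TTTAAA", "ACTAAA",
              "AATAGA")
  if (fix_gataa) motifs[motifs == "GATAA"] <- "GATAAA"
  rank <- ifelse(motifs == "AATAAA", 1L,
                 ifelse(motifs == "ATTAAA", 2L, 3L))
  list(motifs = motifs, canonical_rank = stats::setNames(rank, motifs))
}

#' LD proxies of a query SNP
#'
#' All SNPs with squared Pearson dosage correlation `>= ld_r2_min` to
#' the query within `ld_window_bp` (pairwise-complete); the query itself
#' is included with r-squared 1.
#'
#' @param genotypes a [genotype_matrix()].
#' @param query_snp SNP id.
#' @param config an [analysis_config()].
#' @return data.frame with `snp_id`, `r2`, `pos`, `ref`, `alt`.
#' @export
ld_proxies <- function(genotypes, query_snp, config = analysis_config()) {
  qi <- match(query_snp, genotypes$snps$id)
  if (is.na(qi)) stop("query SNP not found: ", query_snp)
  q <- genotypes$dosages[, qi]
  if (stats::sd(q, na.rm = TRUE) == 0 || all(is.na(q))) {
    warning("monomorphic query SNP: no proxies")
    return(data.frame(snp_id = character(), r2 = numeric(),
                      pos = integer(), ref = character(),
                      alt = character()))
  }
  s <- genotypes$snps
  near <- which(s$chrom == s$chrom[qi] &
                  abs(s$pos - s$pos[qi]) <= config$ld_window_bp)
  r2 <- vapply(near, function(j) {
    r <- suppressWarnings(stats::cor(q, genotypes$dosages[, j],
                                     use = "pairwise.complete.obs"))
    if (is.na(r)) NA_real_ else r^2
  }, numeric(1))
  keep <- !is.na(r2) & (r2 >= config$ld_r2_min | near == qi)
  out <- data.frame(snp_id = s$id[near][keep], r2 = r2[keep],
                    pos = s$pos[near][keep], ref = s$ref[near][keep],
                    alt = s$alt[near][keep], stringsAsFactors = FALSE)
  out$r2[out$snp_id == query_snp] <- 1
  out[order(-out$r2), , drop = FALSE]
}

#' Filter proxy SNPs to those inside a gene span
#'
#' @param proxies data.frame with `snp_id` and `pos` (1-based).
#' @param gene_id gene to intersect with.
#' @param annotation a [genome_annotation()].
#' @return Filtered proxies.
#' @export
snps_in_gene <- function(proxies, gene_id, annotation) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g) || !nrow(proxies)) return(proxies[0, , drop = FALSE])
  inside <- (proxies$pos - 1L) >= g$start & (proxies$pos - 1L) < g$end
  proxies[inside, , drop = FALSE]
}

#' Extract the strand-specific context around a SNP
#'
#' Returns the `2 * flank + 1` nt sequence on the transcribed strand
#' centered on the SNP (reverse-complemented for minus-strand genes,
#' with alleles complemented accordingly), for both the reference and
#' the alternative allele.
#'
#' @param genome a named `Biostrings::DNAStringSet` (or character
#'   vector of sequences).
#' @param chrom chromosome name.
#' @param pos SNP position, 1-based.
#' @param ref,alt alleles on the reference (genomic plus) strand.
#' @param strand transcribed strand, "+" or "-".
#' @param flank context flank in nt (default 5).
#' @return list with `ref_context` and `alt_context` (character).
#' @export
extract_context <- function(genome, chrom, pos, ref, alt, strand,
                            flank = 5L) {
  seqs <- if (is.character(genome)) genome[[chrom]]
  else as.character(genome[[chrom]])
  if (pos - flank < 1 || pos + flank > nchar(seqs))
    stop("SNP at ", pos, " too close to the contig end for flank ", flank)
  ctx <- substr(seqs, pos - flank, pos + flank)
  center <- flank + 1L
  if (toupper(substr(ctx, center, center)) != toupper(ref))
    stop("reference base mismatch at ", chrom, ":", pos, " (genome ",
         substr(ctx, center, center), ", expected ", ref, ")")
  alt_ctx <- ctx
  substr(alt_ctx, center, center) <- alt
  if (strand == "-") {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    ctx <- rc(ctx); alt_ctx <- rc(alt_ctx)
  }
  list(ref_context = toupper(ctx), alt_context = toupper(alt_ctx))
}

# best catalog hit among motif frames overlapping the SNP (center) of a
# context; returns NULL or list(motif, rank, offset) with offset the
# 1-based start within the context
best_motif_hit <- function(context, center, catalog) {
  best <- NULL
  for (m in catalog$motifs) {
    w <- nchar(m)
    for (s in seq_len(nchar(context) - w + 1L)) {
      if (s > center || s + w - 1L < center) next   # must overlap the SNP
      if (substr(context, s, s + w - 1L) == m) {
        r <- catalog$canonical_rank[[m]]
        if (is.null(best) || r < best$rank ||
            (r == best$rank && nchar(m) > nchar(best$motif)))
          best <- list(motif = m, rank = r, offset = s)
      }
    }
  }
  best
}

#' Classify an allele swap as polyA-signal formation or disruption
#'
#' Scans every motif frame overlapping the SNP in the reference and
#' alternative transcribed-strand contexts.  A motif present (or
#' strictly stronger by canonical rank) in the alternative context is a
#' formation; one present in the reference but absent or weaker in the
#' alternative is a disruption.  The motif only counts as a true
#' polyadenylation signal when its 3' end lies within
#' `motif_max_dist_nt` upstream of a polyA site on the transcribed
#' strand.  The predicted effect on 3'-UTR length is shortening when a
#' formed signal sits proximal to a more distal annotated site, or when
#' a disrupted distal signal forces use of a proximal site.
#'
#' @param ref_context,alt_context transcribed-strand contexts from
#'   [extract_context()].
#' @param polya_sites data.frame with `pos` (0-based) and `strand` for
#'   the gene under study (additional sites inform the length
#'   prediction).
#' @param snp_pos SNP position, 1-based genomic.
#' @param strand transcribed strand of the gene.
#' @param catalog a [polya_motif_catalog()].
#' @param config an [analysis_config()].
#' @return list (class `polya_signal_event`) with `event` (formation /
#'   disruption / none), `ref_motif_hit`, `alt_motif_hit`,
#'   `distance_nt`, `predicted_effect`, `reason`.
#' @export
classify_signal_change <- function(ref_context, alt_context, polya_sites,
                                   snp_pos, strand,
                                   catalog = polya_motif_catalog(),
                                   config = analysis_config()) {
  stopifnot(nchar(ref_context) == nchar(alt_context))
  none <- function(reason)
    structure(list(event = "none", ref_motif_hit = NA_character_,
                   alt_motif_hit = NA_character_,
                   distance_nt = NA_integer_,
                   predicted_effect = "none", reason = reason),
              class = "polya_signal_event")
  if (is.null(polya_sites) || nrow(polya_sites) == 0)
    return(none("no polyA sites supplied"))
  center <- (nchar(ref_context) + 1L) %/% 2L
  hr <- best_motif_hit(ref_context, center, catalog)
  ha <- best_motif_hit(alt_context, center, catalog)
  ref_rank <- if (is.null(hr)) Inf else hr$rank
  alt_rank <- if (is.null(ha)) Inf else ha$rank
  if (is.infinite(ref_rank) && is.infinite(alt_rank))
    return(none("no motif in either allele"))
  if (alt_rank < ref_rank) { event <- "formation"; hit <- ha }
  else if (ref_rank < alt_rank) { event <- "disruption"; hit <- hr }
  else return(none("motif unchanged by allele swap"))

  # genomic position of the motif's 3'-most base on the transcribed
  # strand; context position `center` is the SNP base
  w <- nchar(hit$motif)
  if (strand == "+") {
    last0 <- (snp_pos - 1L) + (hit$offset + w - 1L - center)
  } else {
    last0 <- (snp_pos - 1L) - (hit$offset + w - 1L - center)
  }
  sites <- polya_sites[polya_sites$strand == strand, , drop = FALSE]
  dist <- if (strand == "+") sites$pos - last0 else last0 - sites$pos
  down <- which(dist > 0)                    # motif upstream of the site
  if (!length(down) || min(dist[down]) > config$motif_max_dist_nt)
    return(none("no polyA site within distance limit"))
  j <- down[which.min(dist[down])]
  affected <- sites$pos[j]
  # shortening logic relative to other annotated sites of the gene
  more_distal <- if (strand == "+") any(sites$pos > affected)
  else any(sites$pos < affected)
  more_proximal <- if (strand == "+") any(sites$pos < affected)
  else any(sites$pos > affected)
  effect <- if (event == "formation") {
    if (more_distal) "shortening" else "lengthening"
  } else {
    if (more_proximal) "shortening" else "lengthening"
  }
  structure(list(event = event,
                 ref_motif_hit = if (is.null(hr)) NA_character_
                 else hr$motif,
                 alt_motif_hit = if (is.null(ha)) NA_character_
                 else ha$motif,
                 distance_nt = as.integer(min(dist[down])),
                 predicted_effect = effect, reason = NA_character_),
            class = "polya_signal_event")
}

#' Scan query SNPs for polyA-signal changes
#'
#' End-to-end driver: expand each query SNP to its LD proxies, keep
#' proxies inside the cis-regulated gene, extract the strand-specific
#' context for each and classify the allele swap against the gene's
#' polyA sites.
#'
#' @param genotypes a [genotype_matrix()].
#' @param genome named `DNAStringSet` or character vector.
#' @param query_snps character vector of SNP ids.
#' @param gene_ids gene assigned to each query SNP (same length).
#' @param annotation a [genome_annotation()].
#' @param config an [analysis_config()].
#' @return data.frame, one row per (query, proxy) with an event call.
#' @export
scan_polya_signals <- function(genotypes, genome, query_snps, gene_ids,
                               annotation, config = analysis_config()) {
  catalog <- polya_motif_catalog(fix_gataa = config$fix_gataa)
  out <- list()
  for (i in seq_along(query_snps)) {
    prox <- ld_proxies(genotypes, query_snps[i], config)
    prox <- snps_in_gene(prox, gene_ids[i], annotation)
    g <- annotation$genes[annotation$genes$gene_id == gene_ids[i], ]
    sites <- annotation$polya_sites[
      annotation$polya_sites$gene_id == gene_ids[i], , drop = FALSE]
    for (j in seq_len(nrow(prox))) {
      ctx <- extract_context(genome, g$chrom, prox$pos[j], prox$ref[j],
                             prox$alt[j], g$strand,
                             flank = config$context_flank_nt)
      ev <- classify_signal_change(ctx$ref_context, ctx$alt_context,
                                   sites, prox$pos[j], g$strand,
                                   catalog, config)
      out[[length(out) + 1L]] <- data.frame(
        query_snp = query_snps[i], causal_snp = prox$snp_id[j],
        r2 = prox$r2[j], gene_id = gene_ids[i], strand = g$strand,
        ref_context = ctx$ref_context, alt_context = ctx$alt_context,
        ref_motif_hit = ev$ref_motif_hit,
        alt_motif_hit = ev$alt_motif_hit, event = ev$event,
        distance_nt = ev$distance_nt,
        predicted_effect = ev$predicted_effect,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(query_snp = character(), causal_snp = character(),
                      r2 = numeric(), gene_id = character(),
                      strand = character(), ref_context = character(),
                      alt_context = character(),
                      ref_motif_hit = character(),
                      alt_motif_hit = character(), event = character(),
                      distance_nt = integer(),
                      predicted_effect = character()))
  do.call(rbind, out)
}

#' Classify a single printed hexamer swap
#'
#' Builds a minimal synthetic locus for a reported polyA-signal allele
#' swap -- a transcribed-strand sequence carrying `ref_motif` whose 3'
#' end lies `distance_nt` upstream of an annotated polyA site (with one
#' additional more-proximal and one more-distal site so the 3'-UTR
#' length prediction is defined) -- and runs [classify_signal_change()]
#' on the SNP that turns `ref_motif` into `alt_motif`.  Useful to check
#' the classifier against published (reference hexamer, alternative
#' hexamer, distance) triples.
#'
#' @param ref_motif,alt_motif hexamers (or the GATAA 5-mer) differing
#'   at exactly one base.
#' @param distance_nt distance from the motif 3' end to the polyA site.
#' @param strand transcribed strand for the synthetic gene.
#' @param config an [analysis_config()].
#' @return The `polya_signal_event` from [classify_signal_change()].
#' @export
swap_signal_call <- function(ref_motif, alt_motif, distance_nt,
                             strand = "+",
                             config = analysis_config()) {
  stopifnot(nchar(ref_motif) == nchar(alt_motif))
  diff <- which(strsplit(ref_motif, "")[[1]] !=
                  strsplit(alt_motif, "")[[1]])
  if (length(diff) != 1L)
    stop("motifs must differ at exactly one base")
  w <- nchar(ref_motif)
  pad <- 60L
  # transcribed-strand sequence: C-padding avoids spurious A/T motifs
  tseq <- paste0(strrep("C", pad), ref_motif,
                 strrep("C", distance_nt + pad))
  site_t <- pad + w - 1L + distance_nt     # 0-based, transcribed coords
  snp_t <- pad + diff                      # 1-based, transcribed coords
  L <- nchar(tseq)
  if (strand == "+") {
    genome <- c(chrT = tseq)
    pos <- snp_t
    ref <- substr(ref_motif, diff, diff)
    alt <- substr(alt_motif, diff, diff)
    sites <- data.frame(pos = c(site_t, site_t - 40L, site_t + 40L),
                        strand = "+")
  } else {
    genome <- c(chrT = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tseq))))
    pos <- L - snp_t + 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- comp[[substr(ref_motif, diff, diff)]]
    alt <- comp[[substr(alt_motif, diff, diff)]]
    sites <- data.frame(pos = L - 1L - c(site_t, site_t - 40L,
                                         site_t + 40L),
                        strand = "-")
  }
  ctx <- extract_context(genome, "chrT", pos, ref, alt, strand,
                         flank = config$context_flank_nt)
  classify_signal_change(ctx$ref_context, ctx$alt_context, sites, pos,
                         strand,
                         polya_motif_catalog(fix_gataa = config$fix_gataa),
                         config)
}

#' Confirm a signal change with tag-coverage ratios
#'
#' For a called formation/disruption, computes the per-sample ratio of
#' tag counts proximal vs distal of the affected polyA site
#' (pseudocount-stabilized), associates it with dosage by Spearman, and
#' flags the event confirmed when the association direction matches the
#' predicted 3'-UTR length effect (shortening: proximal usage rises
#' with the alternative allele).
#'
#' @param event one row of [scan_polya_signals()] output (or a list
#'   with `event`, `gene_id`, `causal_snp`, `predicted_effect` and
#'   `site_pos`, the affected site's 0-based position).
#' @param counts a [tag_counts()].
#' @param genotypes a [genotype_matrix()].
#' @param annotation a [genome_annotation()].
#' @param site_pos affected polyA site (0-based); defaults to the
#'   gene's site nearest the causal SNP.
#' @return list with `rho`, `p`, `direction`, `confirmed`, `reason`.
#' @export
confirm_tag_ratio <- function(event, counts, genotypes, annotation,
                              site_pos = NULL) {
  if (identical(event$event, "none"))
    return(list(rho = NA_real_, p = NA_real_, direction = NA_character_,
                confirmed = FALSE, reason = "no event"))
  g <- annotation$genes[annotation$genes$gene_id == event$gene_id, ]
  if (is.null(site_pos)) {
    s <- annotation$polya_sites[
      annotation$polya_sites$gene_id == event$gene_id, ]
    sp <- genotypes$snps$pos[match(event$causal_snp, genotypes$snps$id)]
    site_pos <- s$pos[which.min(abs(s$pos - (sp - 1L)))]
  }
  tagi <- which(counts$tags$chrom == g$chrom &
                  counts$tags$start >= g$start &
                  counts$tags$end <= g$end)
  if (!length(tagi))
    return(list(rho = NA_real_, p = NA_real_, direction = NA_character_,
                confirmed = FALSE, reason = "no tags in gene"))
  mid <- floor((counts$tags$start[tagi] + counts$tags$end[tagi]) / 2)
  upstream <- if (g$strand == "+") mid <= site_pos else mid >= site_pos
  prox <- tagi[upstream]; dist <- tagi[!upstream]
  if (!length(prox) || !length(dist))
    return(list(rho = NA_real_, p = NA_real_, direction = NA_character_,
                confirmed = FALSE, reason = "no flanking tags"))
  ps <- rowSums(counts$counts[, prox, drop = FALSE]) + 1
  ds <- rowSums(counts$counts[, dist, drop = FALSE]) + 1
  ratio <- ps / ds
  dosage <- genotypes$dosages[counts$sample_ids,
                              match(event$causal_snp, genotypes$snps$id)]
  a <- spearman_assoc(dosage, ratio, min_samples = 4L)
  if (is.na(a$rho))
    return(list(rho = NA_real_, p = NA_real_, direction = NA_character_,
                confirmed = FALSE, reason = "association not testable"))
  direction <- if (a$rho > 0) "proximal_up_with_alt" else
    "proximal_down_with_alt"
  want_up <- identical(event$predicted_effect, "shortening")
  confirmed <- (want_up && a$rho > 0) || (!want_up && a$rho < 0)
  list(rho = a$rho, p = a$p, direction = direction,
       confirmed = confirmed, reason = NA_character_)
}
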