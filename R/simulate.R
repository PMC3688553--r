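# Synthetic-data generator.
#
# Emulates a DeepSAGE-like blood cohort: LD-blocked biallelic genotypes,
# a single synthetic chromosome with non-overlapping genes whose tags sit
# in the terminal exon / 3'-UTR (ordered proximal -> distal along the
# transcribed strand, a polyA site at each tag's 3' end), repeat elements
# in intergenic gaps, and negative-binomial tag counts driven by planted
# cis-eQTL effects, a latent per-sample GC factor, library-size variation
# and a few dominating hemoglobin-like tags.  Everything planted is
# recorded in a truth ledger.

# sample() without the scalar-x surprise
resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

GENE_PITCH <- 8000L       # fixed per-gene footprint on the chromosome
TAG_PITCH <- 300L         # spacing between consecutive tags in a 3'-UTR

chrom_name <- function(config) "chrS"
chrom_length <- function(config) config$n_genes * GENE_PITCH + 10000L

#' Simulate LD-blocked biallelic genotypes
#'
#' SNPs are laid out along the synthetic chromosome and grouped into
#' consecutive blocks of `ld_block_size`.  Within a block all SNPs share
#' latent haplotype indicators (with a small per-allele flip rate), so
#' within-block pairwise r-squared is high; SNPs in different blocks are
#' independent.  Per-SNP MAFs are drawn from `maf_range`.
#'
#' @param config a [simulation_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_samples
  m <- config$n_snps
  clen <- chrom_length(config)
  pos <- sort(sample.int(clen - 2L, m, replace = FALSE)) + 1L
  block <- (seq_len(m) - 1L) %/% config$ld_block_size
  flip <- 0.005  # per-allele flip noise; keeps within-block r2 ~ 0.9
  haps <- matrix(0L, nrow = 2L * n, ncol = m)
  for (b in unique(block)) {
    idx <- which(block == b)
    p_block <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    u <- stats::runif(2L * n)
    for (j in idx) {
      p_j <- min(max(p_block + stats::runif(1, -0.005, 0.005),
                     config$maf_range[1]), config$maf_range[2])
      a <- as.integer(u < p_j)
      do_flip <- stats::runif(2L * n) < flip
      a[do_flip] <- 1L - a[do_flip]
      haps[, j] <- a
    }
  }
  dos <- haps[seq_len(n) * 2L - 1L, , drop = FALSE] +
    haps[seq_len(n) * 2L, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  snps <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                     chrom = chrom_name(config), pos = pos,
                     ref = ref, alt = unname(alt),
                     stringsAsFactors = FALSE)
  genotype_matrix(sprintf("S%03d", seq_len(n)), snps, dos)
}

#' Simulate gene/tag/polyA/repeat annotation
#'
#' Places non-overlapping genes on one synthetic chromosome.  Each gene
#' has two exons; its tags lie in the 3'-UTR portion of the last exon,
#' ordered proximal to distal along the direction of transcription, with
#' a polyadenylation site at each tag's 3' end.  Repeat elements (LINE,
#' SINE, LTR) occupy some intergenic gaps and a few intergenic tags are
#' placed inside them.  The returned object carries the planned tag
#' layout in its `tag_layout` element (consumed by [simulate_counts()]).
#'
#' @param config a [simulation_config()].
#' @return A [genome_annotation()] with an extra `tag_layout` element.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$tags_per_gene[2] > 9L)
    stop("tags_per_gene max is 9 for the fixed gene footprint")
  set.seed(stage_seed(config$seed, "annotation"))
  ng <- config$n_genes
  chrom <- chrom_name(config)
  k <- if (config$tags_per_gene[1] == config$tags_per_gene[2])
    rep(config$tags_per_gene[1], ng)
  else sample(seq(config$tags_per_gene[1], config$tags_per_gene[2]),
              ng, replace = TRUE)
  strand <- sample(c("+", "-"), ng, replace = TRUE, prob = c(0.6, 0.4))
  biotype <- sample(c("protein_coding", "lincRNA", "antisense"),
                    ng, replace = TRUE, prob = c(0.85, 0.10, 0.05))
  utr_len <- 200L + k * TAG_PITCH
  gene_len <- 800L + 200L + utr_len      # exon1 + intron | cds2 + utr
  gstart <- (seq_len(ng) - 1L) * GENE_PITCH + 3000L
  gend <- gstart + gene_len

  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(ng)),
                      name = sprintf("G%04d", seq_len(ng)),
                      biotype = biotype, chrom = chrom,
                      start = gstart, end = gend, strand = strand,
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = sprintf("tx%04d", seq_len(ng)),
                            gene_id = genes$gene_id,
                            stringsAsFactors = FALSE)
  # two exons per transcript; "last" exon is strand-aware
  ex <- lapply(seq_len(ng), function(i) {
    if (strand[i] == "+") {
      e1 <- c(gstart[i], gstart[i] + 300L)
      e2 <- c(gstart[i] + 800L, gend[i])          # terminal exon
      rk <- c(1L, 2L)
    } else {
      e2 <- c(gstart[i], gend[i] - 800L)          # terminal exon (left)
      e1 <- c(gend[i] - 300L, gend[i])
      rk <- c(2L, 1L)
      tmp <- e1; e1 <- e2; e2 <- tmp; rk <- c(2L, 1L)
    }
    data.frame(exon_id = sprintf("ex%04d_%d", i, 1:2),
               transcript_id = transcripts$transcript_id[i],
               chrom = chrom,
               start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
               strand = strand[i], rank = rk,
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, ex)

  utr3 <- data.frame(gene_id = genes$gene_id, chrom = chrom,
                     start = ifelse(strand == "+", gend - utr_len, gstart),
                     end = ifelse(strand == "+", gend, gstart + utr_len),
                     strand = strand, stringsAsFactors = FALSE)

  # tags: proximal -> distal along transcription, polyA site at 3' end
  tl <- vector("list", ng)
  for (i in seq_len(ng)) {
    js <- seq_len(k[i])
    if (strand[i] == "+") {
      s0 <- utr3$start[i] + 100L + (js - 1L) * TAG_PITCH
      e0 <- s0 + 21L
      pa <- e0                    # 0-based pos of cleavage site base
    } else {
      e0 <- utr3$end[i] - 100L - (js - 1L) * TAG_PITCH
      s0 <- e0 - 21L
      pa <- s0 - 1L
    }
    tl[[i]] <- data.frame(tag_id = sprintf("tag_%s_%d", genes$gene_id[i], js),
                          gene_id = genes$gene_id[i], chrom = chrom,
                          start = s0, end = e0, strand = strand[i],
                          rank = js, polya_pos = pa,
                          stringsAsFactors = FALSE)
  }
  tag_layout <- do.call(rbind, tl)

  polya_sites <- data.frame(
    site_id = sprintf("pa_%s", tag_layout$tag_id),
    gene_id = tag_layout$gene_id, chrom = chrom,
    pos = tag_layout$polya_pos, strand = tag_layout$strand,
    status = sample(c("validated", "predicted"), nrow(tag_layout),
                    replace = TRUE, prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)

  # repeats in intergenic gaps (disjoint from gene spans by construction)
  gap_start <- c(0L, gend[-ng])
  gap_end <- gstart
  has_rep <- which(stats::runif(ng) < 0.4 & gap_end - gap_start > 600L)
  repeats <- data.frame(
    repeat_id = sprintf("rep%04d", seq_along(has_rep)),
    class = sample(c("LINE", "SINE", "LTR"), length(has_rep),
                   replace = TRUE, prob = c(0.5, 0.25, 0.25)),
    chrom = chrom,
    start = gap_start[has_rep] + 200L,
    end = gap_start[has_rep] + 500L,
    stringsAsFactors = FALSE)

  # a few intergenic tags inside repeat elements
  n_ig <- min(nrow(repeats), max(1L, round(0.05 * ng)))
  if (n_ig > 0 && nrow(repeats) > 0) {
    ri <- sample.int(nrow(repeats), n_ig)
    ig <- data.frame(tag_id = sprintf("tag_ig%03d", seq_len(n_ig)),
                     gene_id = NA_character_, chrom = chrom,
                     start = repeats$start[ri] + 50L,
                     end = repeats$start[ri] + 71L,
                     strand = sample(c("+", "-"), n_ig, replace = TRUE),
                     rank = NA_integer_, polya_pos = NA_integer_,
                     stringsAsFactors = FALSE)
    tag_layout <- rbind(tag_layout, ig)
  }

  # tag sequences: CATG anchor + 17 nt with tag-specific GC propensity
  nt <- nrow(tag_layout)
  gc_prop <- 0.25 + 0.5 * stats::rbeta(nt, 2, 2)
  tag_layout$sequence <- vapply(gc_prop, function(p) {
    paste0("CATG", paste(sample(c("G", "C", "A", "T"), 17L, replace = TRUE,
                                prob = c(p / 2, p / 2,
                                         (1 - p) / 2, (1 - p) / 2)),
                         collapse = ""))
  }, character(1))

  ann <- genome_annotation(genes, transcripts, exons, utr3,
                           polya_sites, repeats)
  ann$tag_layout <- tag_layout
  ann
}

#' Simulate negative-binomial tag counts with planted effects
#'
#' Counts are drawn around
#' `exp(baseline + beta * (dosage - mean) + gamma * gc_latent * loading +
#' log library size)` with a negative-binomial observation model
#' (`nb_dispersion = 0` gives the Poisson limit).  A fraction of genes
#' receive a planted cis-eQTL on one tag; a fraction of multi-tag genes
#' receive an APA switch: `+|beta|` on the proximal tag and `-|beta|` on
#' the distal tag for the same SNP.  The per-tag GC loading is the
#' centered GC fraction of the tag sequence, so the latent GC factor
#' loads on the first expression principal component.
#'
#' @param genotypes a [genotype_matrix()].
#' @param annotation output of [simulate_annotation()] (needs
#'   `tag_layout`).
#' @param config a [simulation_config()].
#' @return list with elements `counts` (a [tag_counts()]) and `ledger`
#'   (a truth ledger, see details).
#' @export
simulate_counts <- function(genotypes, annotation, config) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genotypes, "genotype_matrix"))
  tl <- annotation$tag_layout
  if (is.null(tl)) stop("annotation lacks a tag_layout (dimension mismatch)")
  n <- length(genotypes$sample_ids)
  if (n != config$n_samples)
    stop("genotype sample count does not match config (dimension mismatch)")
  set.seed(stage_seed(config$seed, "counts"))
  nt <- nrow(tl)
  base_log <- stats::rnorm(nt, log(30), 1.2)
  genic <- which(!is.na(tl$gene_id))
  ndom <- min(config$n_dominant_tags, length(genic))
  dom <- if (ndom > 0) resample(genic, ndom) else integer()
  base_log[dom] <- log(4e4)

  gc_frac <- (nchar(gsub("[AT]", "", tl$sequence))) / nchar(tl$sequence)
  loading <- gc_frac - mean(gc_frac)
  gc_latent <- stats::rnorm(n)
  lib_log <- stats::rnorm(n, 0, config$library_size_log_sd)

  # choose planted eQTL genes and APA genes (disjoint)
  snps <- genotypes$snps
  genes <- annotation$genes
  mid <- floor((tl$start + tl$end) / 2)
  nearest_snp <- function(m) {
    d <- abs((snps$pos - 1L) - m)
    j <- which.min(d)
    if (d[j] <= 250000L) j else NA_integer_
  }
  tab <- table(tl$gene_id[genic])
  multi <- names(tab)[tab >= 2L]
  n_apa <- round(config$apa_switch_fraction * length(multi))
  apa_genes <- if (n_apa > 0) resample(multi, n_apa) else character()
  cand <- setdiff(unique(tl$gene_id[genic]), apa_genes)
  n_eqtl <- round(config$eqtl_fraction * length(cand))
  eqtl_genes <- if (n_eqtl > 0) resample(cand, n_eqtl) else character()

  beta <- matrix(0, nrow = nt, ncol = 1)
  eqtl_snp <- rep(NA_integer_, nt)
  led_eqtl <- list(); led_apa <- list()
  for (g in eqtl_genes) {
    ti <- resample(which(tl$gene_id %in% g), 1L)
    sj <- nearest_snp(mid[ti])
    if (is.na(sj)) next
    b <- resample(config$eqtl_effect_sizes, 1L) * resample(c(-1, 1), 1L)
    beta[ti] <- b; eqtl_snp[ti] <- sj
    led_eqtl[[length(led_eqtl) + 1L]] <-
      data.frame(snp_id = snps$id[sj], tag_id = tl$tag_id[ti],
                 effect_size = b,
                 direction = if (b > 0) "up" else "down",
                 stringsAsFactors = FALSE)
  }
  for (g in apa_genes) {
    ti <- which(tl$gene_id %in% g)
    ti <- ti[order(tl$rank[ti])]
    prox <- ti[1]; dist <- ti[length(ti)]
    sj <- nearest_snp(floor(mean(mid[c(prox, dist)])))
    if (is.na(sj)) next
    b <- abs(resample(config$eqtl_effect_sizes, 1L))
    beta[prox] <- b; beta[dist] <- -b
    eqtl_snp[prox] <- sj; eqtl_snp[dist] <- sj
    led_apa[[length(led_apa) + 1L]] <-
      data.frame(snp_id = snps$id[sj], gene_id = g,
                 proximal_tag = tl$tag_id[prox],
                 distal_tag = tl$tag_id[dist],
                 effect_size = b, stringsAsFactors = FALSE)
    led_eqtl[[length(led_eqtl) + 1L]] <-
      data.frame(snp_id = rep(snps$id[sj], 2),
                 tag_id = tl$tag_id[c(prox, dist)],
                 effect_size = c(b, -b),
                 direction = c("up", "down"), stringsAsFactors = FALSE)
  }

  log_mu <- matrix(rep(base_log, each = n), nrow = n) +
    outer(gc_latent, loading) * config$gc_factor_sd +
    matrix(rep(lib_log, nt), nrow = n)
  planted <- which(beta[, 1] != 0)
  for (ti in planted) {
    d <- genotypes$dosages[, eqtl_snp[ti]]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    log_mu[, ti] <- log_mu[, ti] + beta[ti] * (d - mean(d))
  }
  mu <- exp(log_mu)
  cnt <- if (config$nb_dispersion > 0)
    matrix(stats::rnbinom(n * nt, mu = mu, size = 1 / config$nb_dispersion),
           nrow = n)
  else matrix(stats::rpois(n * nt, lambda = mu), nrow = n)

  tags <- data.frame(id = tl$tag_id, chrom = tl$chrom, start = tl$start,
                     end = tl$end, strand = tl$strand,
                     sequence = tl$sequence, stringsAsFactors = FALSE)
  counts <- tag_counts(genotypes$sample_ids, tags, cnt)
  ledger <- structure(list(
    planted_eqtls = if (length(led_eqtl)) do.call(rbind, led_eqtl)
    else data.frame(snp_id = character(), tag_id = character(),
                    effect_size = numeric(), direction = character()),
    planted_apa = if (length(led_apa)) do.call(rbind, led_apa)
    else data.frame(snp_id = character(), gene_id = character(),
                    proximal_tag = character(), distal_tag = character(),
                    effect_size = numeric()),
    planted_polya = data.frame(snp_id = character(), event = character(),
                               motif = character(),
                               distance_nt = integer()),
    latent_gc = stats::setNames(gc_latent, genotypes$sample_ids),
    library_log = stats::setNames(lib_log, genotypes$sample_ids)),
    class = "truth_ledger")
  list(counts = counts, ledger = ledger)
}

POLYA_SWAPS <- list(
  c("AATGAA", "AATAAA"), c("AACAAA", "AATAAA"),
  c("AGTAAA", "AATAAA"), c("AATAGA", "AATAAA"))

#' Simulate a genome sequence with planted polyA-signal SNPs
#'
#' Generates a background chromosome sequence free of the 13
#' polyadenylation-signal motifs (on both strands, by rejection
#' resampling), then plants: formation SNPs, where the reference carries
#' a non-canonical hexamer whose alternative allele yields canonical
#' AATAAA within 30 nt upstream of a proximal polyA site; and disruption
#' SNPs, where a planted AATAAA upstream of a distal site is destroyed
#' by the alternative allele (AATAAA -> AAAAAA).
#'
#' @param annotation output of [simulate_annotation()].
#' @param config a [simulation_config()].
#' @param ledger optional truth ledger to update.
#' @return list with `genome` (named `Biostrings::DNAStringSet`),
#'   `polya_snp_table` (data.frame of planted SNPs, 1-based positions,
#'   genomic-strand alleles) and `ledger`.
#' @export
simulate_sequences <- function(annotation, config, ledger = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(annotation$polya_sites) == 0)
    stop("annotation has no polyA sites")
  set.seed(stage_seed(config$seed, "sequences"))
  tl <- annotation$tag_layout
  clen <- chrom_length(config)
  seqc <- sample(c("A", "C", "G", "T"), clen, replace = TRUE)
  seqs <- paste(seqc, collapse = "")
  motifs <- polya_motif_catalog(fix_gataa = FALSE)$motifs
  scrub <- unique(c(motifs,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAStringSet(motifs)))))
  for (it in 1:50) {
    hit <- FALSE
    for (m in scrub) {
      g <- gregexpr(m, seqs, fixed = TRUE)[[1]]
      if (g[1] != -1) {
        hit <- TRUE
        for (s in g) {
          w <- nchar(m)
          substr(seqs, s, s + w - 1L) <-
            paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                  collapse = "")
        }
      }
    }
    if (!hit) break
  }

  # candidate genes with >= 2 polyA sites so shortening is predictable
  pa <- annotation$polya_sites
  tab <- table(pa$gene_id)
  multi <- names(tab)[tab >= 2L]
  nf <- min(config$n_polya_formation, length(multi))
  pick <- if (length(multi)) resample(multi,
                                      min(length(multi),
                                          nf + config$n_polya_disruption))
  else character()
  events <- list()
  put_motif <- function(seqs, site_pos, strand, motif, dist) {
    # transcribed-strand motif whose 3'-most base lies `dist` nt upstream
    # of the cleavage site; returns genomic interval [s0, s0+6) and seq
    if (strand == "+") {
      last0 <- site_pos - dist
      s0 <- last0 - 5L
      gseq <- motif
    } else {
      last0 <- site_pos + dist
      s0 <- last0
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    }
    substr(seqs, s0 + 1L, s0 + 6L) <- gseq
    list(seqs = seqs, s0 = s0)
  }
  k <- 0L
  for (g in pick) {
    k <- k + 1L
    is_formation <- k <= nf
    sites <- pa[pa$gene_id == g, ]
    strand <- sites$strand[1]
    # proximal = first in transcription order
    ord <- if (strand == "+") order(sites$pos) else order(-sites$pos)
    sites <- sites[ord, ]
    site <- if (is_formation) sites[1, ] else sites[nrow(sites), ]
    dist <- sample(10:28, 1L)
    if (is_formation) {
      swap <- POLYA_SWAPS[[sample(length(POLYA_SWAPS), 1L)]]
      m_ref <- swap[1]; m_alt <- swap[2]
    } else {
      m_ref <- "AATAAA"; m_alt <- "AAAAAA"
    }
    off <- which(strsplit(m_ref, "")[[1]] != strsplit(m_alt, "")[[1]])[1]
    pm <- put_motif(seqs, site$pos, strand, m_ref, dist)
    seqs <- pm$seqs
    # genomic position of the substituted base
    gpos0 <- if (strand == "+") pm$s0 + off - 1L
    else pm$s0 + (6L - off)
    ref_t <- substr(m_ref, off, off)   # transcribed-strand alleles
    alt_t <- substr(m_alt, off, off)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_g <- if (strand == "+") ref_t else comp[[ref_t]]
    alt_g <- if (strand == "+") alt_t else comp[[alt_t]]
    events[[k]] <- data.frame(
      snp_id = sprintf("pa_snp%02d", k), chrom = chrom_name(config),
      pos = gpos0 + 1L, ref = ref_g, alt = alt_g, gene_id = g,
      strand = strand,
      event = if (is_formation) "formation" else "disruption",
      motif_ref = m_ref, motif_alt = m_alt, distance_nt = dist,
      stringsAsFactors = FALSE)
  }
  tab_out <- if (length(events)) do.call(rbind, events)
  else data.frame(snp_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  gene_id = character(), strand = character(),
                  event = character(), motif_ref = character(),
                  motif_alt = character(), distance_nt = integer())
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs,
                                                     chrom_name(config)))
  if (!is.null(ledger)) {
    ledger$planted_polya <- tab_out[, c("snp_id", "event", "motif_ref",
                                        "motif_alt", "distance_nt")]
    names(ledger$planted_polya)[3:4] <- c("motif", "motif_alt")
  }
  list(genome = genome, polya_snp_table = tab_out, ledger = ledger)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_annotation()], [simulate_counts()] and (optionally)
#' [simulate_sequences()] under one configuration.
#'
#' @param config a [simulation_config()].
#' @param sequences also generate the genome sequence and planted
#'   polyA-signal SNPs (slower; off by default).
#' @return list with `genotypes`, `annotation`, `counts`, `ledger` and,
#'   when requested, `genome` and `polya_snp_table`.
#' @export
simulate_dataset <- function(config, sequences = FALSE) {
  geno <- simulate_genotypes(config)
  ann <- simulate_annotation(config)
  cs <- simulate_counts(geno, ann, config)
  out <- list(genotypes = geno, annotation = ann,
              counts = cs$counts, ledger = cs$ledger)
  if (sequences) {
    sq <- simulate_sequences(ann, config, cs$ledger)
    out$genome <- sq$genome
    out$polya_snp_table <- sq$polya_snp_table
    out$ledger <- sq$ledger
  }
  out
}
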