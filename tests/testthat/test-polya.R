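# polyadenylation-signal motif scanning and LD proxy expansion

test_that("the motif catalog matches the canonical 13-signal list", {
  cat13 <- polya_motif_catalog()
  expect_identical(cat13$motifs,
                   c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA",
                     "AATATA", "AATACA", "CATAAA", "GATAA", "AATGAA",
                     "TTTAAA", "ACTAAA", "AATAGA"))
  expect_equal(unname(cat13$canonical_rank["AATAAA"]), 1L)
  expect_equal(unname(cat13$canonical_rank["ATTAAA"]), 2L)
  expect_true(all(cat13$canonical_rank[
    !names(cat13$canonical_rank) %in% c("AATAAA", "ATTAAA")] == 3L))
  fixed <- polya_motif_catalog(fix_gataa = TRUE)
  expect_true("GATAAA" %in% fixed$motifs)
  expect_false("GATAA" %in% fixed$motifs)
})

test_that("LD proxies include self, duplicates, and exclude independents", {
  cfg <- simulation_config(seed = 71, n_samples = 1000, n_genes = 30,
                           n_snps = 100, ld_block_size = 5L)
  g <- simulate_genotypes(cfg)
  cfgA <- analysis_config()
  pr <- ld_proxies(g, g$snps$id[3], cfgA)
  expect_true(g$snps$id[3] %in% pr$snp_id)
  expect_equal(pr$r2[pr$snp_id == g$snps$id[3]], 1)
  # block mates qualify as proxies
  expect_true(any(g$snps$id[1:5] %in% setdiff(pr$snp_id, g$snps$id[3])))
  # duplicated SNP column gives r2 = 1
  g2 <- g
  g2$snps <- rbind(g2$snps, data.frame(id = "dup", chrom = "chrS",
                                       pos = g$snps$pos[3] + 1L,
                                       ref = "A", alt = "G"))
  g2$dosages <- cbind(g2$dosages, dup = g$dosages[, 3])
  g2 <- genotype_matrix(g2$sample_ids, g2$snps, g2$dosages)
  pr2 <- ld_proxies(g2, "dup", cfgA)
  expect_equal(pr2$r2[pr2$snp_id == g$snps$id[3]], 1, tolerance = 1e-12)

  # independent SNPs (other blocks) never pass 0.8 at n = 1000
  cfg1 <- simulation_config(seed = 72, n_samples = 1000, n_genes = 30,
                            n_snps = 100, ld_block_size = 1L)
  gi <- simulate_genotypes(cfg1)
  for (q in gi$snps$id[seq(1, 50, by = 10)]) {
    pri <- ld_proxies(gi, q, cfgA)
    expect_identical(pri$snp_id, q)
  }

  mono <- genotype_matrix(paste0("s", 1:4),
                          data.frame(id = "m", chrom = "c", pos = 10L,
                                     ref = "A", alt = "G"),
                          matrix(1, 4, 1))
  expect_warning(pm <- ld_proxies(mono, "m", cfgA), "monomorphic")
  expect_equal(nrow(pm), 0L)
})

test_that("snps_in_gene uses strict interval containment", {
  ann <- tiny_annotation()   # gA spans [1000, 3000)
  pr <- data.frame(snp_id = c("in", "edge", "out"),
                   r2 = 1, pos = c(1500L, 3000L, 3001L),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  kept <- snps_in_gene(pr, "gA", ann)
  # 1-based 3000 is 0-based 2999, the last base inside [1000, 3000)
  expect_identical(kept$snp_id, c("in", "edge"))
  expect_equal(nrow(snps_in_gene(pr[0, ], "gA", ann)), 0L)
})

test_that("context extraction is strand-specific with allele complement", {
  genome <- c(chr1 = "AAAAACAGTCGGGGG")
  ctx <- extract_context(genome, "chr1", 8, "G", "A", "+", 5)
  expect_equal(nchar(ctx$ref_context), 11L)
  expect_equal(substr(ctx$ref_context, 6, 6), "G")
  expect_equal(substr(ctx$alt_context, 6, 6), "A")
  expect_equal(sub("G", "A", ctx$ref_context), ctx$alt_context)

  ctxm <- extract_context(genome, "chr1", 8, "G", "A", "-", 5)
  expect_equal(substr(ctxm$ref_context, 6, 6), "C")
  expect_equal(substr(ctxm$alt_context, 6, 6), "T")
  expect_equal(ctxm$ref_context, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      ctx$ref_context))))

  expect_error(extract_context(genome, "chr1", 3, "A", "G", "+", 5),
               "contig end")
  expect_error(extract_context(genome, "chr1", 8, "T", "A", "+", 5),
               "mismatch")
})

test_that("scanning is frame-complete against a substring oracle", {
  cat13 <- polya_motif_catalog()
  cfg <- analysis_config()
  set.seed(73)
  # plant AATAAA at every offset overlapping the SNP in the alt context
  for (off in 1:6) {
    # SNP at context position 6; motif spans [off, off+5]
    alt <- strsplit(strrep("C", 11), "")[[1]]
    alt[off:(off + 5)] <- strsplit("AATAAA", "")[[1]]
    ref <- alt
    ref[6] <- "G"                        # destroy it in ref
    sites <- data.frame(pos = 130L, strand = "+")
    ev <- classify_signal_change(paste(ref, collapse = ""),
                                 paste(alt, collapse = ""), sites,
                                 snp_pos = 101L, strand = "+",
                                 catalog = cat13, config = cfg)
    expect_identical(ev$event, "formation")
    expect_identical(ev$alt_motif_hit, "AATAAA")
  }
  # the 5-mer GATAA is found too
  alt <- strsplit("CCGATAACCCC", "")[[1]]
  ref <- alt; ref[6] <- "C"
  ev5 <- classify_signal_change(paste(ref, collapse = ""),
                                paste(alt, collapse = ""),
                                data.frame(pos = 120L, strand = "+"),
                                101L, "+", cat13, cfg)
  expect_identical(ev5$event, "formation")
  expect_identical(ev5$alt_motif_hit, "GATAA")

  # random contexts: scanner "sees a motif" iff a substring match
  # overlapping the SNP position (index 6) exists (brute-force oracle)
  oracle_hit <- function(ctx) {
    any(vapply(cat13$motifs, function(m) {
      w <- nchar(m)
      any(vapply(seq_len(11 - w + 1L), function(s)
        s <= 6L && s + w - 1L >= 6L &&
          substr(ctx, s, s + w - 1L) == m, logical(1)))
    }, logical(1)))
  }
  for (i in 1:200) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 11, replace = TRUE),
                 collapse = "")
    hit <- classify_signal_change(strrep("C", 11), ctx,
                                  data.frame(pos = 130L, strand = "+"),
                                  101L, "+", cat13, cfg)
    expect_identical(hit$event != "none", oracle_hit(ctx))
  }
})

test_that("allele-swap duality maps formations onto disruptions", {
  rows <- list(c("AATGAA", "AATAAA", 15), c("AACAAA", "AATAAA", 27),
               c("AATAAA", "AAAAAA", 23))
  for (r in rows) for (st in c("+", "-")) {
    fwd <- swap_signal_call(r[1], r[2], as.integer(r[3]), strand = st)
    rev <- swap_signal_call(r[2], r[1], as.integer(r[3]), strand = st)
    expect_true(fwd$event %in% c("formation", "disruption"))
    expect_identical(sort(c(fwd$event, rev$event)),
                     c("disruption", "formation"))
    expect_identical(fwd$distance_nt, rev$distance_nt)
  }
})

test_that("the 30-nt distance rule and upstream requirement gate events", {
  cfg <- analysis_config()
  # formation motif, but the nearest downstream site is 55 nt away
  alt50 <- "CCCCCAATAAA"                      # motif 3' end genomic 105
  ev <- classify_signal_change("CCCCCCCCCCC", alt50,
                               data.frame(pos = 160L, strand = "+"),
                               101L, "+", polya_motif_catalog(), cfg)
  expect_identical(ev$event, "none")
  # motif strictly downstream of the only polyA site: no call
  alt <- "CCCCCAATAAA"   # motif 3' end at genomic 105 (0-based)
  sites_up <- data.frame(pos = 80L, strand = "+")   # upstream of motif
  ev2 <- classify_signal_change("CCCCCCCCCCC", alt, sites_up, 101L, "+",
                                polya_motif_catalog(), cfg)
  expect_identical(ev2$event, "none")
})

test_that("non-canonical to canonical strengthening counts as formation", {
  ev <- swap_signal_call("AGTAAA", "AATAAA", 21L)
  expect_identical(ev$event, "formation")
  expect_identical(ev$ref_motif_hit, "AGTAAA")
  expect_identical(ev$alt_motif_hit, "AATAAA")
})

test_that("confirm_tag_ratio matches the predicted shortening direction", {
  # two tags flanking an affected site; dosage raises the proximal tag
  tags <- data.frame(id = c("prox", "dist"), chrom = "chr1",
                     start = c(100L, 400L), end = c(121L, 421L),
                     strand = "+", stringsAsFactors = FALSE)
  set.seed(74)
  n <- 60
  dos <- sample(0:2, n, replace = TRUE)
  prox <- rpois(n, lambda = exp(3 + 0.8 * dos))
  dist <- rpois(n, lambda = exp(3 - 0.8 * dos))
  ct <- make_counts(tags, cbind(prox, dist),
                    samples = sprintf("s%02d", 1:n))
  geno <- genotype_matrix(ct$sample_ids,
                          data.frame(id = "rsX", chrom = "chr1",
                                     pos = 150L, ref = "C", alt = "T"),
                          matrix(dos, ncol = 1))
  genes <- data.frame(gene_id = "g1", name = "G1",
                      biotype = "protein_coding", chrom = "chr1",
                      start = 0L, end = 600L, strand = "+",
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(
    genes,
    data.frame(transcript_id = "t1", gene_id = "g1"),
    data.frame(exon_id = "e1", transcript_id = "t1", chrom = "chr1",
               start = 0L, end = 600L, strand = "+", rank = 1L),
    data.frame(gene_id = "g1", chrom = "chr1", start = 50L, end = 550L,
               strand = "+"),
    data.frame(site_id = c("sp", "sd"), gene_id = "g1", chrom = "chr1",
               pos = c(150L, 450L), strand = "+", status = "validated"),
    data.frame(repeat_id = character(), class = character(),
               chrom = character(), start = integer(),
               end = integer()))
  event <- list(event = "formation", gene_id = "g1", causal_snp = "rsX",
                predicted_effect = "shortening")
  out <- confirm_tag_ratio(event, ct, geno, ann, site_pos = 200L)
  expect_true(out$confirmed)
  expect_gt(out$rho, 0)
  expect_lt(out$p, 1e-4)
  # no event: skipped
  skip_out <- confirm_tag_ratio(list(event = "none"), ct, geno, ann)
  expect_false(skip_out$confirmed)
  # monomorphic dosage: not testable
  geno0 <- genotype_matrix(ct$sample_ids, geno$snps,
                           matrix(1, n, 1))
  out0 <- confirm_tag_ratio(event, ct, geno0, ann, site_pos = 200L)
  expect_true(is.na(out0$rho))
})
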