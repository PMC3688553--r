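# opposite-direction (APA) detection and classification

test_that("differential correlation test matches its closed form", {
  expect_equal(diff_correlation_test(0.5, 0.5, 94), 1)
  expect_equal(diff_correlation_test(0.3, -0.6, 94),
               diff_correlation_test(-0.6, 0.3, 94))
  # direct evaluation of the Fisher-z statistic at rho = +/- 0.8, n = 94
  stat <- (atanh(0.8) - atanh(-0.8)) / sqrt(2 / 91)
  expect_equal(diff_correlation_test(0.8, -0.8, 94),
               2 * pnorm(-abs(stat)), tolerance = 1e-12)
  expect_lt(diff_correlation_test(0.8, -0.8, 94), 1e-7)
  # monotone decreasing in |z1 - z2| and in n
  p1 <- diff_correlation_test(0.2, -0.2, 50)
  p2 <- diff_correlation_test(0.4, -0.4, 50)
  p3 <- diff_correlation_test(0.2, -0.2, 200)
  expect_lt(p2, p1)
  expect_lt(p3, p1)
  expect_error(diff_correlation_test(0.5, 0.2, 3), "exceed 3")
  expect_error(diff_correlation_test(1, 0.2, 50), "rho")
  # dependent form needs r12 and stays a valid p-value
  expect_error(diff_correlation_test(0.5, -0.5, 50,
                                     method = "dependent"), "r12")
  pd <- diff_correlation_test(0.5, -0.5, 50, method = "dependent",
                              r12 = -0.3)
  expect_true(pd > 0 && pd < 1)
})

two_tag_records <- function(z1, z2, p1, p2, sig1, sig2,
                            gene = c("g1", "g1")) {
  rho <- c(z1, z2) / 10
  rbind(rec_row("snpX", "tagP", rho[1], z1, p1, sig1),
        rec_row("snpX", "tagQ", rho[2], z2, p2, sig2)) ->
    rec
  attr(rec, "genes") <- gene
  rec
}

test_that("strict detection needs both tags significant and opposite", {
  cfg <- analysis_config()
  t2g <- c(tagP = "g1", tagQ = "g1")
  rec <- two_tag_records(8, -7, 1e-12, 1e-10, TRUE, TRUE)
  ev <- detect_opposite_strict(rec, t2g, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$tag_up, "tagP")
  expect_equal(ev$tag_down, "tagQ")
  expect_identical(ev$mode, "strict")

  # same sign: nothing
  expect_equal(nrow(detect_opposite_strict(
    two_tag_records(8, 7, 1e-12, 1e-10, TRUE, TRUE), t2g, cfg)), 0L)
  # one sub-threshold: strict empty, permissive finds it
  rec2 <- two_tag_records(8, -6, 1e-12, 1e-3, TRUE, FALSE)
  expect_equal(nrow(detect_opposite_strict(rec2, t2g, cfg)), 0L)
  evp <- detect_opposite_permissive(rec2, t2g, cfg)
  expect_equal(nrow(evp), 1L)
  expect_identical(evp$mode, "permissive")
  # strict p gate: significant but p above 1e-7
  rec3 <- two_tag_records(5, -5, 1e-6, 1e-6, TRUE, TRUE)
  expect_equal(nrow(detect_opposite_strict(rec3, t2g, cfg)), 0L)
})

test_that("permissive detection gates on the differential correlation p", {
  cfg <- analysis_config()
  t2g <- c(tagP = "g1", tagQ = "g1")
  # weak opposite correlations: diff test cannot reach 1e-7
  rec <- two_tag_records(3, -1, 1e-9, 0.3, TRUE, FALSE)
  rec$rho <- c(0.25, -0.05)
  expect_equal(nrow(detect_opposite_permissive(rec, t2g, cfg)), 0L)
  # strong opposite correlations pass
  rec$rho <- c(0.7, -0.5)
  expect_equal(nrow(detect_opposite_permissive(rec, t2g, cfg)), 1L)
  # tags of different genes are never paired
  t2g2 <- c(tagP = "g1", tagQ = "g2")
  expect_equal(nrow(detect_opposite_permissive(rec, t2g2, cfg)), 0L)
})

test_that("every strict event is also a permissive event", {
  cfg <- simulation_config(seed = 61, n_genes = 40,
                           apa_switch_fraction = 0.8,
                           eqtl_effect_sizes = 2)
  ds <- simulate_dataset(cfg)
  qn <- quantile_normalize(filter_tags(ds$counts,
                                       config = analysis_config()))
  res <- permutation_fdr(ds$genotypes, qn, config = analysis_config(),
                         seed = 2)
  feats <- qn$features
  t2g <- tags_to_genes(feats, ds$annotation)
  st <- detect_opposite_strict(res$records, t2g, analysis_config())
  pm <- detect_opposite_permissive(res$records, t2g, analysis_config())
  expect_gt(nrow(st), 0)
  key <- function(d) paste(d$snp_id, d$tag_up, d$tag_down)
  expect_true(all(key(st) %in% key(pm)))
  # planted APA pairs have the proximal tag up (alt allele shortening)
  led <- ds$ledger$planted_apa
  found <- merge(pm, led, by.x = c("snp_id", "gene_id"),
                 by.y = c("snp_id", "gene_id"))
  expect_gt(nrow(found), 0)
})

test_that("events classify by shared UTR, shared last exon, or neither", {
  ann <- tiny_annotation()
  feats <- data.frame(
    id = c("u1", "u2", "e1", "x1"),
    chrom = "chr1",
    start = c(2550L, 2800L, 2100L, 1100L),
    end = c(2571L, 2821L, 2121L, 1121L), stringsAsFactors = FALSE)
  ev <- function(a, b) data.frame(tag_up = a, tag_down = b,
                                  stringsAsFactors = FALSE)
  expect_identical(classify_event(ev("u1", "u2"), feats, ann),
                   "same_3utr_apa")
  # u1 (in UTR) and e1 share terminal exon eA2 but not a UTR interval
  expect_identical(classify_event(ev("e1", "u1"), feats, ann),
                   "same_last_exon_apa")
  # x1 is in first exon eA1: different (non-terminal) exon
  expect_identical(classify_event(ev("x1", "u1"), feats, ann),
                   "different_last_exon")
  # intronic tag cannot be resolved
  feats2 <- rbind(feats, data.frame(id = "intr", chrom = "chr1",
                                    start = 1500L, end = 1521L))
  expect_warning(
    cls <- classify_event(ev("intr", "u1"), feats2, ann), "unresolved")
  expect_identical(cls, "unresolved")
})

test_that("permutation null check finds nothing on null data", {
  cfg <- simulation_config(seed = 62, n_genes = 40, n_snps = 120,
                           eqtl_fraction = 0, apa_switch_fraction = 0)
  ds <- simulate_dataset(cfg)
  qn <- quantile_normalize(filter_tags(ds$counts,
                                       config = analysis_config()))
  t2g <- tags_to_genes(qn$features, ds$annotation)
  counts <- permutation_null_check(ds$genotypes, qn, qn$features, t2g,
                                   analysis_config(), n_runs = 3L,
                                   n_top = 30L, seed = 7)
  expect_identical(counts, c(0L, 0L, 0L))
  counts2 <- permutation_null_check(ds$genotypes, qn, qn$features, t2g,
                                    analysis_config(), n_runs = 3L,
                                    n_top = 30L, seed = 7)
  expect_identical(counts, counts2)
  # relaxing the threshold lets chance events through eventually
  lax <- analysis_config(diffcorr_p_threshold = 0.5)
  counts3 <- permutation_null_check(ds$genotypes, qn, qn$features, t2g,
                                    lax, n_runs = 3L, n_top = 30L,
                                    seed = 7)
  expect_gt(sum(counts3), 0)
})

test_that("proximal/distal densities and ratios follow the definitions", {
  tags <- data.frame(id = c("p", "d"), chrom = "chr1",
                     start = c(100L, 400L), end = c(121L, 421L),
                     strand = "+", stringsAsFactors = FALSE)
  cnt <- rbind(c(10L, 5L), c(4L, 4L), c(3L, 0L))
  ct <- make_counts(tags, cnt)
  rr <- proximal_distal_ratio(ct, "chr1", c(50L, 150L), c(350L, 450L))
  expect_equal(rr$ratio[1], 2.0)
  expect_equal(rr$ratio[2], 1.0)
  expect_true(is.na(rr$ratio[3]) && !rr$defined[3])
  expect_error(proximal_distal_ratio(ct, "chr1", c(50L, 150L),
                                     c(100L, 200L)), "disjoint")
})

test_that("ratio-genotype association recovers a planted APA switch", {
  cfg <- simulation_config(seed = 63, n_genes = 40,
                           tags_per_gene = c(2L, 2L),
                           apa_switch_fraction = 1,
                           eqtl_effect_sizes = 2, eqtl_fraction = 0)
  ds <- simulate_dataset(cfg)
  led <- ds$ledger$planted_apa
  hit <- 0L
  for (i in seq_len(min(5, nrow(led)))) {
    e <- led[i, ]
    tl <- ds$annotation$tag_layout
    tp <- tl[tl$tag_id == e$proximal_tag, ]
    td <- tl[tl$tag_id == e$distal_tag, ]
    reg <- function(t) c(t$start - 10L, t$end + 10L)
    pr <- reg(tp); di <- reg(td)
    if (pr[1] > di[1]) { tmp <- pr; pr <- di; di <- tmp }
    # order regions along the genome; proximal is transcription-first
    prox <- if (tp$strand == "+") pr else di
    dist <- if (tp$strand == "+") di else pr
    rr <- proximal_distal_ratio(ds$counts, "chrS", prox, dist)
    dosage <- stats::setNames(
      ds$genotypes$dosages[, e$snp_id], ds$genotypes$sample_ids)
    a <- ratio_genotype_assoc(rr, dosage)
    if (!is.na(a$rho) && a$rho > 0 && a$p < 0.01) hit <- hit + 1L
  }
  expect_gte(hit, 4L)
})
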