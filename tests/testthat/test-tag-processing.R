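# filtering, normalization, GC estimation, annotation, summarization

make_presence_counts <- function(n_present, n_samples = 94) {
  tags <- data.frame(id = "t1", chrom = "chr1", start = 100L,
                     end = 121L, strand = "+",
                     sequence = random_tag_seq(1),
                     stringsAsFactors = FALSE)
  cnt <- matrix(0L, nrow = n_samples, ncol = 1)
  cnt[seq_len(n_present), 1] <- 5L
  make_counts(tags, cnt)
}

test_that("presence filter uses a strict >90% threshold", {
  cfg <- analysis_config()
  kept <- filter_tags(make_presence_counts(85), config = cfg)   # 90.4%
  expect_equal(ncol(kept$counts), 1L)
  gone <- filter_tags(make_presence_counts(84), config = cfg)   # 89.4%
  expect_equal(ncol(gone$counts), 0L)
})

test_that("CATG-anchor SNPs remove tags, strand-aware", {
  tags <- data.frame(id = c("plus", "minus"), chrom = "chr1",
                     start = c(100L, 300L), end = c(121L, 321L),
                     strand = c("+", "-"),
                     sequence = random_tag_seq(2),
                     stringsAsFactors = FALSE)
  cnt <- matrix(5L, nrow = 4, ncol = 2)
  ct <- make_counts(tags, cnt)
  cfg <- analysis_config(presence_fraction = 0)
  # SNP at 2nd base of the + tag's CATG (0-based 101 -> 1-based 102)
  out <- filter_tags(ct, data.frame(chrom = "chr1", pos = 102L), cfg)
  expect_identical(out$tags$id, "minus")
  # anchor of the - strand tag is its last 4 bases: [317, 321)
  out2 <- filter_tags(ct, data.frame(chrom = "chr1", pos = 318L), cfg)
  expect_identical(out2$tags$id, "plus")
  # SNP just outside the anchor leaves both
  out3 <- filter_tags(ct, data.frame(chrom = "chr1", pos = 106L), cfg)
  expect_equal(ncol(out3$counts), 2L)
})

test_that("filter_tags is idempotent and the no-op case is identity", {
  cfg <- simulation_config(seed = 31, n_genes = 20)
  ds <- simulate_dataset(cfg)
  ubiq <- ds$counts$counts
  ubiq[ubiq == 0] <- 1L
  ct <- tag_counts(ds$counts$sample_ids, ds$counts$tags, ubiq)
  once <- filter_tags(ct, config = analysis_config())
  expect_equal(once$counts, ct$counts)
  twice <- filter_tags(once, config = analysis_config())
  expect_equal(twice$counts, once$counts)
})

test_that("quantile normalization maps samples onto the mean distribution", {
  m <- rbind(s1 = c(1, 3), s2 = c(2, 4))
  colnames(m) <- c("f1", "f2")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values),
               rbind(c(1.5, 3.5), c(1.5, 3.5)))

  # identical samples unchanged
  m2 <- rbind(s1 = c(2, 7, 5), s2 = c(2, 7, 5))
  expect_equal(unname(quantile_normalize(m2)$values), unname(m2))

  # permuted columns give permutations of one shared vector
  set.seed(1)
  v <- rnorm(20)
  m3 <- rbind(a = v, b = sample(v), c = sample(v))
  qn3 <- quantile_normalize(m3)$values
  for (i in 1:3)
    expect_equal(sort(qn3[i, ]), sort(qn3[1, ]), tolerance = 1e-12)

  # ties receive the mean of spanned reference values
  m4 <- rbind(s1 = c(1, 1, 10), s2 = c(2, 4, 6))
  qn4 <- quantile_normalize(m4)$values
  ref <- (sort(m4[1, ]) + sort(m4[2, ])) / 2    # 1.5, 2.5, 8
  expect_equal(unname(qn4[1, ]), c(2, 2, 8))    # mean(1.5, 2.5) twice
  expect_equal(unname(qn4[2, ]), ref)

  expect_warning(quantile_normalize(matrix(1:3, nrow = 1)), "single")
})

test_that("log2_center_scale standardizes and drops constants", {
  m <- cbind(f1 = c(0, 1, 3, 7), f2 = rep(2, 4), f3 = c(5, 0, 2, 9))
  rownames(m) <- paste0("s", 1:4)
  expect_warning(out <- log2_center_scale(m), "zero-variance")
  expect_equal(ncol(out$values), 2L)
  expect_true(all(abs(colMeans(out$values)) < 1e-10))
  expect_true(all(abs(apply(out$values, 2, sd) - 1) < 1e-10))
  expect_error(log2_center_scale(matrix(c(-1, 2), 2)), "negative")
  expect_identical(out$state, c("log2", "centered_scaled"))
})

test_that("per-sample GC content is count-weighted with top-tag exclusion", {
  seq1 <- paste0("CATG", strrep("G", 17))            # GC 19/21
  tags <- data.frame(id = "t1", chrom = "c", start = 0L, end = 21L,
                     strand = "+", sequence = seq1,
                     stringsAsFactors = FALSE)
  ct <- make_counts(tags, matrix(10L, 1, 1), samples = "s1")
  gc <- gc_content_per_sample(ct, analysis_config(gc_exclude_top = 0))
  expect_equal(unname(gc), 19 / 21)

  # all tags identical sequence: GC independent of counts
  tags2 <- data.frame(id = c("a", "b"), chrom = "c",
                      start = c(0L, 50L), end = c(21L, 71L),
                      strand = "+", sequence = rep(seq1, 2),
                      stringsAsFactors = FALSE)
  ct2 <- make_counts(tags2, matrix(c(1L, 100L), 1), samples = "s1")
  expect_equal(unname(gc_content_per_sample(
    ct2, analysis_config(gc_exclude_top = 0))), 19 / 21)

  # exclusion: 20 dominant extreme-GC tags, the rest GC 0.5 (oracle:
  # count-weighted mean over the remainder only)
  hi <- paste0("CATG", strrep("C", 17))
  mix <- paste0("CATG", strrep("CA", 8), "C")        # roughly half GC
  tags3 <- data.frame(id = sprintf("t%02d", 1:30), chrom = "c",
                      start = seq(0L, by = 50L, length.out = 30),
                      end = seq(21L, by = 50L, length.out = 30),
                      strand = "+",
                      sequence = c(rep(hi, 20), rep(mix, 10)),
                      stringsAsFactors = FALSE)
  cnt <- matrix(c(rep(1000L, 20), rep(3L, 10)), nrow = 1)
  ct3 <- make_counts(tags3, cnt, samples = "s1")
  gc_mix <- nchar(gsub("[^GC]", "", mix)) / 21
  expect_equal(unname(gc_content_per_sample(ct3, analysis_config())),
               gc_mix)
  expect_error(gc_content_per_sample(make_counts(
    data.frame(id = "x", chrom = "c", start = 0L, end = 21L,
               strand = "+"), matrix(1L, 1, 1), "s1")), "sequence")
})

test_that("tag locations are labelled by region, orientation and repeat", {
  ann <- tiny_annotation()
  tags <- data.frame(
    id = c("utr_sense", "intron_anti", "interg"),
    chrom = "chr1",
    start = c(2600L, 10200L, 5100L),
    end = c(2621L, 10221L, 5121L),
    strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  loc <- annotate_tag_location(tags, ann)
  expect_equal(loc$region, c("3'-UTR", "intron", "intergenic"))
  expect_equal(loc$orientation[1:2], c("sense", "antisense"))
  expect_equal(loc$repeat_class, c("none", "none", "LINE"))
  expect_equal(loc$nearest_gene[3], "gA")
})

test_that("transcript summarization applies the half-length overlap rule", {
  ann <- tiny_annotation()
  # exon eA2 spans [2000, 3000); craft overlaps of 10, 11, 21 bases
  # 21-bp tags ending 10, 11 and 21 bases into the exon
  tags <- data.frame(
    id = c("ov10", "ov11", "inside"),
    chrom = "chr1",
    start = c(2010L - 21L, 2011L - 21L, 2100L),
    end = c(2010L, 2011L, 2121L),
    strand = "+", stringsAsFactors = FALSE)
  cnt <- matrix(c(2L, 3L, 7L), nrow = 1)
  ct <- make_counts(tags, cnt, samples = "s1")
  tx <- summarize_transcripts_from_tags(ct, ann)
  expect_equal(unname(tx$values[1, "tA"]), 3 + 7)   # ov10 excluded
  expect_equal(unname(tx$values[1, "tB"]), 0)
})

test_that("read-based transcript quantification follows sum(c_e * b_e)", {
  expect_equal(quantify_transcript_from_reads(
    data.frame(count = 10, breadth = 1.0)), 10)
  expect_equal(quantify_transcript_from_reads(
    data.frame(count = c(10, 4), breadth = c(0.5, 1.0))), 9)
  expect_equal(quantify_transcript_from_reads(
    data.frame(count = numeric(), breadth = numeric())), 0)
  # additive over disjoint exon subsets
  set.seed(2)
  ec <- data.frame(count = rpois(6, 20), breadth = runif(6))
  expect_equal(quantify_transcript_from_reads(ec),
               quantify_transcript_from_reads(ec[1:3, ]) +
                 quantify_transcript_from_reads(ec[4:6, ]))
})
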