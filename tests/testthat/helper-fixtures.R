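# shared in-code fixtures

# a small hand-built annotation: two genes (one minus strand), explicit
# UTRs/exons, one repeat element
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), name = c("GA", "GB"),
    biotype = c("protein_coding", "lincRNA"),
    chrom = "chr1", start = c(1000L, 9000L), end = c(3000L, 11000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = c("tA", "tB"),
                            gene_id = c("gA", "gB"),
                            stringsAsFactors = FALSE)
  exons <- data.frame(
    exon_id = c("eA1", "eA2", "eB1", "eB2"),
    transcript_id = c("tA", "tA", "tB", "tB"),
    chrom = "chr1",
    start = c(1000L, 2000L, 10500L, 9000L),
    end = c(1300L, 3000L, 11000L, 10000L),
    strand = c("+", "+", "-", "-"),
    rank = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
  utr3 <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                     start = c(2500L, 9000L), end = c(3000L, 9400L),
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  polya <- data.frame(site_id = c("pA1", "pA2"), gene_id = "gA",
                      chrom = "chr1", pos = c(2700L, 2950L),
                      strand = "+", status = c("validated", "predicted"),
                      stringsAsFactors = FALSE)
  repeats <- data.frame(repeat_id = "r1", class = "LINE", chrom = "chr1",
                        start = 5000L, end = 5400L,
                        stringsAsFactors = FALSE)
  genome_annotation(genes, transcripts, exons, utr3, polya, repeats)
}

# a tag_counts object with n samples and the given per-tag presence
make_counts <- function(tags, counts, samples = NULL) {
  n <- nrow(counts)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  tag_counts(samples, tags, counts)
}

random_tag_seq <- function(n) {
  vapply(seq_len(n), function(i)
    paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17,
                                replace = TRUE), collapse = "")),
    character(1))
}

# an eQTL record table row
rec_row <- function(snp, feat, rho, z, p, sig, n = 94) {
  data.frame(snp_id = snp, feature_id = feat, n_used = n, rho = rho,
             p = p, z = z, allele_assessed = "A", significant = sig,
             stringsAsFactors = FALSE)
}
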