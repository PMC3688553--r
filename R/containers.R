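#' Genotype matrix container
#'
#' Sample-by-SNP alt-allele dosages in \{0, 1, 2, NA\} plus SNP metadata
#' (1-based positions, ref/alt alleles).
#'
#' @param sample_ids unique sample identifiers.
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param dosages numeric matrix, `length(sample_ids)` rows by
#'   `nrow(snps)` columns.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, snps, dosages) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(snps$id)) stop("snp ids must be unique")
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(snps)))
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1 (1-based)")
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(snps))
    stop("dosage dimensions do not match sample/SNP metadata")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be in {0, 1, 2} or missing")
  dimnames(dosages) <- list(sample_ids, snps$id)
  structure(list(sample_ids = sample_ids,
                 snps = as.data.frame(snps, stringsAsFactors = FALSE),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' Tag count matrix container
#'
#' Raw integer counts of 21-bp SAGE tags per sample, with tag genomic
#' coordinates (0-based half-open), strand, and (optionally) the tag
#' sequence, which must be 21 nt starting with the CATG anchor.
#'
#' @param sample_ids unique sample identifiers.
#' @param tags data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `sequence`.
#' @param counts integer matrix, samples by tags.
#' @return An object of class `tag_counts`.
#' @export
tag_counts <- function(sample_ids, tags, counts) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  stopifnot(all(c("id", "chrom", "start", "end", "strand") %in% names(tags)))
  if (anyDuplicated(tags$id)) stop("tag ids must be unique")
  if (any(tags$end < tags$start)) stop("tag end < start")
  if (!all(tags$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!is.null(tags$sequence)) {
    seqs <- tags$sequence
    has <- !is.na(seqs)
    if (any(has) && (any(nchar(seqs[has]) != 21L) ||
                     !all(startsWith(seqs[has], "CATG"))))
      stop("tag sequences must be 21 nt and begin with CATG")
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != length(sample_ids) || ncol(counts) != nrow(tags))
    stop("count dimensions do not match sample/tag metadata")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(sample_ids, tags$id)
  structure(list(sample_ids = sample_ids,
                 tags = as.data.frame(tags, stringsAsFactors = FALSE),
                 counts = counts),
            class = "tag_counts")
}

#' Genome annotation container
#'
#' Genes, transcripts, exons, 3'-UTRs, polyadenylation sites and repeat
#' elements on a shared reference.  All intervals are 0-based half-open;
#' polyA sites are 0-based single positions.
#'
#' @param genes data.frame `gene_id`, `name`, `biotype`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param transcripts data.frame `transcript_id`, `gene_id`.
#' @param exons data.frame `exon_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `rank` (transcription order, 1 = first).
#' @param utr3 data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param polya_sites data.frame `site_id`, `gene_id`, `chrom`, `pos`
#'   (0-based), `strand`, `status` in validated/predicted.
#' @param repeats data.frame `repeat_id`, `class` (LINE/SINE/LTR),
#'   `chrom`, `start`, `end`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, transcripts, exons, utr3,
                              polya_sites, repeats) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (any(exons$end < exons$start) || any(genes$end < genes$start))
    stop("interval end < start")
  if (nrow(polya_sites) && !all(polya_sites$status %in%
                                c("validated", "predicted")))
    stop("polyA site status must be validated or predicted")
  # exons must lie within their transcript's gene span
  tx2gene <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
  if (nrow(exons)) {
    g <- genes[match(tx2gene[exons$transcript_id], genes$gene_id), ]
    if (any(exons$start < g$start | exons$end > g$end, na.rm = TRUE))
      stop("exon outside its gene span")
  }
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 utr3 = utr3, polya_sites = polya_sites, repeats = repeats),
            class = "genome_annotation")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$snps), "SNPs\n")
  invisible(x)
}

#' @export
print.tag_counts <- function(x, ...) {
  cat("tag_counts:", length(x$sample_ids), "samples x",
      nrow(x$tags), "tags\n")
  invisible(x)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      nrow(x$exons), "exons,", nrow(x$polya_sites), "polyA sites,",
      nrow(x$repeats), "repeats\n")
  invisible(x)
}

#' Expression matrix container
#'
#' Real-valued descendant of a count matrix, tracking which transforms
#' have been applied (append-only state).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param state character vector of applied transforms.
#' @param features optional feature metadata data.frame (coordinates).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, state = character(), features = NULL) {
  values <- as.matrix(values)
  structure(list(values = values,
                 sample_ids = rownames(values),
                 feature_ids = colnames(values),
                 state = state,
                 features = features),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features; state:", paste(x$state, collapse = " -> "), "\n")
  invisible(x)
}

add_state <- function(expr, transform) {
  expr$state <- c(expr$state, transform)
  expr
}
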