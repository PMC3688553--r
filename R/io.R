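# On-disk formats.  Internal convention is 0-based half-open intervals
# everywhere; conversion happens only at the I/O boundary (BED is
# already 0-based half-open, GFF3 and VCF are 1-based inclusive).

#' Read genotypes from VCF or dosage TSV
#'
#' VCF GT fields are converted to alt-allele dosage (missing GT ->
#' missing); multi-allelic sites are skipped with a warning.  The TSV
#' layout is the one produced by [write_genotypes()]: columns `id`,
#' `chrom`, `pos`, `ref`, `alt`, then one dosage column per sample.
#'
#' @param path input file.
#' @param format "vcf" or "tsv".
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
    meta_cols <- c("id", "chrom", "pos", "ref", "alt")
    if (!all(meta_cols %in% names(d)))
      stop("genotype TSV must start with columns ",
           paste(meta_cols, collapse = ", "))
    samp <- setdiff(names(d), meta_cols)
    dos <- t(as.matrix(d[, samp, drop = FALSE]))
    bad <- which(!(dos %in% c(0, 1, 2) | is.na(dos)), arr.ind = TRUE)
    if (nrow(bad))
      stop("parse error: invalid dosage at data line ", bad[1, 2])
    return(genotype_matrix(samp, d[, meta_cols], dos))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr_i <- which(startsWith(body, "#CHROM"))
  if (!length(hdr_i)) stop("parse error: missing #CHROM header line")
  hdr <- strsplit(sub("^#", "", body[hdr_i]), "\t")[[1]]
  samp <- hdr[-(1:9)]
  rows <- body[-seq_len(hdr_i)]
  rows <- rows[nzchar(rows)]
  keep <- list(); dosr <- list()
  for (k in seq_along(rows)) {
    f <- strsplit(rows[k], "\t")[[1]]
    if (length(f) < 9 + length(samp))
      stop("parse error at VCF data line ", k)
    if (grepl(",", f[5], fixed = TRUE)) {
      warning("multi-allelic site skipped at data line ", k)
      next
    }
    gt_i <- match("GT", strsplit(f[9], ":")[[1]])
    if (is.na(gt_i)) stop("parse error: no GT field at data line ", k)
    gts <- vapply(strsplit(f[-(1:9)], ":"), `[`, character(1), gt_i)
    a <- strsplit(gts, "[/|]")
    dos <- vapply(a, function(x) {
      if (any(x == ".")) return(NA_real_)
      sum(as.numeric(x))
    }, numeric(1))
    keep[[length(keep) + 1L]] <- data.frame(
      id = f[3], chrom = f[1], pos = as.integer(f[2]), ref = f[4],
      alt = f[5], stringsAsFactors = FALSE)
    dosr[[length(dosr) + 1L]] <- dos
  }
  snps <- do.call(rbind, keep)
  genotype_matrix(samp, snps, t(do.call(rbind, dosr)))
}

#' Write genotypes as dosage TSV and/or VCF
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @param format "tsv" or "vcf" (GT field, unphased).
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(genotypes, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- cbind(genotypes$snps,
               as.data.frame(t(genotypes$dosages)))
    data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(path))
  }
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(genotypes$snps)), function(i) {
    d <- genotypes$dosages[, i]
    gt <- ifelse(is.na(d), "./.", gt_of[as.character(d)])
    s <- genotypes$snps[i, ]
    paste(c(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       genotypes$sample_ids), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Read a tag count matrix
#'
#' Expects the layout of [write_counts()]: tag metadata columns (`id`,
#' `chrom`, `start`, `end`, `strand`, optional `sequence`) followed by
#' one count column per sample.
#'
#' @param path input TSV.
#' @return A [tag_counts()].
#' @export
read_counts <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  meta_cols <- intersect(c("id", "chrom", "start", "end", "strand",
                           "sequence"), names(d))
  if (!all(c("id", "chrom", "start", "end", "strand") %in% meta_cols))
    stop("count TSV lacks tag coordinate columns")
  if (any(d$end < d$start))
    stop("parse error: end < start at data line ",
         which(d$end < d$start)[1])
  samp <- setdiff(names(d), meta_cols)
  tag_counts(samp, d[, meta_cols, drop = FALSE],
             t(as.matrix(d[, samp, drop = FALSE])))
}

#' @rdname read_counts
#' @param counts a [tag_counts()].
#' @export
write_counts <- function(counts, path) {
  d <- cbind(counts$tags, as.data.frame(t(counts$counts)))
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read annotation from GFF3 plus polyA-site and repeat BED
#'
#' GFF3 is 1-based inclusive and converted to the internal 0-based
#' half-open convention; BED is used as-is.  Gene biotype is taken from
#' the `biotype` attribute, exon order from `rank`.  PolyA-site BED
#' names are `site_id;gene_id;status`; repeat BED names are the repeat
#' class.
#'
#' @param gff_path GFF3 with gene/mRNA/exon/three_prime_UTR features.
#' @param polya_bed,repeat_bed BED files (may be absent -> empty).
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gff_path, polya_bed = NULL,
                            repeat_bed = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  pick <- function(type) df[df$type %in% type, , drop = FALSE]
  gdf <- pick("gene")
  genes <- data.frame(gene_id = gdf$ID,
                      name = if (!is.null(gdf$Name)) gdf$Name else gdf$ID,
                      biotype = if (!is.null(gdf$biotype)) gdf$biotype
                      else "protein_coding",
                      chrom = as.character(gdf$seqnames),
                      start = gdf$start - 1L, end = gdf$end,
                      strand = as.character(gdf$strand),
                      stringsAsFactors = FALSE)
  tdf <- pick(c("mRNA", "transcript"))
  transcripts <- data.frame(
    transcript_id = tdf$ID,
    gene_id = vapply(tdf$Parent, `[`, character(1), 1),
    stringsAsFactors = FALSE)
  edf <- pick("exon")
  exons <- data.frame(
    exon_id = if (!is.null(edf$ID)) edf$ID
    else sprintf("exon%05d", seq_len(nrow(edf))),
    transcript_id = vapply(edf$Parent, `[`, character(1), 1),
    chrom = as.character(edf$seqnames),
    start = edf$start - 1L, end = edf$end,
    strand = as.character(edf$strand),
    rank = if (!is.null(edf$rank)) as.integer(edf$rank)
    else seq_len(nrow(edf)),
    stringsAsFactors = FALSE)
  udf <- pick("three_prime_UTR")
  tx2gene <- stats::setNames(transcripts$gene_id,
                             transcripts$transcript_id)
  utr3 <- if (nrow(udf)) data.frame(
    gene_id = unname(tx2gene[vapply(udf$Parent, `[`, character(1), 1)]),
    chrom = as.character(udf$seqnames),
    start = udf$start - 1L, end = udf$end,
    strand = as.character(udf$strand), stringsAsFactors = FALSE)
  else data.frame(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  strand = character())
  read_bed <- function(path) {
    if (is.null(path) || is.na(path) || !file.exists(path) ||
        file.size(path) == 0) return(NULL)
    b <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE)
    if (ncol(b) < 3) stop("parse error: BED needs >= 3 columns")
    names(b)[1:3] <- c("chrom", "start", "end")
    if (any(b$end < b$start))
      stop("parse error: BED end < start at data line ",
           which(b$end < b$start)[1])
    b
  }
  pb <- read_bed(polya_bed)
  polya <- if (!is.null(pb) && nrow(pb)) {
    parts <- strsplit(as.character(pb[[4]]), ";", fixed = TRUE)
    data.frame(site_id = vapply(parts, `[`, character(1), 1),
               gene_id = vapply(parts, `[`, character(1), 2),
               chrom = pb$chrom, pos = pb$start,
               strand = as.character(pb[[6]]),
               status = vapply(parts, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  } else data.frame(site_id = character(), gene_id = character(),
                    chrom = character(), pos = integer(),
                    strand = character(), status = character())
  rb <- read_bed(repeat_bed)
  repeats <- if (!is.null(rb) && nrow(rb)) data.frame(
    repeat_id = sprintf("rep%05d", seq_len(nrow(rb))),
    class = as.character(rb[[4]]), chrom = rb$chrom,
    start = rb$start, end = rb$end, stringsAsFactors = FALSE)
  else data.frame(repeat_id = character(), class = character(),
                  chrom = character(), start = integer(),
                  end = integer())
  genome_annotation(genes, transcripts, exons, utr3, polya, repeats)
}

#' Write annotation to GFF3 and BED files
#'
#' @param annotation a [genome_annotation()].
#' @param gff_path output GFF3 path.
#' @param polya_bed,repeat_bed optional BED output paths.
#' @return Invisibly, `gff_path`.
#' @export
write_annotation <- function(annotation, gff_path, polya_bed = NULL,
                             repeat_bed = NULL) {
  esc <- function(x) gsub("[;=\t]", "_", x)
  g <- annotation$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tsageqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
                     g$chrom, g$start + 1L, g$end, g$strand,
                     esc(g$gene_id), esc(g$name), esc(g$biotype)))
  t <- annotation$transcripts
  gx <- g[match(t$gene_id, g$gene_id), ]
  lines <- c(lines,
             sprintf("%s\tsageqtl\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     gx$chrom, gx$start + 1L, gx$end, gx$strand,
                     esc(t$transcript_id), esc(t$gene_id)))
  e <- annotation$exons
  lines <- c(lines,
             sprintf("%s\tsageqtl\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;rank=%d",
                     e$chrom, e$start + 1L, e$end, e$strand,
                     esc(e$exon_id), esc(e$transcript_id), e$rank))
  u <- annotation$utr3
  if (nrow(u)) {
    tx <- t$transcript_id[match(u$gene_id, t$gene_id)]
    lines <- c(lines,
               sprintf("%s\tsageqtl\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tID=utr3_%s;Parent=%s",
                       u$chrom, u$start + 1L, u$end, u$strand,
                       esc(u$gene_id), esc(tx)))
  }
  writeLines(lines, gff_path)
  if (!is.null(polya_bed)) {
    p <- annotation$polya_sites
    writeLines(sprintf("%s\t%d\t%d\t%s;%s;%s\t0\t%s", p$chrom, p$pos,
                       p$pos + 1L, p$site_id, p$gene_id, p$status,
                       p$strand), polya_bed)
  }
  if (!is.null(repeat_bed)) {
    r <- annotation$repeats
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", r$chrom, r$start, r$end,
                       r$class), repeat_bed)
  }
  invisible(gff_path)
}

#' Write a genome as FASTA
#'
#' @param genome named `Biostrings::DNAStringSet` or named character
#'   vector.
#' @param path output FASTA.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read / write an expression matrix TSV
#'
#' Feature-per-row layout: `id`, `chrom`, `start`, `end`, then one
#' real-valued column per sample.
#'
#' @param path input/output TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  meta_cols <- intersect(c("id", "chrom", "start", "end"), names(d))
  if (!"id" %in% meta_cols) stop("expression TSV needs an id column")
  samp <- setdiff(names(d), meta_cols)
  m <- t(as.matrix(d[, samp, drop = FALSE]))
  colnames(m) <- d$id
  expression_matrix(m, features = d[, meta_cols, drop = FALSE])
}

#' @rdname read_expression
#' @param expr an [expression_matrix()].
#' @export
write_expression <- function(expr, path) {
  feats <- expr$features
  if (is.null(feats))
    feats <- data.frame(id = colnames(expr$values),
                        stringsAsFactors = FALSE)
  d <- cbind(feats, as.data.frame(t(expr$values)))
  data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param records data.frame of results (eQTL records, APA events, ...).
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}
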