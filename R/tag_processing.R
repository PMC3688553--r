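# Tag-level filtering, normalization and annotation.

#' Filter tags by presence and CATG-anchor SNPs
#'
#' Keeps tags with a non-zero count in strictly more than
#' `presence_fraction` of samples, and removes tags whose 4-bp CATG
#' anchor interval (strand-aware: the first four aligned bases of the
#' tag) overlaps any supplied SNP position, since such SNPs can move the
#' anchoring site.  Transcripts containing a removed CATG-SNP tag are
#' reported so they can be excluded from transcript-level summaries.
#'
#' @param counts a [tag_counts()].
#' @param snp_positions optional data.frame with `chrom` and `pos`
#'   (1-based) genomic SNP points.
#' @param config an [analysis_config()].
#' @param annotation optional [genome_annotation()]; when given, the
#'   result carries an `excluded_transcripts` attribute.
#' @return Filtered [tag_counts()].
#' @export
filter_tags <- function(counts, snp_positions = NULL,
                        config = analysis_config(), annotation = NULL) {
  stopifnot(inherits(counts, "tag_counts"))
  n <- length(counts$sample_ids)
  present <- colSums(counts$counts > 0)
  keep <- present > config$presence_fraction * n

  catg_hit <- rep(FALSE, nrow(counts$tags))
  if (!is.null(snp_positions) && nrow(snp_positions) > 0) {
    t <- counts$tags
    a_start <- ifelse(t$strand == "+", t$start, t$end - 4L)
    a_end <- a_start + 4L                     # [a_start, a_end) 0-based
    for (i in seq_len(nrow(t))) {
      s <- snp_positions[snp_positions$chrom == t$chrom[i], , drop = FALSE]
      if (nrow(s))
        catg_hit[i] <- any(s$pos - 1L >= a_start[i] & s$pos - 1L < a_end[i])
    }
  }
  keep <- keep & !catg_hit
  out <- tag_counts(counts$sample_ids, counts$tags[keep, , drop = FALSE],
                    counts$counts[, keep, drop = FALSE])
  if (!is.null(annotation) && any(catg_hit)) {
    bad <- counts$tags[catg_hit, , drop = FALSE]
    ov <- tag_exon_overlaps(bad, annotation, min_overlap = 1L)
    attr(out, "excluded_transcripts") <- unique(ov$transcript_id)
  } else {
    attr(out, "excluded_transcripts") <- character()
  }
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample's value distribution onto the across-sample mean
#' of sorted vectors; tied values within a sample receive the mean of
#' the reference values their ranks span.
#'
#' @param x a [tag_counts()], [expression_matrix()] or numeric matrix
#'   (samples in rows).
#' @return An [expression_matrix()] with state `quantile_normalized`.
#' @export
quantile_normalize <- function(x) {
  m <- as_values(x)
  if (anyNA(m)) stop("quantile normalization requires complete data")
  if (nrow(m) == 1L) {
    warning("single sample: quantile normalization is the identity")
    return(add_state(expression_matrix(m, state = state_of(x),
                                       features = features_of(x)),
                     "quantile_normalized"))
  }
  ref <- rowMeans(apply(m, 1L, sort))     # mean of sorted sample vectors
  out <- t(apply(m, 1L, function(v) {
    res <- numeric(length(v))
    res[order(v)] <- ref
    # tied values share the mean of the reference values they span
    stats::ave(res, v, FUN = mean)
  }))
  dimnames(out) <- dimnames(m)
  add_state(expression_matrix(out, state = state_of(x),
                              features = features_of(x)),
            "quantile_normalized")
}

#' Log2 transform, center and scale per feature
#'
#' Applies `log2(x + pseudocount)` and standardizes each feature to mean
#' 0, sd 1.  Zero-variance features are dropped with a warning.
#'
#' @param x matrix-like as in [quantile_normalize()]; values must be
#'   non-negative.
#' @param pseudocount added before the log (default 1).
#' @return An [expression_matrix()] with states `log2`,
#'   `centered_scaled` appended.
#' @export
log2_center_scale <- function(x, pseudocount = 1) {
  m <- as_values(x)
  if (any(m < 0, na.rm = TRUE)) stop("negative values in input")
  m <- log2(m + pseudocount)
  sds <- apply(m, 2L, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance feature(s) dropped")
    m <- m[, !drop, drop = FALSE]
  }
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  feats <- features_of(x)
  if (!is.null(feats)) feats <- feats[!drop, , drop = FALSE]
  add_state(add_state(expression_matrix(m, state = state_of(x),
                                        features = feats), "log2"),
            "centered_scaled")
}

#' Per-sample GC content of mapped tags
#'
#' For each sample, the count-weighted mean GC fraction of tag
#' sequences, after excluding that sample's `gc_exclude_top` most
#' abundant tags (their dominance would bias the estimate).
#'
#' @param counts a [tag_counts()] with tag sequences.
#' @param config an [analysis_config()].
#' @return Named numeric vector of per-sample GC fractions.
#' @export
gc_content_per_sample <- function(counts, config = analysis_config()) {
  stopifnot(inherits(counts, "tag_counts"))
  seqs <- counts$tags$sequence
  if (is.null(seqs) || anyNA(seqs)) stop("tag sequences are required")
  gc <- nchar(gsub("[^GCgc]", "", seqs)) / nchar(seqs)
  apply(counts$counts, 1L, function(v) {
    ord <- order(v, decreasing = TRUE)
    excl <- ord[seq_len(min(config$gc_exclude_top, length(v)))]
    keep <- setdiff(seq_along(v), excl)
    if (sum(v[keep]) == 0) return(NA_real_)
    sum(v[keep] * gc[keep]) / sum(v[keep])
  })
}

#' Annotate the genomic location of a tag
#'
#' Labels a tag as 3'-UTR / exon / intron crossed with sense/antisense
#' when it falls inside a gene (3'-UTR takes precedence over exon over
#' intron, using the tag midpoint for containment), otherwise as
#' intergenic with the nearest gene reported.  Overlap with repeat
#' elements (LINE/SINE/LTR) is annotated independently.
#'
#' @param tags data.frame with `id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open), e.g. `counts$tags`.
#' @param annotation a [genome_annotation()].
#' @return data.frame with columns `id`, `region`, `orientation`,
#'   `gene_id`, `nearest_gene`, `repeat_class`.
#' @export
annotate_tag_location <- function(tags, annotation) {
  g <- annotation$genes
  u <- annotation$utr3
  e <- annotation$exons
  mid <- floor((tags$start + tags$end) / 2)
  res <- data.frame(id = tags$id, region = "intergenic",
                    orientation = NA_character_,
                    gene_id = NA_character_,
                    nearest_gene = NA_character_,
                    repeat_class = "none", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tags))) {
    gi <- which(g$chrom == tags$chrom[i] & g$start <= mid[i] &
                  mid[i] < g$end)
    if (length(gi)) {
      gi <- gi[1]
      res$gene_id[i] <- g$gene_id[gi]
      res$orientation[i] <- if (g$strand[gi] == tags$strand[i]) "sense"
      else "antisense"
      in_utr <- any(u$gene_id == g$gene_id[gi] & u$start <= mid[i] &
                      mid[i] < u$end)
      tx <- annotation$transcripts$transcript_id[
        annotation$transcripts$gene_id == g$gene_id[gi]]
      in_exon <- any(e$transcript_id %in% tx & e$start <= mid[i] &
                       mid[i] < e$end)
      res$region[i] <- if (in_utr) "3'-UTR" else if (in_exon) "exon"
      else "intron"
    } else {
      gc <- g[g$chrom == tags$chrom[i], , drop = FALSE]
      if (nrow(gc)) {
        d <- pmax(gc$start - mid[i], mid[i] - gc$end, 0)
        res$nearest_gene[i] <- gc$gene_id[which.min(d)]
      }
    }
    r <- annotation$repeats
    ri <- which(r$chrom == tags$chrom[i] & r$start <= mid[i] &
                  mid[i] < r$end)
    if (length(ri)) res$repeat_class[i] <- r$class[ri[1]]
  }
  res
}

# overlap width of tags vs exons; returns (tag index, transcript_id, width)
tag_exon_overlaps <- function(tags, annotation, min_overlap) {
  e <- annotation$exons
  if (!nrow(e) || !nrow(tags))
    return(data.frame(tag = integer(), transcript_id = character(),
                      width = integer()))
  tg <- GenomicRanges::GRanges(tags$chrom,
                               IRanges::IRanges(tags$start + 1L, tags$end))
  eg <- GenomicRanges::GRanges(e$chrom,
                               IRanges::IRanges(e$start + 1L, e$end))
  ov <- GenomicRanges::findOverlaps(tg, eg,
                                    minoverlap = as.integer(min_overlap))
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(tg)[S4Vectors::queryHits(ov)],
    IRanges::ranges(eg)[S4Vectors::subjectHits(ov)]))
  data.frame(tag = S4Vectors::queryHits(ov),
             transcript_id = e$transcript_id[S4Vectors::subjectHits(ov)],
             width = w, stringsAsFactors = FALSE)
}

#' Summarize tag counts to transcripts
#'
#' Sums, per transcript, the counts of tags whose overlap with any of
#' the transcript's exons is at least half the tag length (ceiling: 11
#' of 21 bases).  A tag may contribute to several transcripts.
#'
#' @param counts a [tag_counts()].
#' @param annotation a [genome_annotation()].
#' @param exclude_transcripts transcript ids to drop (e.g. the
#'   CATG-SNP-flagged set from [filter_tags()]).
#' @return An [expression_matrix()] of transcript counts (samples x
#'   transcripts).
#' @export
summarize_transcripts_from_tags <- function(counts, annotation,
                                            exclude_transcripts =
                                              character()) {
  stopifnot(inherits(counts, "tag_counts"))
  tlen <- counts$tags$end - counts$tags$start
  half <- as.integer(ceiling(tlen / 2))
  ov <- tag_exon_overlaps(counts$tags, annotation, min_overlap = 1L)
  ov <- ov[ov$width >= half[ov$tag], , drop = FALSE]
  ov <- unique(ov[, c("tag", "transcript_id")])
  txs <- setdiff(annotation$transcripts$transcript_id, exclude_transcripts)
  out <- matrix(0, nrow = length(counts$sample_ids), ncol = length(txs),
                dimnames = list(counts$sample_ids, txs))
  for (tx in unique(ov$transcript_id)) {
    if (!tx %in% txs) next
    ti <- ov$tag[ov$transcript_id == tx]
    out[, tx] <- rowSums(counts$counts[, ti, drop = FALSE])
  }
  tx2gene <- annotation$transcripts
  mids <- vapply(txs, function(tx) {
    e <- annotation$exons[annotation$exons$transcript_id == tx, ,
                          drop = FALSE]
    if (!nrow(e)) return(c(NA_real_, NA_real_))
    c(min(e$start), max(e$end))
  }, numeric(2))
  feats <- data.frame(id = txs,
                      chrom = annotation$exons$chrom[
                        match(txs, annotation$exons$transcript_id)],
                      start = mids[1, ], end = mids[2, ],
                      gene_id = tx2gene$gene_id[match(txs,
                                                      tx2gene$transcript_id)],
                      stringsAsFactors = FALSE)
  expression_matrix(out, state = character(), features = feats)
}

#' Transcript expression from exon read coverage
#'
#' The transcript-level expression for a set of exon coverages is
#' `sum_e c_e * b_e`, where `c_e` is the number of reads overlapping
#' exon `e` by at least half the read length and `b_e` the breadth of
#' coverage (fraction of the exon covered).  Weighting by breadth
#' down-weights alternative exons only partly covered.
#'
#' @param exon_coverages data.frame with columns `count` and `breadth`.
#' @return Numeric scalar.
#' @export
quantify_transcript_from_reads <- function(exon_coverages) {
  if (is.null(exon_coverages) || nrow(exon_coverages) == 0) return(0)
  stopifnot(all(c("count", "breadth") %in% names(exon_coverages)),
            all(exon_coverages$count >= 0),
            all(exon_coverages$breadth >= 0 & exon_coverages$breadth <= 1))
  sum(exon_coverages$count * exon_coverages$breadth)
}

# ---- small matrix-view helpers ------------------------------------------

as_values <- function(x) {
  if (inherits(x, "tag_counts")) x$counts
  else if (inherits(x, "expression_matrix")) x$values
  else as.matrix(x)
}

state_of <- function(x) {
  if (inherits(x, "expression_matrix")) x$state else character()
}

features_of <- function(x) {
  if (inherits(x, "tag_counts"))
    data.frame(id = x$tags$id, chrom = x$tags$chrom, start = x$tags$start,
               end = x$tags$end, stringsAsFactors = FALSE)
  else if (inherits(x, "expression_matrix")) x$features
  else NULL
}
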