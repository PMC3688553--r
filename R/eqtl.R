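# Cis-eQTL mapping: Spearman rank association of SNP dosage with tag (or
# transcript) expression within a 250 kb window of the feature midpoint,
# with tag-level FDR control from sample-label permutations.

#' Enumerate cis SNP-feature pairs
#'
#' A pair is tested when SNP and feature share a chromosome and the SNP
#' lies within `window_bp` of the feature midpoint
#' (`floor((start + end) / 2)`, 0-based); the window boundary is
#' inclusive.
#'
#' @param snps data.frame with `id`, `chrom`, `pos` (1-based).
#' @param features data.frame with `id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window_bp window half-width in bp.
#' @return data.frame with `snp_id`, `feature_id`, `snp_idx`,
#'   `feature_idx`, `distance`.
#' @export
enumerate_cis_pairs <- function(snps, features, window_bp = 250000L) {
  mid <- floor((features$start + features$end) / 2)
  out <- list()
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    si <- which(snps$chrom == ch)
    if (!length(fi) || !length(si)) next
    sp <- snps$pos[si] - 1L               # to 0-based
    sg <- GenomicRanges::GRanges(ch, IRanges::IRanges(sp, width = 1L))
    fg <- GenomicRanges::GRanges(ch, IRanges::IRanges(mid[fi], width = 1L))
    ov <- GenomicRanges::findOverlaps(sg, fg,
                                      maxgap = as.integer(window_bp))
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    d <- abs(sp[q] - mid[fi][s])
    keep <- d <= window_bp
    out[[length(out) + 1L]] <- data.frame(
      snp_id = snps$id[si][q][keep], feature_id = features$id[fi][s][keep],
      snp_idx = si[q][keep], feature_idx = fi[s][keep],
      distance = d[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(snp_id = character(), feature_id = character(),
                      snp_idx = integer(), feature_idx = integer(),
                      distance = integer()))
  do.call(rbind, out)
}

#' Spearman association of dosage with expression
#'
#' Tie-corrected Spearman correlation (Pearson on average ranks) with a
#' two-sided p-value from the t approximation and a signed
#' standard-normal deviate `z = sign(rho) * qnorm(1 - p/2)`.  Missing
#' values are dropped pairwise.
#'
#' @param dosage numeric vector of alt-allele dosages.
#' @param expression numeric vector.
#' @param min_samples minimum non-missing pairs required.
#' @return list with `rho`, `p`, `z`, `n_used` (all NA when the test is
#'   not possible, e.g. zero variance).
#' @export
spearman_assoc <- function(dosage, expression, min_samples = 10L) {
  ok <- !is.na(dosage) & !is.na(expression)
  n <- sum(ok)
  na <- list(rho = NA_real_, p = NA_real_, z = NA_real_, n_used = n)
  if (n < max(min_samples, 3L)) return(na)
  x <- rank(dosage[ok]); y <- rank(expression[ok])
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(na)
  rho <- stats::cov(x, y) / (sx * sy)
  rho <- max(min(rho, 1), -1)
  if (abs(rho) == 1) {
    p <- .Machine$double.xmin
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE),
             .Machine$double.xmin)
  }
  z <- sign(rho) * stats::qnorm(p / 2, lower.tail = FALSE)
  list(rho = rho, p = p, z = z, n_used = n)
}

# rank each column and standardize to zero mean, unit L2 norm so that
# crossprod(Zx, Zy) is the Spearman correlation matrix.  Zero-variance
# columns come back as all-zero with attribute "invalid".
rank_standardize <- function(m) {
  r <- apply(m, 2L, rank)
  r <- sweep(r, 2L, colMeans(r))
  nrm <- sqrt(colSums(r^2))
  bad <- nrm == 0
  nrm[bad] <- 1
  z <- sweep(r, 2L, nrm, "/")
  z[, bad] <- 0
  attr(z, "invalid") <- bad
  z
}

p_from_rho <- function(rho, n) {
  rho <- pmax(pmin(rho, 1), -1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)   # keep p in (0, 1] so z stays finite
}

# internal: align genotype and expression samples, apply the MAF filter,
# and build the cis pair table plus rank-standardized matrices
prepare_assoc <- function(genotypes, expr, features, config) {
  ev <- as_values(expr)
  samp <- intersect(genotypes$sample_ids, rownames(ev))
  if (is.null(rownames(ev)) &&
      nrow(ev) == length(genotypes$sample_ids)) {
    samp <- genotypes$sample_ids
    rownames(ev) <- samp
  }
  if (!length(samp)) stop("no shared samples between genotypes and expression")
  dos <- genotypes$dosages[samp, , drop = FALSE]
  ev <- ev[samp, , drop = FALSE]
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= config$maf_min & maf > 0
  snps <- genotypes$snps[keep, , drop = FALSE]
  dos <- dos[, keep, drop = FALSE]
  pairs <- enumerate_cis_pairs(snps, features, config$cis_window_bp)
  list(samples = samp, snps = snps, dosages = dos, values = ev,
       features = features, pairs = pairs)
}

# internal: Spearman rho for all cis pairs given prepared inputs; `perm`
# optionally permutes the expression sample labels
assoc_all_pairs <- function(prep, perm = NULL) {
  ev <- prep$values
  if (!is.null(perm)) ev <- ev[perm, , drop = FALSE]
  n <- nrow(ev)
  if (anyNA(prep$dosages) || anyNA(ev)) {
    rho <- mapply(function(si, fi) {
      spearman_assoc(prep$dosages[, si], ev[, fi], min_samples = 4L)$rho
    }, prep$pairs$snp_idx_local, prep$pairs$feature_idx)
    return(list(rho = rho, n = n))
  }
  zg <- rank_standardize(prep$dosages)
  ze <- rank_standardize(ev)
  badg <- attr(zg, "invalid"); bade <- attr(ze, "invalid")
  rho_m <- crossprod(zg, ze)
  rho <- rho_m[cbind(prep$pairs$snp_idx_local, prep$pairs$feature_idx)]
  rho[badg[prep$pairs$snp_idx_local] | bade[prep$pairs$feature_idx]] <-
    NA_real_
  list(rho = rho, n = n)
}

#' Map cis-eQTLs
#'
#' Tests every SNP-feature pair within the cis window with a Spearman
#' rank correlation.  Returns one record per tested pair with rho, p,
#' signed z (sign relative to the alt-allele dosage) and the best
#' (minimum-p) SNP per feature.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expr an [expression_matrix()], [tag_counts()] or matrix
#'   (samples x features).
#' @param features feature coordinates; defaults to the expression
#'   matrix's own feature table.
#' @param config an [analysis_config()].
#' @return list of class `eqtl_result` with `records` (data.frame),
#'   `best` (per-feature best record) and `n_samples`.
#' @export
map_cis_eqtls <- function(genotypes, expr, features = NULL,
                          config = analysis_config()) {
  if (is.null(features)) features <- features_of(expr)
  if (is.null(features)) stop("feature coordinates are required")
  prep <- prepare_assoc(genotypes, expr, features, config)
  prep$pairs$snp_idx_local <- match(prep$pairs$snp_id, prep$snps$id)
  a <- assoc_all_pairs(prep)
  p <- p_from_rho(a$rho, a$n)
  z <- sign(a$rho) * stats::qnorm(p / 2, lower.tail = FALSE)
  z[!is.na(a$rho) & a$rho == 0] <- 0
  rec <- data.frame(snp_id = prep$pairs$snp_id,
                    feature_id = prep$pairs$feature_id,
                    n_used = a$n, rho = a$rho, p = p, z = z,
                    allele_assessed =
                      prep$snps$alt[prep$pairs$snp_idx_local],
                    distance = prep$pairs$distance,
                    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$rho), , drop = FALSE]
  best <- rec[order(rec$feature_id, rec$p), , drop = FALSE]
  best <- best[!duplicated(best$feature_id), , drop = FALSE]
  structure(list(records = rec, best = best, n_samples = a$n,
                 prep = prep),
            class = "eqtl_result")
}

#' Permutation-based tag-level FDR
#'
#' Builds the null by shuffling expression sample labels (one shuffle
#' per permutation, shared by all features, which breaks the
#' genotype-expression link while preserving LD and expression
#' covariance) and re-running the cis scan.  For each candidate
#' threshold t, `FDR(t)` is the mean number of null features with
#' minimum p <= t divided by the number of real features with minimum
#' p <= t; the chosen p threshold is the largest t with `FDR(t) <=
#' config$fdr`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expr expression as in [map_cis_eqtls()].
#' @param features feature coordinates.
#' @param config an [analysis_config()].
#' @param seed integer seed for the permutations.
#' @param result optionally a precomputed `eqtl_result` for the real
#'   data (avoids recomputation).
#' @return list of class `fdr_result_set` with `fdr_result`
#'   (`p_threshold`, `n_real_significant`, `mean_null_significant`,
#'   `fdr`), `records` (real records with a `significant` flag),
#'   `best` (per-feature best with flags) and `null_min_p`.
#' @export
permutation_fdr <- function(genotypes, expr, features = NULL,
                            config = analysis_config(), seed = 1L,
                            result = NULL) {
  if (is.null(result)) result <- map_cis_eqtls(genotypes, expr,
                                               features, config)
  prep <- result$prep
  real_minp <- result$best$p
  null_minp <- c()
  set.seed(as.integer(seed))
  n <- length(prep$samples)
  for (b in seq_len(config$n_permutations)) {
    perm <- sample.int(n)
    a <- assoc_all_pairs(prep, perm = perm)
    p <- p_from_rho(a$rho, a$n)
    mp <- suppressWarnings(tapply(p, prep$pairs$feature_id, min,
                                  na.rm = TRUE))
    null_minp <- c(null_minp, as.numeric(mp[is.finite(mp)]))
  }
  ts <- sort(unique(real_minp))
  null_sorted <- sort(null_minp)
  n_null <- findInterval(ts, null_sorted) / config$n_permutations
  n_real <- findInterval(ts, sort(real_minp))
  fdr_t <- n_null / pmax(n_real, 1)
  ok <- which(fdr_t <= config$fdr)
  if (length(ok)) {
    p_thr <- ts[max(ok)]
    nsig <- n_real[max(ok)]
    mnull <- n_null[max(ok)]
    fdr_at <- fdr_t[max(ok)]
  } else {
    p_thr <- 0; nsig <- 0L; mnull <- 0; fdr_at <- 0
  }
  best <- result$best
  best$significant <- best$p <= p_thr
  rec <- result$records
  rec$significant <- rec$p <= p_thr
  structure(list(fdr_result = list(p_threshold = p_thr,
                                   n_real_significant = as.integer(nsig),
                                   mean_null_significant = mnull,
                                   fdr = fdr_at),
                 records = rec, best = best, null_min_p = null_minp),
            class = "fdr_result_set")
}

#' Filter eQTL records by a SNP list
#'
#' Generic helper for trait-associated-SNP style queries: keep the
#' records whose SNP is in a supplied list (e.g. a GWAS catalog
#' extract).
#'
#' @param records data.frame with an `snp_id` column.
#' @param snp_ids character vector of SNP ids to keep.
#' @return The filtered records.
#' @export
filter_records_by_snps <- function(records, snp_ids) {
  records[records$snp_id %in% snp_ids, , drop = FALSE]
}

#' Cross-dataset replication of eQTLs
#'
#' For each significant record of dataset A, reports whether dataset B
#' reaches its own FDR threshold for the same (SNP, feature) pair with
#' the same sign of z for the same assessed allele.
#'
#' @param records_a data.frame of significant A records (needs
#'   `snp_id`, `feature_id`, `z`, `allele_assessed`).
#' @param records_b data.frame of B records with a `significant` flag.
#' @return list with `table` (per-record outcome), `replication_fraction`
#'   and `direction_concordance` (among replicated records).
#' @export
replicate_eqtls <- function(records_a, records_b) {
  key <- function(d) paste(d$snp_id, d$feature_id, sep = "\r")
  i <- match(key(records_a), key(records_b))
  if (all(is.na(i))) {
    warning("no shared (SNP, feature) pairs between datasets")
    return(list(table = data.frame(), replication_fraction = NA_real_,
                direction_concordance = NA_real_))
  }
  b <- records_b[i, , drop = FALSE]
  same_allele <- records_a$allele_assessed == b$allele_assessed
  zb <- ifelse(same_allele, b$z, -b$z)
  tab <- data.frame(snp_id = records_a$snp_id,
                    feature_id = records_a$feature_id,
                    z_a = records_a$z, z_b = zb,
                    replicated = !is.na(i) & b$significant %in% TRUE,
                    concordant = !is.na(zb) &
                      sign(records_a$z) == sign(zb),
                    stringsAsFactors = FALSE)
  rep_frac <- mean(tab$replicated)
  conc <- if (any(tab$replicated))
    mean(tab$concordant[tab$replicated]) else NA_real_
  list(table = tab, replication_fraction = rep_frac,
       direction_concordance = conc)
}
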