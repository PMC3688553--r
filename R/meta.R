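# Weighted Z-score meta-analysis across sequencing-based eQTL datasets.

#' Harmonize assessed alleles across datasets
#'
#' Expresses every dataset's signed z relative to one assessed allele
#' per SNP (taken from the first dataset carrying the SNP).  Records
#' assessing the other allele have their z negated; records whose
#' allele set cannot be reconciled are dropped with a warning.
#' Strand-ambiguous SNPs (A/T or C/G) are flagged.
#'
#' @param inputs list of dataset records; each element is a data.frame
#'   with `snp_id`, `feature_id`, `z`, `allele_assessed`, `ref`, `alt`.
#' @return The list with aligned `z` signs and an added
#'   `strand_ambiguous` flag.
#' @export
harmonize_alleles <- function(inputs) {
  ref_allele <- list()
  for (d in seq_along(inputs)) {
    rec <- inputs[[d]]
    keep <- rep(TRUE, nrow(rec))
    amb <- rep(FALSE, nrow(rec))
    for (i in seq_len(nrow(rec))) {
      alleles <- sort(c(rec$ref[i], rec$alt[i]))
      amb[i] <- identical(alleles, c("A", "T")) ||
        identical(alleles, c("C", "G"))
      sid <- rec$snp_id[i]
      if (is.null(ref_allele[[sid]])) {
        ref_allele[[sid]] <- list(assessed = rec$allele_assessed[i],
                                  alleles = alleles)
      } else {
        anchor <- ref_allele[[sid]]
        if (!setequal(alleles, anchor$alleles)) {
          keep[i] <- FALSE
          next
        }
        if (rec$allele_assessed[i] != anchor$assessed) {
          rec$z[i] <- -rec$z[i]
          rec$allele_assessed[i] <- anchor$assessed
        }
      }
    }
    if (any(!keep))
      warning(sum(!keep), " record(s) dropped: irreconcilable alleles")
    rec$strand_ambiguous <- amb
    inputs[[d]] <- rec[keep, , drop = FALSE]
  }
  inputs
}

#' Combine signed Z-scores with square-root-of-n weights
#'
#' `z_meta = sum(sqrt(n_i) * z_i) / sqrt(sum(n_i))`, with a two-sided
#' normal p-value.  With equal sample sizes this reduces to the
#' unweighted Stouffer combination.
#'
#' @param z_list numeric vector of per-dataset signed z-scores.
#' @param n_list integer vector of per-dataset sample sizes (>= 2).
#' @return list with `z_meta` and `p_meta`.
#' @export
combine_weighted_z <- function(z_list, n_list) {
  if (!length(z_list)) stop("empty z list")
  if (length(z_list) != length(n_list)) stop("z and n lengths differ")
  if (any(n_list < 2)) stop("each dataset needs n >= 2")
  z_meta <- sum(sqrt(n_list) * z_list) / sqrt(sum(n_list))
  p_meta <- max(2 * stats::pnorm(abs(z_meta), lower.tail = FALSE),
                .Machine$double.xmin)
  list(z_meta = z_meta, p_meta = p_meta)
}

# combine record tables (already harmonized) for one analysis pass
combine_records <- function(tabs, ns, exclude_ambiguous = TRUE) {
  for (d in seq_along(tabs)) tabs[[d]]$dataset <- d
  all <- do.call(rbind, lapply(tabs, function(t)
    t[, c("snp_id", "feature_id", "z", "dataset",
          if ("strand_ambiguous" %in% names(t)) "strand_ambiguous"),
      drop = FALSE]))
  if (exclude_ambiguous && "strand_ambiguous" %in% names(all))
    all <- all[!all$strand_ambiguous, , drop = FALSE]
  key <- paste(all$snp_id, all$feature_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    sub <- all[idx, , drop = FALSE]
    cw <- combine_weighted_z(sub$z, ns[sub$dataset])
    data.frame(snp_id = sub$snp_id[1], feature_id = sub$feature_id[1],
               z_meta = cw$z_meta, p_meta = cw$p_meta,
               n_datasets_used = nrow(sub), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weighted Z-score meta-analysis with permutation FDR
#'
#' Maps cis-eQTLs in each dataset, harmonizes allele directions,
#' combines per-pair z-scores with square-root-of-n weights, and
#' controls the FDR on feature-level minimum meta p-values against a
#' permutation null in which each dataset's expression labels are
#' shuffled independently per permutation (combined with the same
#' weights, keeping the null honest across platforms).
#'
#' @param datasets list of datasets, each a list with `genotypes`,
#'   `expr`, `features` and optionally `n` (defaults to the number of
#'   shared samples).
#' @param config an [analysis_config()].
#' @param seed permutation seed.
#' @return list with `results` (per-pair meta records), `best`
#'   (per-feature best with `significant` flag) and `fdr_result`.
#' @export
run_meta <- function(datasets, config = analysis_config(), seed = 1L) {
  preps <- list(); ns <- integer(length(datasets))
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    prep <- prepare_assoc(ds$genotypes, ds$expr,
                          if (is.null(ds$features))
                            features_of(ds$expr) else ds$features,
                          config)
    prep$pairs$snp_idx_local <- match(prep$pairs$snp_id, prep$snps$id)
    preps[[d]] <- prep
    ns[d] <- if (is.null(ds$n)) length(prep$samples) else ds$n
  }
  pass <- function(perm_seeds = NULL) {
    tabs <- lapply(seq_along(preps), function(d) {
      prep <- preps[[d]]
      perm <- NULL
      if (!is.null(perm_seeds)) {
        set.seed(perm_seeds[d])
        perm <- sample.int(length(prep$samples))
      }
      a <- assoc_all_pairs(prep, perm = perm)
      p <- p_from_rho(a$rho, a$n)
      data.frame(snp_id = prep$pairs$snp_id,
                 feature_id = prep$pairs$feature_id,
                 z = sign(a$rho) * stats::qnorm(p / 2,
                                                lower.tail = FALSE),
                 allele_assessed =
                   preps[[d]]$snps$alt[prep$pairs$snp_idx_local],
                 ref = preps[[d]]$snps$ref[prep$pairs$snp_idx_local],
                 alt = preps[[d]]$snps$alt[prep$pairs$snp_idx_local],
                 stringsAsFactors = FALSE)[!is.na(a$rho), , drop = FALSE]
    })
    combine_records(harmonize_alleles(tabs), ns)
  }
  real <- pass()
  best <- real[order(real$feature_id, real$p_meta), , drop = FALSE]
  best <- best[!duplicated(best$feature_id), , drop = FALSE]
  set.seed(as.integer(seed))
  null_minp <- c()
  for (b in seq_len(config$n_permutations)) {
    ps <- sample.int(2^30, length(preps))
    nullr <- pass(perm_seeds = ps)
    mp <- tapply(nullr$p_meta, nullr$feature_id, min)
    null_minp <- c(null_minp, as.numeric(mp))
  }
  ts <- sort(unique(best$p_meta))
  n_null <- findInterval(ts, sort(null_minp)) / config$n_permutations
  n_real <- findInterval(ts, sort(best$p_meta))
  fdr_t <- n_null / pmax(n_real, 1)
  ok <- which(fdr_t <= config$fdr)
  p_thr <- if (length(ok)) ts[max(ok)] else 0
  best$significant <- best$p_meta <= p_thr
  real$significant <- real$p_meta <= p_thr
  list(results = real, best = best,
       fdr_result = list(p_threshold = p_thr,
                         n_real_significant = sum(best$significant),
                         mean_null_significant =
                           if (length(ok)) n_null[max(ok)] else 0,
                         fdr = if (length(ok)) fdr_t[max(ok)] else 0))
}
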