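# Principal-component confounder correction.
#
# PCA is performed on the sample-by-sample Pearson correlation matrix of
# the (log2, centered, scaled) expression matrix, so the "eigenvector
# coefficients" live in sample space.  Leading components capture
# technical and physiological variability (GC content, cell counts,
# batch); regressing them out of each feature increases cis-eQTL power.

#' PCA on the sample correlation matrix
#'
#' Eigendecomposition of the sample-by-sample Pearson correlation matrix
#' computed across features.  The sign of each component is fixed so its
#' largest-magnitude coefficient is positive, making results
#' deterministic.
#'
#' @param expr an [expression_matrix()] (samples x features), normally
#'   log2-transformed, centered and scaled per feature.
#' @return list of class `pca_result` with `eigenvalues` (descending),
#'   `sample_coefficients` (samples x PCs, orthonormal columns) and
#'   `variance_explained`.
#' @export
compute_sample_pca <- function(expr) {
  m <- as_values(expr)
  if (nrow(m) < 3L) stop("need at least 3 samples for PCA")
  cc <- stats::cor(t(m))
  ed <- eigen(cc, symmetric = TRUE)
  vec <- ed$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  ev <- pmax(ed$values, 0)
  rownames(vec) <- rownames(m)
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))
  structure(list(eigenvalues = ev,
                 sample_coefficients = vec,
                 variance_explained = ev / sum(ev)),
            class = "pca_result")
}

#' Correlate principal components with sample covariates
#'
#' Pearson correlation (pairwise-complete) between each PC's sample
#' coefficients and each covariate, with two-sided p-values.  Used to
#' identify which components track known confounders (per-sample GC
#' content, blood cell counts, ...).
#'
#' @param pca a `pca_result`.
#' @param covariates data.frame or matrix of sample covariates (rows
#'   aligned to the PCA's samples).
#' @param n_pcs number of leading PCs to test.
#' @return data.frame with columns `pc`, `covariate`, `r`, `p`.
#' @export
correlate_pcs_with_covariates <- function(pca, covariates,
                                          n_pcs = 10L) {
  cv <- as.matrix(covariates)
  if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
  n_pcs <- min(n_pcs, ncol(pca$sample_coefficients))
  out <- list()
  for (j in seq_len(n_pcs)) {
    for (k in seq_len(ncol(cv))) {
      x <- pca$sample_coefficients[, j]
      y <- cv[, k]
      ok <- !is.na(y)
      if (sum(ok) < 3 || stats::sd(y[ok]) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          pc = j, covariate = colnames(cv)[k], r = NA_real_, p = NA_real_)
        next
      }
      ct <- stats::cor.test(x[ok], y[ok])
      out[[length(out) + 1L]] <- data.frame(
        pc = j, covariate = colnames(cv)[k],
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  do.call(rbind, out)
}

#' Residualize expression on leading principal components
#'
#' Replaces each feature by its least-squares residual on the first
#' `n_pcs` sample-coefficient vectors (plus intercept).  Residuals are
#' orthogonal to the removed components; the operation is idempotent and
#' `n_pcs = 0` is the identity.
#'
#' @param expr an [expression_matrix()].
#' @param pca a `pca_result` computed from the same samples.
#' @param n_pcs number of leading PCs to remove; must be `<
#'   n_samples - 1`.
#' @param covariates optional sample-by-k matrix of known covariates
#'   (cell counts, GC content, ...) regressed out alongside the PCs;
#'   off by default.
#' @return An [expression_matrix()] with state `pc_residualized`.
#' @export
residualize <- function(expr, pca, n_pcs, covariates = NULL) {
  m <- as_values(expr)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs == 0L && is.null(covariates)) return(expr)
  if (n_pcs >= nrow(m) - 1L)
    stop("n_pcs must be smaller than n_samples - 1")
  v <- pca$sample_coefficients[, seq_len(n_pcs), drop = FALSE]
  x <- cbind(1, v)
  if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
  # hat projection: residual = (I - X (X'X)^-1 X') M
  resid <- m - x %*% solve(crossprod(x), crossprod(x, m))
  dimnames(resid) <- dimnames(m)
  add_state(expression_matrix(resid, state = state_of(expr),
                              features = features_of(expr)),
            "pc_residualized")
}

#' Sweep the number of removed PCs against eQTL yield
#'
#' Utility that maps cis-eQTLs after removing `0..k_max` leading PCs and
#' reports the number of FDR-significant features for each choice, so a
#' user can pick the argmax.
#'
#' @param genotypes a [genotype_matrix()].
#' @param expr an [expression_matrix()] (quantile-normalized counts).
#' @param features feature coordinate data.frame (see
#'   [map_cis_eqtls()]).
#' @param config an [analysis_config()].
#' @param k_values candidate numbers of PCs to remove.
#' @param seed permutation seed.
#' @return data.frame with `n_pcs` and `n_significant`.
#' @export
sweep_pc_removal <- function(genotypes, expr, features,
                             config = analysis_config(),
                             k_values = c(0L, 1L, 2L, 5L, 10L),
                             seed = 1L) {
  base <- log2_center_scale(expr, config$log2_pseudocount)
  pca <- compute_sample_pca(base)
  out <- lapply(k_values, function(k) {
    ex <- if (k == 0L) expr else {
      r <- residualize(base, pca, k)
      r
    }
    fdr <- permutation_fdr(genotypes, ex, features, config, seed = seed)
    data.frame(n_pcs = k, n_significant = fdr$fdr_result$n_real_significant)
  })
  do.call(rbind, out)
}
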