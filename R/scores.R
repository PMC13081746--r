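#' Beta-value / M-value conversion
#'
#' `M = log2(beta / (1 - beta))`; the inverse is
#' `beta = 2^M / (2^M + 1)`. M-values reduce the non-normality of
#' methylation proportions near the boundaries and are the modelling
#' scale; beta values are the reporting scale.
#'
#' @param beta numeric vector/matrix strictly in (0, 1).
#' @param m numeric vector/matrix of M-values.
#' @return the converted values, same shape as the input.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    stop_invalid("beta values must be strictly in (0, 1)")
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # numerically stable logistic: 2^m / (2^m + 1) = 1 / (1 + 2^-m)
  1 / (1 + 2^(-m))
}

#' Compute raw polygenic scores from a weight table
#'
#' `raw_score_i = sum_j weight_j * dosage_ij` after allele harmonization:
#' where the weight table's effect allele is the dosage panel's other
#' allele (and vice versa), the dosage is flipped (`d -> 2 - d`). A SNP
#' whose alleles match in neither orientation is an error; strand flips
#' are never guessed. Weight rows with `NA` weights (e.g. SNPs dropped in
#' the reference GWAS) are skipped.
#'
#' @param dosages matrix of effect-allele dosages, samples x SNPs, with
#'   SNP ids as column names.
#' @param weights a `weight_set` (or data.frame with `snp_id`,
#'   `effect_allele`, `other_allele`, `weight`).
#' @param panel a `snp_panel` (or data.frame with `snp_id`,
#'   `effect_allele`, `other_allele`) describing the allele coding of
#'   `dosages`.
#' @return numeric vector of raw scores (grams scale), named by sample.
#' @export
compute_pgs <- function(dosages, weights, panel) {
  if (anyDuplicated(weights$snp_id)) {
    stop_invalid(
      "duplicate SNP ids in weight set: ",
      paste(unique(weights$snp_id[duplicated(weights$snp_id)]), collapse = ", ")
    )
  }
  weights <- weights[!is.na(weights$weight), , drop = FALSE]
  idx <- match(weights$snp_id, panel$snp_id)
  if (anyNA(idx)) {
    stop_invalid(
      "weight-set SNPs absent from the dosage panel: ",
      paste(weights$snp_id[is.na(idx)], collapse = ", ")
    )
  }
  same <- weights$effect_allele == panel$effect_allele[idx] &
    weights$other_allele == panel$other_allele[idx]
  flipped <- weights$effect_allele == panel$other_allele[idx] &
    weights$other_allele == panel$effect_allele[idx]
  if (any(!same & !flipped)) {
    stop_invalid(
      "unresolvable allele mismatch for SNP(s): ",
      paste(weights$snp_id[!same & !flipped], collapse = ", ")
    )
  }
  D <- dosages[, weights$snp_id, drop = FALSE]
  if (any(flipped)) {
    D[, flipped] <- 2 - D[, flipped]
  }
  as.vector(D %*% weights$weight)
}

#' Genetic principal components of a dosage matrix
#'
#' Principal components of the column-standardized dosage matrix via
#' singular value decomposition. SNPs with zero variance are dropped with
#' a warning. Component signs are fixed by making each component's
#' largest-magnitude loading positive.
#'
#' @param dosages samples x SNPs dosage matrix.
#' @param k number of components (default 10, the conventional number of
#'   ancestry components adjusted for in polygenic-score analyses).
#' @return list of class `"pc_basis"`: `loadings` (SNP x k, unit norm),
#'   `scores` (sample x k), `k`, `d` (singular values).
#' @export
compute_genetic_pcs <- function(dosages, k = 10) {
  n <- nrow(dosages)
  v <- apply(dosages, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance SNP(s) dropped before PCA")
    dosages <- dosages[, v > 0, drop = FALSE]
  }
  if (n < k + 1) stop_invalid("need at least k + 1 samples")
  if (k >= min(n, ncol(dosages))) {
    stop_invalid("k must be < min(n_samples, n_snps)")
  }
  X <- scale(dosages)
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(
    seq_len(k),
    function(j) sign(sv$v[which.max(abs(sv$v[, j])), j]),
    numeric(1)
  )
  loadings <- sweep(sv$v, 2, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  rownames(scores) <- rownames(dosages)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(loadings = loadings, scores = scores, k = k, d = sv$d[seq_len(k)]),
    class = "pc_basis"
  )
}

#' Residualize a z-scored polygenic score on genetic principal components
#'
#' The raw score is z-scored (sample n-1 SD) and regressed on the first
#' `k` PC score columns plus an intercept; the residuals are re-scaled
#' to unit sample SD, giving standardized scores orthogonal to ancestry
#' (what downstream models use, so coefficients stay per-SD).
#' Residualizing an already-residualized score changes nothing.
#'
#' @param raw_score numeric vector of raw PGS values.
#' @param pc_basis a [compute_genetic_pcs()] result (or a numeric matrix
#'   of PC scores with matching rows).
#' @return numeric vector of residualized standardized scores.
#' @export
residualize_pgs <- function(raw_score, pc_basis) {
  scores <- if (inherits(pc_basis, "pc_basis")) pc_basis$scores else pc_basis
  if (length(raw_score) != nrow(scores)) {
    stop_invalid("score and PC basis cover different samples")
  }
  z <- zscore(raw_score)
  res <- stats::lm.fit(cbind(1, scores), z)$residuals
  res / stats::sd(res)
}

#' Nearest-neighbour imputation of a methylation matrix
#'
#' Each missing entry of a CpG row is replaced by the mean of that
#' sample's values in the `k` nearest CpG rows (Euclidean distance on the
#' samples observed in both rows, scaled to the full sample count), the
#' convention of nearest-neighbour averaging for array data. Intended to
#' be applied per array subcohort.
#'
#' @param beta CpGs x samples matrix in (0, 1) with `NA`s.
#' @param k number of neighbouring CpG rows (default 10).
#' @param max_missing per-CpG missingness ceiling (fraction; default 0.5).
#' @return completed matrix; imputed entries remain in (0, 1).
#' @export
knn_impute_methylation <- function(beta, k = 10, max_missing = 0.5) {
  miss <- is.na(beta)
  if (!any(miss)) return(beta)
  frac <- rowMeans(miss)
  if (any(frac == 1)) {
    stop_invalid(
      "CpG(s) missing in every sample: ",
      paste(rownames(beta)[frac == 1], collapse = ", ")
    )
  }
  if (any(frac > max_missing)) {
    stop_invalid(
      "CpG(s) exceed the missingness ceiling (", max_missing, "): ",
      paste(rownames(beta)[frac > max_missing], collapse = ", ")
    )
  }
  incomplete <- which(rowSums(miss) > 0)
  n_samp <- ncol(beta)
  for (i in incomplete) {
    obs_i <- !miss[i, ]
    # distances to all other rows over shared observed samples
    diffs <- sweep(beta[-i, , drop = FALSE], 2, beta[i, ], `-`)
    shared <- sweep(!miss[-i, , drop = FALSE], 2, obs_i, `&`)
    d2 <- rowSums(diffs^2 * shared, na.rm = TRUE)
    n_shared <- rowSums(shared)
    d <- sqrt(d2 / n_shared * n_samp)
    d[n_shared == 0] <- Inf
    ord <- order(d)
    for (j in which(miss[i, ])) {
      # nearest k rows with an observed value at sample j
      cand <- ord[!miss[-i, , drop = FALSE][ord, j]]
      use <- cand[seq_len(min(k, length(cand)))]
      beta[i, j] <- mean(beta[-i, , drop = FALSE][use, j])
    }
  }
  beta
}

#' Methylation profile score for birthweight (MPS-BW)
#'
#' For each sample, the product of the methylation beta value and the
#' corresponding EWAS regression weight is summed over the CpGs shared
#' between the matrix and the weight table, then z-scored within each
#' array subcohort to standardize across arrays (sample n-1 SD).
#'
#' @param beta samples x CpGs beta matrix with CpG ids as column names.
#' @param ewas_weights data.frame with `cpg_id` and `weight`.
#' @param array_labels per-sample array labels (one group if `NULL`).
#' @return data.frame of class `"mps"`: `sample_id`, `raw`, `mps`
#'   (z-scored within array), with attribute `n_cpgs_used`.
#' @export
compute_mps <- function(beta, ewas_weights, array_labels = NULL) {
  if (anyDuplicated(ewas_weights$cpg_id)) {
    stop_invalid("duplicate CpG ids in EWAS weight table")
  }
  shared <- intersect(colnames(beta), ewas_weights$cpg_id)
  if (length(shared) == 0L) {
    stop_invalid("no CpGs shared between the beta matrix and the weight table")
  }
  w <- ewas_weights$weight[match(shared, ewas_weights$cpg_id)]
  raw <- as.vector(beta[, shared, drop = FALSE] %*% w)
  if (stats::sd(raw) == 0) {
    stop_invalid("degenerate methylation profile score: zero variance ",
                 "(all weights zero or constant methylation)")
  }
  groups <- if (is.null(array_labels)) rep("all", length(raw)) else array_labels
  z <- raw
  for (grp in unique(groups)) {
    sel <- groups == grp
    z[sel] <- zscore(raw[sel])
  }
  out <- data.frame(
    sample_id = rownames(beta) %||% seq_along(raw),
    raw = raw,
    mps = z,
    stringsAsFactors = FALSE
  )
  attr(out, "n_cpgs_used") <- length(shared)
  class(out) <- c("mps", "data.frame")
  out
}
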