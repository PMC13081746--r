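#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools estimates with weights `w_i = 1 / se_i^2`:
#' `b = sum(w_i b_i) / sum(w_i)`, `se = 1 / sqrt(sum(w_i))`, and a
#' two-sided p-value from the normal reference for `z = b / se` (the
#' convention of GWAS/EWAS meta-analysis software).
#'
#' @param b vector of per-study estimates.
#' @param se vector of per-study standard errors (> 0).
#' @return list of class `"meta_result"`: `b`, `se`, `z`, `p`,
#'   `k_studies`.
#' @export
fixed_effect_meta <- function(b, se) {
  if (length(b) != length(se) || length(b) < 1L) {
    stop_invalid("b and se must have equal, positive length")
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_invalid("all standard errors must be finite and > 0")
  }
  w <- 1 / se^2
  bp <- sum(w * b) / sum(w)
  sep <- 1 / sqrt(sum(w))
  z <- bp / sep
  structure(
    list(
      b = bp, se = sep, z = z,
      p = 2 * stats::pnorm(-abs(z)),
      k_studies = length(b)
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Fixed-effect meta (%d studies): b = %.4g, se = %.4g, z = %.3f, p = %.3g\n",
    x$k_studies, x$b, x$se, x$z, x$p
  ))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' Optional companion to [fixed_effect_meta()]; not computed by default.
#'
#' @inheritParams fixed_effect_meta
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(b, se) {
  m <- fixed_effect_meta(b, se)
  w <- 1 / se^2
  Q <- sum(w * (b - m$b)^2)
  df <- length(b) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the
#' input order. Input p-values must lie in (0, 1].
#'
#' @param p vector of p-values.
#' @param m family size; defaults to `length(p)` but can be larger when
#'   the tested set is a subset of the family.
#' @return vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  if (m < length(p)) stop_invalid("family size m cannot be below length(p)")
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  q_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  q <- numeric(length(p))
  q[o] <- q_sorted
  q
}

#' Pool a battery result table across array subcohorts
#'
#' Meta-analyzes each (model, outcome, scale, term) across subcohorts by
#' [fixed_effect_meta()], then applies Benjamini-Hochberg FDR within each
#' (model, term, scale) family across the CpG outcomes. MPS and
#' birthweight outcomes are single tests and left uncorrected
#' (`q = NA`).
#'
#' @param results long table from [run_model_battery()].
#' @param fdr_family_size BH family size; defaults to the number of CpG
#'   outcomes present per (model, term, scale) family.
#' @return data.frame with `model_id`, `outcome`, `scale`, `term`,
#'   `genetic_effect`, `pooled_b`, `pooled_se`, `z`, `p_meta`, `q`,
#'   `k_studies`, `n_total`.
#' @export
pool_battery <- function(results, fdr_family_size = NULL) {
  key <- interaction(
    results$model_id, results$outcome, results$scale, results$term,
    drop = TRUE
  )
  ncoh <- tapply(results$subcohort, key, function(s) length(unique(s)))
  nrow_key <- tapply(results$subcohort, key, length)
  if (any(ncoh != nrow_key)) {
    stop_invalid("each (model, outcome, scale, term) must appear exactly ",
                 "once per subcohort")
  }
  pooled <- do.call(rbind, lapply(split(results, key), function(d) {
    mr <- fixed_effect_meta(d$estimate, d$se)
    data.frame(
      model_id = d$model_id[1],
      outcome = d$outcome[1],
      scale = d$scale[1],
      term = d$term[1],
      genetic_effect = d$genetic_effect[1],
      pooled_b = mr$b,
      pooled_se = mr$se,
      z = mr$z,
      p_meta = mr$p,
      k_studies = mr$k_studies,
      n_total = sum(d$n),
      stringsAsFactors = FALSE
    )
  }))
  rownames(pooled) <- NULL

  pooled$q <- NA_real_
  is_cpg <- startsWith(pooled$outcome, "cpg:")
  if (any(is_cpg)) {
    fam <- interaction(
      pooled$model_id[is_cpg], pooled$term[is_cpg], pooled$scale[is_cpg],
      drop = TRUE
    )
    for (f in levels(fam)) {
      sel <- which(is_cpg)[fam == f]
      m <- fdr_family_size %||% length(sel)
      pooled$q[sel] <- bh_fdr(pooled$p_meta[sel], m = m)
    }
  }
  pooled
}
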