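#' Enumerate the mediation pathway test family
#'
#' The multiple-testing family is the full cross product of mediators,
#' exposure effect types (e.g. fetal direct and maternal indirect) and
#' outcomes; with 13 mediators, 2 effect types and 7 outcomes this is
#' 13 x 2 x 7 = 182 pathways.
#'
#' @param n_mediators,n_exposures,n_outcomes positive counts, or
#'   character vectors of names (counts are then their lengths).
#' @return list with `count` and `grid` (stable ordering: outcome slowest,
#'   then exposure, then mediator).
#' @export
enumerate_pathways <- function(n_mediators, n_exposures, n_outcomes) {
  as_names <- function(x, prefix) {
    if (is.character(x)) return(x)
    x <- as.integer(x)
    if (is.na(x) || x < 1L) stop_invalid("pathway counts must be >= 1")
    paste0(prefix, seq_len(x))
  }
  med <- as_names(n_mediators, "mediator")
  exp_ <- as_names(n_exposures, "exposure")
  out <- as_names(n_outcomes, "outcome")
  grid <- expand.grid(
    mediator = med, exposure = exp_, outcome = out,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  list(count = nrow(grid), grid = grid)
}

#' Multiple-mediator path model for direct and indirect genetic effects
#'
#' Product-of-coefficients estimator with all mediators entered
#' simultaneously (hence mutually adjusted):
#' a-paths regress each mediator on both exposures jointly (probit link
#' for binary mediators by default, approximating a latent-response
#' treatment; linear otherwise); b-paths and the direct effect c' come
#' from one outcome regression on both exposures, all mediators and sex;
#' the total effect c comes from the outcome regression without
#' mediators. Sex adjusts the b and c paths; a-paths are unadjusted
#' unless `adjust_a_for_sex = TRUE` (with linear links and a common
#' covariate set the exact OLS identity `c = c' + sum(a*b)` then holds).
#' Indirect effects are `a * b` per (exposure, mediator) pathway with
#' percentile bootstrap confidence intervals over families, normal-
#' approximation p-values from the bootstrap SE, and Benjamini-Hochberg
#' q-values across the enumerated pathway family. The proportion
#' mediated divides by the total effect c and may fall outside [0, 1]
#' when paths oppose; it is flagged, never clipped.
#'
#' @param data complete-case data.frame holding exposures, mediators,
#'   outcome and `sex`.
#' @param exposures character vector of exposure columns (standardized
#'   scores), e.g. `c("pgs_fetal_effect", "pgs_maternal_effect")`.
#' @param mediators character vector of mediator columns.
#' @param outcome outcome column name.
#' @param standardize z-score the outcome and continuous mediators so
#'   paths are in SD units (binary mediators stay 0/1).
#' @param adjust_a_for_sex also adjust a-paths for sex.
#' @param links `"auto"` (probit for binary mediators) or `"linear"`.
#' @param boot bootstrap replicates (default 1000).
#' @param family_size BH family size for pathway q-values; defaults to
#'   the number of pathways fitted here.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `"mediation_fit"` with elements `pathways`
#'   (per exposure x mediator: `a`, `b`, `indirect`, `ci_lo`, `ci_hi`,
#'   `p`, `q`, `prop_mediated`), `totals` (per exposure: `c`, `c_prime`,
#'   `total_indirect`, `prop_mediated` with CI and flag), `n`, `boot`.
#' @export
fit_multiple_mediation <- function(data, exposures, mediators, outcome,
                                   standardize = TRUE,
                                   adjust_a_for_sex = FALSE,
                                   links = c("auto", "linear"),
                                   boot = 1000, family_size = NULL,
                                   seed = NULL) {
  links <- match.arg(links)
  if (anyDuplicated(mediators)) stop_invalid("mediators must be distinct")
  if (outcome %in% mediators) {
    stop_invalid("the outcome cannot also be a mediator")
  }
  need <- c(exposures, mediators, outcome, "sex")
  missing_vars <- setdiff(need, names(data))
  if (length(missing_vars)) {
    stop_invalid("variables absent from data: ",
                 paste(missing_vars, collapse = ", "))
  }
  dat <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  n <- nrow(dat)

  med_types <- infer_types(dat[, mediators, drop = FALSE], NULL)
  binary_med <- names(med_types)[med_types == "binary"]
  if (links == "linear") binary_med <- character(0)

  if (standardize) {
    dat[[outcome]] <- zscore(dat[[outcome]])
    for (m in setdiff(mediators, names(med_types)[med_types == "binary"])) {
      dat[[m]] <- zscore(dat[[m]])
    }
  }

  est <- mediation_point_estimates(
    dat, exposures, mediators, outcome, binary_med, adjust_a_for_sex
  )

  boot_mat <- NULL
  if (boot > 0) {
    boot_mat <- with_seed(seed, {
      reps <- matrix(NA_real_, nrow = boot,
                     ncol = length(est$flat), dimnames = list(NULL, names(est$flat)))
      fail <- 0L
      for (r in seq_len(boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        br <- tryCatch(
          mediation_point_estimates(
            dat[idx, , drop = FALSE], exposures, mediators, outcome,
            binary_med, adjust_a_for_sex
          )$flat,
          error = function(e) NULL
        )
        if (is.null(br)) fail <- fail + 1L else reps[r, ] <- br
      }
      if (fail > 0.05 * boot) {
        stop_invalid("more than 5% of bootstrap replicates failed (",
                     fail, "/", boot, ")")
      }
      reps[stats::complete.cases(reps), , drop = FALSE]
    })
  }

  pathways <- est$pathways
  totals <- est$totals
  if (!is.null(boot_mat) && nrow(boot_mat) > 1) {
    ql <- function(nm) stats::quantile(boot_mat[, nm], 0.025, names = FALSE)
    qh <- function(nm) stats::quantile(boot_mat[, nm], 0.975, names = FALSE)
    sdv <- function(nm) stats::sd(boot_mat[, nm])
    ind_nm <- paste0("indirect.", pathways$exposure, ".", pathways$mediator)
    path_nm <- paste0(pathways$exposure, ".", pathways$mediator)
    pathways$a_ci_lo <- vapply(paste0("a.", path_nm), ql, numeric(1))
    pathways$a_ci_hi <- vapply(paste0("a.", path_nm), qh, numeric(1))
    pathways$b_ci_lo <- vapply(paste0("b.", path_nm), ql, numeric(1))
    pathways$b_ci_hi <- vapply(paste0("b.", path_nm), qh, numeric(1))
    pathways$ci_lo <- vapply(ind_nm, ql, numeric(1))
    pathways$ci_hi <- vapply(ind_nm, qh, numeric(1))
    bsd <- vapply(ind_nm, sdv, numeric(1))
    pathways$p <- ifelse(
      bsd > 0, 2 * stats::pnorm(-abs(pathways$indirect) / bsd), 1
    )
    tot_nm <- paste0("prop_mediated.", totals$exposure)
    totals$prop_ci_lo <- vapply(tot_nm, ql, numeric(1))
    totals$prop_ci_hi <- vapply(tot_nm, qh, numeric(1))
    ti_nm <- paste0("total_indirect.", totals$exposure)
    tsd <- vapply(ti_nm, sdv, numeric(1))
    totals$p_total_indirect <- ifelse(
      tsd > 0, 2 * stats::pnorm(-abs(totals$total_indirect) / tsd), 1
    )
  } else {
    pathways$a_ci_lo <- pathways$a_ci_hi <- pathways$b_ci_lo <-
      pathways$b_ci_hi <- pathways$ci_lo <- pathways$ci_hi <-
      pathways$p <- NA_real_
    totals$prop_ci_lo <- totals$prop_ci_hi <-
      totals$p_total_indirect <- NA_real_
  }
  if (all(!is.na(pathways$p))) {
    m_fam <- family_size %||% nrow(pathways)
    pathways$q <- bh_fdr(pmin(pmax(pathways$p, 1e-300), 1), m = m_fam)
  } else {
    pathways$q <- NA_real_
  }

  structure(
    list(
      pathways = pathways, totals = totals, n = n, boot = boot,
      exposures = exposures, mediators = mediators, outcome = outcome,
      binary_mediators = binary_med,
      adjust_a_for_sex = adjust_a_for_sex,
      linear = length(binary_med) == 0L
    ),
    class = "mediation_fit"
  )
}

# Point estimates for one dataset: a-paths, b-paths, c, c', indirects,
# proportions. Returns structured tables plus a flat named vector for
# bootstrap aggregation.
mediation_point_estimates <- function(dat, exposures, mediators, outcome,
                                      binary_med, adjust_a_for_sex) {
  a_covars <- if (adjust_a_for_sex) c(exposures, "sex") else exposures

  a_mat <- matrix(
    NA_real_, nrow = length(exposures), ncol = length(mediators),
    dimnames = list(exposures, mediators)
  )
  for (m in mediators) {
    if (m %in% binary_med) {
      fit <- tryCatch(
        suppressWarnings(stats::glm(
          stats::reformulate(a_covars, response = m),
          family = stats::binomial("probit"), data = dat
        )),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        warning("probit a-path for '", m,
                "' did not converge; linear-probability fallback")
        fit <- stats::lm(stats::reformulate(a_covars, response = m),
                         data = dat)
      }
    } else {
      fit <- stats::lm(stats::reformulate(a_covars, response = m), data = dat)
    }
    a_mat[, m] <- stats::coef(fit)[exposures]
  }

  bfit <- stats::lm(
    stats::reformulate(c(exposures, mediators, "sex"), response = outcome),
    data = dat
  )
  b <- stats::coef(bfit)[mediators]
  c_prime <- stats::coef(bfit)[exposures]
  cfit <- stats::lm(
    stats::reformulate(c(exposures, "sex"), response = outcome), data = dat
  )
  c_tot <- stats::coef(cfit)[exposures]

  grid <- expand.grid(
    mediator = mediators, exposure = exposures,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$a <- a_mat[cbind(grid$exposure, grid$mediator)]
  grid$b <- unname(b[grid$mediator])
  grid$indirect <- grid$a * grid$b
  grid$prop_mediated <- grid$indirect / c_tot[grid$exposure]

  total_indirect <- tapply(grid$indirect, grid$exposure, sum)[exposures]
  totals <- data.frame(
    exposure = exposures,
    c = unname(c_tot),
    c_prime = unname(c_prime),
    total_indirect = unname(total_indirect),
    prop_mediated = unname(total_indirect / c_tot),
    stringsAsFactors = FALSE
  )
  totals$outside_unit <- totals$prop_mediated < 0 | totals$prop_mediated > 1

  flat <- c(
    stats::setNames(grid$a,
                    paste0("a.", grid$exposure, ".", grid$mediator)),
    stats::setNames(grid$b,
                    paste0("b.", grid$exposure, ".", grid$mediator)),
    stats::setNames(grid$indirect,
                    paste0("indirect.", grid$exposure, ".", grid$mediator)),
    stats::setNames(totals$total_indirect,
                    paste0("total_indirect.", totals$exposure)),
    stats::setNames(totals$prop_mediated,
                    paste0("prop_mediated.", totals$exposure)),
    stats::setNames(totals$c, paste0("c.", totals$exposure))
  )
  list(pathways = grid[, c("exposure", "mediator", "a", "b", "indirect",
                           "prop_mediated")],
       totals = totals, flat = flat)
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(
    "Multiple mediation: %d mediator(s), outcome '%s', n = %d, %d bootstrap reps\n",
    length(x$mediators), x$outcome, x$n, x$boot
  ))
  cat("\nTotals per exposure:\n")
  print(x$totals, row.names = FALSE, digits = 3)
  cat("\nLeading pathways (|indirect|):\n")
  pw <- x$pathways[order(-abs(x$pathways$indirect)), ]
  print(utils::head(pw, 6), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) object$pathways

#' @export
coef.mediation_fit <- function(object, ...) {
  stats::setNames(
    object$pathways$indirect,
    paste0(object$pathways$exposure, "->", object$pathways$mediator)
  )
}

#' Residualize M-values for batch and cell composition
#'
#' Regresses each CpG column on sample plate and the six non-reference
#' cell proportions and returns the residuals (plus the grand mean), the
#' preprocessing used before DNAm enters a mediation model.
#'
#' @param mvalues samples x CpGs matrix.
#' @param data data.frame with `plate` and cell-proportion columns.
#' @return matrix of residualized M-values, same shape.
#' @export
residualize_methylation <- function(mvalues, data) {
  rhs <- cell_covariates()
  data$plate <- factor(data$plate)
  if (nlevels(droplevels(data$plate)) >= 2) rhs <- c("plate", rhs)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(rhs, collapse = " + "))), data
  )
  fit <- stats::lm.fit(X, mvalues)
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  res <- sweep(res, 2, colMeans(mvalues), `+`)
  dimnames(res) <- dimnames(mvalues)
  res
}

#' Mediation with DNA methylation as the mediator
#'
#' Same estimator as [fit_multiple_mediation()] with the roles swapped:
#' the mediators are CpG M-values (jointly) or the methylation profile
#' score (singly), and the outcome is birthweight. DNAm mediators should
#' be residualized for batch and cell proportions beforehand
#' ([residualize_methylation()]). Reports, per exposure, the proportion
#' of the total effect jointly explained by the DNAm mediators.
#'
#' @param data per-family data.frame with exposures, outcome and sex.
#' @param exposures exposure columns.
#' @param dnam_mediators a samples x CpGs matrix of (residualized)
#'   M-values, or the name of a single column in `data` (e.g. the MPS).
#' @param outcome outcome column (default `"birthweight"`).
#' @param ... passed on to [fit_multiple_mediation()].
#' @return a `mediation_fit`.
#' @export
fit_dnam_as_mediator <- function(data, exposures, dnam_mediators,
                                 outcome = "birthweight", ...) {
  if (is.matrix(dnam_mediators)) {
    if (nrow(dnam_mediators) != nrow(data)) {
      stop_invalid("dnam_mediators rows must match data rows")
    }
    med_names <- colnames(dnam_mediators)
    data <- cbind(data, as.data.frame(dnam_mediators))
  } else {
    med_names <- dnam_mediators
  }
  fit_multiple_mediation(
    data, exposures = exposures, mediators = med_names, outcome = outcome, ...
  )
}
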