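#' Specify one model of the duo/trio/GWAS-adjusted battery
#'
#' The battery follows the standard family-PGS designs:
#' model 1 (duo: child + mother PGS from own-birthweight weights),
#' 2 (trio: + father), 3 (a priori GWAS-adjusted: fetal-effect +
#' maternal-effect PGS), and 4-8 (each single PGS alone: child, mother,
#' father, fetal-effect, maternal-effect). In adjusted models the child
#' term is interpreted as the direct genetic effect and parental terms as
#' indirect effects; single-PGS models do not partition. All models
#' adjust for child sex; methylation-based outcomes (`"cpg:<id>"` or
#' `"mps"`) additionally adjust for sample plate and 6 of the 7 cord-blood
#' cell proportions, with nRBC the omitted reference level to avoid
#' multicollinearity.
#'
#' @param model_id integer 1-8.
#' @param outcome `"birthweight"`, `"mps"`, or `"cpg:<cpg_id>"`.
#' @param interaction add PGS x female product terms (main effects kept).
#' @param subcohort an array label to restrict to, or `NULL` for the full
#'   sample (birthweight outcome is typically pooled; methylation
#'   outcomes are fitted per array and pooled by meta-analysis).
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(model_id, outcome = "birthweight",
                       interaction = FALSE, subcohort = NULL) {
  model_id <- as.integer(model_id)
  if (is.na(model_id) || model_id < 1L || model_id > 8L) {
    stop_invalid("model_id must be in 1..8")
  }
  structure(
    list(
      model_id = model_id,
      outcome = outcome,
      interaction = isTRUE(interaction),
      subcohort = subcohort,
      terms = battery_terms()[[model_id]]
    ),
    class = "model_spec"
  )
}

battery_terms <- function() {
  list(
    c(direct = "pgs_child", indirect_maternal = "pgs_mother"),
    c(direct = "pgs_child", indirect_maternal = "pgs_mother",
      indirect_paternal = "pgs_father"),
    c(direct = "pgs_fetal_effect", indirect_maternal = "pgs_maternal_effect"),
    c(unpartitioned = "pgs_child"),
    c(unpartitioned = "pgs_mother"),
    c(unpartitioned = "pgs_father"),
    c(unpartitioned = "pgs_fetal_effect"),
    c(unpartitioned = "pgs_maternal_effect")
  )
}

cell_covariates <- function() c("B", "CD4T", "CD8T", "Gran", "Mono", "NK")

is_methylation_outcome <- function(outcome) {
  outcome == "mps" || startsWith(outcome, "cpg:")
}

outcome_column <- function(outcome) {
  if (startsWith(outcome, "cpg:")) sub("^cpg:", "", outcome) else outcome
}

#' Fit one family PGS model by ordinary least squares
#'
#' Complete-case OLS with intercept and classical standard errors;
#' two-sided p-values and 95\% CIs from the t distribution on the
#' residual degrees of freedom. Plate enters as a categorical fixed
#' effect dummy-coded against its first level.
#'
#' @param spec a [model_spec()].
#' @param data data.frame with one row per family/sample carrying the PGS
#'   columns (`pgs_child`, `pgs_mother`, `pgs_father`,
#'   `pgs_fetal_effect`, `pgs_maternal_effect` as needed), `sex`
#'   (female = 1), the outcome column, and for methylation outcomes
#'   `plate`, `array_label` and cell-proportion columns.
#' @param robust use heteroskedasticity-robust (HC1) standard errors
#'   instead of classical ones.
#' @return object of class `"family_model_fit"`: the underlying `lm` fit
#'   plus a tidy coefficient table (`$coefficients`).
#' @export
fit_family_model <- function(spec, data, robust = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$subcohort)) {
    data <- data[data$array_label == spec$subcohort, , drop = FALSE]
  }
  ycol <- outcome_column(spec$outcome)
  covars <- "sex"
  if (is_methylation_outcome(spec$outcome)) {
    covars <- c(covars, "plate", cell_covariates())
  }
  vars <- c(ycol, spec$terms, covars)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop_invalid("variables absent from data: ",
                 paste(missing_vars, collapse = ", "))
  }

  rhs <- c(spec$terms, covars)
  if (spec$interaction) {
    rhs <- c(rhs, paste0(spec$terms, ":sex"))
  }
  # single-level factors (e.g. one plate in a small subcohort) are dropped
  if ("plate" %in% rhs) {
    data$plate <- factor(data$plate)
    if (nlevels(droplevels(data$plate[!is.na(data$plate)])) < 2) {
      rhs <- setdiff(rhs, "plate")
    }
  }
  fml <- stats::as.formula(
    paste(sprintf("`%s`", ycol), "~", paste(rhs, collapse = " + "))
  )
  cc <- stats::complete.cases(data[, intersect(vars, names(data))])
  dat <- data[cc, , drop = FALSE]
  n_par <- length(rhs) + 1L
  if (nrow(dat) < n_par + 2L) {
    stop_invalid("insufficient complete cases (", nrow(dat),
                 ") for ", n_par, " parameters")
  }
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    stop_invalid(
      "rank-deficient design; collinear columns: ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")
    )
  }

  tab <- tidy_lm(fit, robust = robust)
  tab$genetic_effect <- NA_character_
  for (lab in names(spec$terms)) {
    tab$genetic_effect[tab$term == spec$terms[[lab]]] <- lab
    tab$genetic_effect[tab$term %in% paste0(spec$terms[[lab]], c(":sex"))] <-
      paste0(lab, "_x_sex")
  }
  tab$model_id <- spec$model_id
  tab$outcome <- spec$outcome
  tab$subcohort <- spec$subcohort %||% "pooled"
  tab$n <- nrow(dat)

  structure(
    list(spec = spec, fit = fit, coefficients = tab),
    class = "family_model_fit"
  )
}

tidy_lm <- function(fit, robust = FALSE) {
  est <- stats::coef(fit)
  if (robust) {
    X <- stats::model.matrix(fit)
    u <- stats::residuals(fit)
    n <- nrow(X); p <- ncol(X)
    bread <- chol2inv(qr.R(fit$qr))
    meat <- crossprod(X * u)
    V <- bread %*% meat %*% bread * n / (n - p)
    se <- sqrt(diag(V))
  } else {
    se <- sqrt(diag(stats::vcov(fit)))
  }
  df <- fit$df.residual
  tcrit <- stats::qt(0.975, df)
  tval <- est / se
  data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_lo = unname(est - tcrit * se),
    ci_hi = unname(est + tcrit * se),
    p = unname(2 * stats::pt(-abs(tval), df)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.family_model_fit <- function(x, ...) {
  cat(sprintf(
    "Family PGS model %d, outcome %s, subcohort %s (n = %d)\n",
    x$spec$model_id, x$spec$outcome, x$spec$subcohort %||% "pooled",
    x$coefficients$n[1]
  ))
  keep <- !is.na(x$coefficients$genetic_effect)
  print(x$coefficients[keep, c("term", "genetic_effect", "estimate",
                               "se", "ci_lo", "ci_hi", "p")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.family_model_fit <- function(object, ...) {
  object$coefficients
}

#' @export
coef.family_model_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.family_model_fit <- function(object, ...) {
  m <- as.matrix(object$coefficients[, c("ci_lo", "ci_hi")])
  rownames(m) <- object$coefficients$term
  colnames(m) <- c("2.5 %", "97.5 %")
  m
}

#' @export
predict.family_model_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.family_model_fit <- function(object, ...) {
  stats::residuals(object$fit)
}

#' Fit a family PGS model with PGS-by-sex interaction terms
#'
#' Adds a product term between each PGS in the model and female sex
#' (female = 1), keeping the main effects. The female-stratum slope is
#' the main effect plus the interaction.
#'
#' @inheritParams fit_family_model
#' @export
fit_sex_interaction <- function(spec, data, robust = FALSE) {
  spec$interaction <- TRUE
  fit_family_model(spec, data, robust = robust)
}

#' Run the full model battery over outcomes and subcohorts
#'
#' Fits every requested (model x outcome x subcohort) combination and
#' returns a long-format coefficient table. Methylation and MPS outcomes
#' are fitted separately per array subcohort (for downstream fixed-effect
#' pooling); birthweight is fitted on the pooled sample. CpG outcomes are
#' fitted on the M-value scale and, as a reporting companion, on the beta
#' scale (`scale` column). Per-combination failures are caught, recorded
#' in the `failures` attribute, and do not abort the batch.
#'
#' When many CpG outcomes share one design (no missing covariates), all
#' outcomes are fitted through a single QR decomposition.
#'
#' @param data per-sample data.frame (see [fit_family_model()]).
#' @param outcomes character vector: `"birthweight"`, `"mps"` and/or CpG
#'   outcomes as `"cpg:<id>"`.
#' @param models integer vector of model ids (default 1:8).
#' @param mvalues optional samples x CpGs M-value matrix aligned with
#'   `data` rows, required for CpG outcomes.
#' @param interaction fit the PGS x sex variant instead.
#' @param scales for CpG outcomes: fit `"mvalue"`, `"beta"` or both.
#' @return long data.frame: `model_id`, `outcome`, `subcohort`, `scale`,
#'   `term`, `genetic_effect`, `estimate`, `se`, `ci_lo`, `ci_hi`, `p`,
#'   `n`; PGS (and interaction) rows only.
#' @export
run_model_battery <- function(data, outcomes, models = 1:8, mvalues = NULL,
                              interaction = FALSE,
                              scales = c("mvalue", "beta")) {
  if (length(outcomes) == 0L) stop_invalid("outcomes must be nonempty")
  scales <- match.arg(scales, several.ok = TRUE)
  out <- list()
  failures <- list()
  add <- function(tab) out[[length(out) + 1L]] <<- tab

  cpg_outcomes <- outcomes[startsWith(outcomes, "cpg:")]
  plain_outcomes <- setdiff(outcomes, cpg_outcomes)

  for (m in models) {
    for (oc in plain_outcomes) {
      subcohorts <- if (is_methylation_outcome(oc)) {
        unique(data$array_label)
      } else {
        list(NULL)
      }
      for (sc in subcohorts) {
        res <- tryCatch(
          {
            fit <- fit_family_model(
              model_spec(m, oc, interaction = interaction,
                         subcohort = if (is.null(sc)) NULL else sc),
              data
            )
            tab <- fit$coefficients
            tab <- tab[!is.na(tab$genetic_effect), , drop = FALSE]
            tab$scale <- "raw"
            tab
          },
          error = function(e) e
        )
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- list(
            model_id = m, outcome = oc, subcohort = sc,
            message = conditionMessage(res)
          )
        } else {
          add(res)
        }
      }
    }
    if (length(cpg_outcomes) > 0) {
      if (is.null(mvalues)) {
        stop_invalid("CpG outcomes requested but no mvalues matrix supplied")
      }
      cpgs <- sub("^cpg:", "", cpg_outcomes)
      bad <- setdiff(cpgs, colnames(mvalues))
      if (length(bad) > 0) {
        stop_invalid("CpGs absent from mvalues: ", paste(bad, collapse = ", "))
      }
      for (sc in unique(data$array_label)) {
        for (scl in scales) {
          Y <- mvalues[, cpgs, drop = FALSE]
          if (scl == "beta") Y <- m_to_beta(Y)
          res <- tryCatch(
            fit_cpg_block(m, data, Y, sc, interaction = interaction,
                          scale = scl),
            error = function(e) e
          )
          if (inherits(res, "error")) {
            failures[[length(failures) + 1L]] <- list(
              model_id = m, outcome = "cpg block", subcohort = sc,
              scale = scl, message = conditionMessage(res)
            )
          } else {
            add(res)
          }
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cols <- c("model_id", "outcome", "subcohort", "scale", "term",
            "genetic_effect", "estimate", "se", "ci_lo", "ci_hi", "p", "n")
  res <- res[, cols]
  attr(res, "failures") <- failures
  res
}

# All CpG outcomes of one (model, subcohort, scale) through a single QR.
fit_cpg_block <- function(model_id, data, Y, subcohort, interaction = FALSE,
                          scale = "mvalue") {
  sel <- data$array_label == subcohort
  data <- data[sel, , drop = FALSE]
  Y <- Y[sel, , drop = FALSE]
  terms <- battery_terms()[[model_id]]
  covars <- c("sex", cell_covariates())
  vars <- c(terms, covars, "plate")
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop_invalid("variables absent from data: ",
                 paste(missing_vars, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, vars]) & stats::complete.cases(Y)
  data <- data[cc, , drop = FALSE]
  Y <- Y[cc, , drop = FALSE]

  rhs <- c(terms, covars)
  data$plate <- factor(data$plate)
  if (nlevels(droplevels(data$plate)) >= 2) rhs <- c(rhs, "plate")
  if (interaction) rhs <- c(rhs, paste0(terms, ":sex"))
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(rhs, collapse = " + "))), data
  )
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) stop_invalid("insufficient complete cases in subcohort")
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop_invalid("rank-deficient design; collinear columns: ",
                 paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]],
                       collapse = ", "))
  }
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  sigma2 <- unname(colSums(res^2)) / (n - p)
  XtX_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]

  keep_terms <- terms
  if (interaction) keep_terms <- c(terms, paste0(terms, ":sex"))
  labels <- names(terms)
  if (interaction) labels <- c(labels, paste0(names(terms), "_x_sex"))
  rowsel <- match(keep_terms, colnames(X))
  tcrit <- stats::qt(0.975, n - p)

  blocks <- lapply(seq_along(rowsel), function(ii) {
    i <- rowsel[ii]
    est <- B[i, ]
    se <- sqrt(XtX_inv_diag[i] * sigma2)
    data.frame(
      model_id = model_id,
      outcome = paste0("cpg:", colnames(Y)),
      subcohort = subcohort,
      scale = scale,
      term = unname(keep_terms[ii]),
      genetic_effect = labels[ii],
      estimate = unname(est),
      se = unname(se),
      ci_lo = unname(est - tcrit * se),
      ci_hi = unname(est + tcrit * se),
      p = unname(2 * stats::pt(-abs(est / se), n - p)),
      n = n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, blocks)
}
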