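#' Simulate birthweight, gestational age and prenatal mediators
#'
#' Birthweight (grams) is generated, on the standardized scale, as
#' `sqrt(var_direct) * z_d + k_unmed * z_m + ga_b * z_ga + sex + noise`,
#' where `z_d` is the child's standardized direct (fetal) genetic value,
#' `z_m` the standardized maternal indirect genetic value,
#' `z_ga = ga_a * z_m + noise` the standardized gestational age, and
#' `k_unmed = sqrt(var_indirect) - ga_a * ga_b` the unmediated part of the
#' maternal path; the result is scaled to the target mean/SD in grams.
#' Residual noise is calibrated so the population birthweight variance
#' equals the target. Standardization of the genetic values uses their
#' population (panel-implied) moments, not sample moments, so realized
#' shares differ from the configured ones only by sampling error.
#'
#' The other 12 mediators are drawn with realistic cohort means, SDs and
#' prevalences and are, by default, independent of the genetic values
#' (configurable through `config$mediator_links`). Mixed types are drawn
#' through a latent-normal construction for binary/ordinal variables,
#' log-normals for skewed biomarkers and a Poisson for parity.
#' Missingness is applied MCAR at the configured per-mediator rates
#' (birthweight and sex are never missing).
#'
#' @param cohort a `trio_cohort`.
#' @param panel the `snp_panel` the cohort was generated from.
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return a `data.frame` of class `"family_phenotypes"` with one row per
#'   family; attribute `"latents"` holds the generating standardized
#'   values (`z_direct`, `z_maternal`, `z_ga`) for calibration audits.
#' @export
simulate_phenotypes <- function(cohort, panel, config = generator_config(),
                                seed = NULL) {
  stopifnot(inherits(cohort, "trio_cohort"), inherits(panel, "snp_panel"))
  if (!identical(colnames(cohort$dosage_child), panel$snp_id)) {
    stop_invalid("cohort and panel do not share the same SNP set")
  }
  n <- length(cohort$family_id)
  systematic_bw_variance(config) # errors if residual variance negative

  z_d <- standardized_genetic_value(cohort$dosage_child, panel,
                                    panel$beta_fetal)
  z_m <- standardized_genetic_value(cohort$dosage_mother, panel,
                                    panel$beta_maternal)

  with_seed(seed, {
    a_eff <- if (config$var_indirect > 0) config$ga_a else 0
    z_ga <- a_eff * z_m + stats::rnorm(n, 0, sqrt(1 - a_eff^2))
    k_unmed <- sqrt(config$var_indirect) - a_eff * config$ga_b
    sex_sd <- config$sex_effect_g / config$bw_sd_g
    resid_sd <- sqrt(1 - systematic_bw_variance(config))
    bw_z <- sqrt(config$var_direct) * z_d + k_unmed * z_m +
      config$ga_b * z_ga - sex_sd * (cohort$sex_child - 0.5) +
      stats::rnorm(n, 0, resid_sd)
    birthweight <- config$bw_mean_g + config$bw_sd_g * bw_z
    birthweight <- pmax(birthweight, 300)
    gestational_age <- pmin(pmax(
      config$ga_mean_wk + config$ga_sd_wk * z_ga, 22.01
    ), 43.99)

    med <- draw_mediators(n, z_m, z_d, config$mediator_links)

    phen <- data.frame(
      family_id = cohort$family_id,
      sex = cohort$sex_child,
      birthweight = birthweight,
      gestational_age = gestational_age,
      med,
      stringsAsFactors = FALSE
    )
    phen <- apply_missingness(phen, config$missingness)
    attr(phen, "latents") <- data.frame(
      z_direct = z_d, z_maternal = z_m, z_ga = z_ga
    )
    class(phen) <- c("family_phenotypes", "data.frame")
    phen
  })
}

#' Names of the 13 prenatal mediators
#' @return character vector in canonical order (gestational age first).
#' @export
mediator_names <- function() {
  c(
    "gestational_age", "parity", "maternal_age", "bmi", "insulin",
    "folate", "homocysteine", "diet_score", "psychopathology",
    "smoking", "hypertensive_disorder", "education", "income"
  )
}

# Draw the 12 non-GA mediators. `links` entries are lists with elements
# `maternal` and/or `fetal`: shifts (per SD of genetic value) applied on
# the latent / standardized scale of the mediator.
draw_mediators <- function(n, z_m, z_d, links) {
  shift <- function(name) {
    l <- links[[name]]
    if (is.null(l)) return(numeric(n))
    (l$maternal %||% 0) * z_m + (l$fetal %||% 0) * z_d
  }
  lognormal_pars <- function(m, s) {
    s2 <- log(1 + (s / m)^2)
    c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  draw_lnorm <- function(name, m, s) {
    p <- lognormal_pars(m, s)
    exp(p[["meanlog"]] + p[["sdlog"]] * (stats::rnorm(n) + shift(name)))
  }
  # latent-normal draw mapped to ordered categories with marginal probs
  draw_ordinal <- function(name, probs, values = seq_along(probs)) {
    z <- stats::rnorm(n) + shift(name)
    cuts <- stats::qnorm(cumsum(probs))
    values[findInterval(z, cuts[-length(cuts)]) + 1L]
  }

  data.frame(
    parity = stats::rpois(n, 0.49 * exp(0.5 * shift("parity"))),
    maternal_age = 31.97 + 4.22 * (stats::rnorm(n) + shift("maternal_age")),
    bmi = 24.61 + 3.94 * (stats::rnorm(n) + shift("bmi")),
    insulin = draw_lnorm("insulin", 146.03, 134.57),
    folate = draw_lnorm("folate", 20.08, 8.89),
    homocysteine = draw_lnorm("homocysteine", 7.22, 1.87),
    diet_score = 7.97 + 1.51 * (stats::rnorm(n) + shift("diet_score")),
    psychopathology = draw_lnorm("psychopathology", 0.20, 0.26),
    smoking = draw_ordinal("smoking", c(0.744, 0.256), c(0L, 1L)),
    hypertensive_disorder = draw_ordinal(
      "hypertensive_disorder", c(0.924, 0.076), c(0L, 1L)
    ),
    education = draw_ordinal(
      "education", c(0.04, 0.08, 0.10, 0.15, 0.33, 0.30)
    ),
    income = draw_ordinal(
      "income", c(rep(0.173 / 6, 6), rep(0.827 / 6, 6))
    )
  )
}

apply_missingness <- function(phen, rates) {
  for (v in intersect(names(rates), names(phen))) {
    r <- rates[[v]]
    if (r > 0) {
      miss <- stats::runif(nrow(phen)) < r
      phen[[v]][miss] <- NA
    }
  }
  phen
}
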