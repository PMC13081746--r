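#' Configuration for the synthetic trio-cohort generator
#'
#' Collects every tunable of the simulator in one validated list. The
#' defaults emulate a population-based pregnancy cohort of European
#' ancestry: birthweight with mean 3534.61 g and SD 509.91 g, gestational
#' age 40.10 (1.48) weeks, a direct (fetal) genetic component explaining
#' 15\% of birthweight variance, a maternal indirect component explaining
#' 4\% (0.2 SD of birthweight per SD of the maternal genetic value), and a
#' gestational-age path with a = 0.12 SD of GA per SD of maternal genetic
#' value and b = 0.46 SD of birthweight per SD of GA. Under these defaults
#' the implied proportion of the maternal effect mediated by gestational
#' age is a*b / 0.2 = 0.276.
#'
#' @param n_families number of mother-father-child trios.
#' @param n_snps number of independent (linkage-equilibrium) SNPs.
#' @param n_cpgs number of CpG sites on the simulated methylome.
#' @param n_reference_duos size of the independent reference population of
#'   mother-child duos used to estimate GWAS weight sets.
#' @param var_direct share of birthweight variance explained by the child's
#'   own (fetal) genetic value.
#' @param var_indirect share of birthweight variance explained by the
#'   maternal genetic value (total, i.e. including the part routed through
#'   gestational age).
#' @param ga_a effect of the standardized maternal genetic value on
#'   gestational age, in SD units.
#' @param ga_b effect of gestational age on birthweight, in SD units.
#' @param sex_effect_g birthweight difference in grams (male minus female);
#'   females are coded 1.
#' @param bw_mean_g,bw_sd_g target birthweight mean and SD in grams.
#' @param ga_mean_wk,ga_sd_wk gestational-age mean and SD in weeks.
#' @param array_split fraction of families assayed on the 450K-like array;
#'   the remainder go to the EPIC-like array.
#' @param frac_effect_cpgs fraction of CpGs carrying true direct and/or
#'   indirect genetic effects.
#' @param cpg_effect_sd SD of the per-CpG genetic effect sizes (M-value
#'   units per SD of genetic value) among effect CpGs.
#' @param cpg_ga_weight how much of the maternal input to a CpG is routed
#'   through realized gestational age rather than the maternal genetic
#'   value directly (0 = none, 1 = all).
#' @param cpg_noise_sd residual SD of CpG M-values.
#' @param cell_concentration Dirichlet concentration for cord-blood cell
#'   proportions.
#' @param plate_size samples per plate (batch) and `plate_sd`/`array_sd`
#'   the SDs of per-CpG plate and array shifts on the M-value scale.
#' @param plate_sd,array_sd batch effect SDs (M-value units).
#' @param mediator_links named list of per-SD effects of the standardized
#'   maternal (`maternal`) and fetal (`fetal`) genetic values on mediators
#'   other than gestational age; zero by default.
#' @param missingness named numeric vector of MCAR missingness rates for
#'   the mediators; defaults reflect typical item non-response in such
#'   cohorts. Use `missingness = 0` for complete data.
#'
#' @return a list of class `"triomethyl_config"`.
#' @export
generator_config <- function(n_families = 2116L,
                             n_snps = 1000L,
                             n_cpgs = 200L,
                             n_reference_duos = 50000L,
                             var_direct = 0.15,
                             var_indirect = 0.04,
                             ga_a = 0.12,
                             ga_b = 0.46,
                             sex_effect_g = 100,
                             bw_mean_g = 3534.61,
                             bw_sd_g = 509.91,
                             ga_mean_wk = 40.10,
                             ga_sd_wk = 1.48,
                             array_split = 1198 / 2116,
                             frac_effect_cpgs = 0.3,
                             cpg_effect_sd = 0.06,
                             cpg_ga_weight = 0.89,
                             cpg_noise_sd = 0.3,
                             cell_concentration = 24,
                             plate_size = 96L,
                             plate_sd = 0.08,
                             array_sd = 0.15,
                             mediator_links = NULL,
                             missingness = NULL) {
  cfg <- list(
    n_families = as.integer(n_families),
    n_snps = as.integer(n_snps),
    n_cpgs = as.integer(n_cpgs),
    n_reference_duos = as.integer(n_reference_duos),
    var_direct = var_direct,
    var_indirect = var_indirect,
    ga_a = ga_a,
    ga_b = ga_b,
    sex_effect_g = sex_effect_g,
    bw_mean_g = bw_mean_g,
    bw_sd_g = bw_sd_g,
    ga_mean_wk = ga_mean_wk,
    ga_sd_wk = ga_sd_wk,
    array_split = array_split,
    frac_effect_cpgs = frac_effect_cpgs,
    cpg_effect_sd = cpg_effect_sd,
    cpg_ga_weight = cpg_ga_weight,
    cpg_noise_sd = cpg_noise_sd,
    cell_concentration = cell_concentration,
    plate_size = as.integer(plate_size),
    plate_sd = plate_sd,
    array_sd = array_sd,
    mediator_links = mediator_links %||% list(),
    missingness = missingness %||% default_missingness()
  )
  if (length(cfg$missingness) == 1L && is.null(names(cfg$missingness))) {
    cfg$missingness <- stats::setNames(
      rep(cfg$missingness, length(default_missingness())),
      names(default_missingness())
    )
  }
  validate_config(cfg)
  class(cfg) <- "triomethyl_config"
  cfg
}

# Item non-response rates patterned on a population pregnancy cohort
# (largest for the blood biomarkers, near-complete for registry items).
default_missingness <- function() {
  c(
    gestational_age = 0, parity = 0.002, maternal_age = 0, bmi = 0.028,
    insulin = 0.178, folate = 0.198, homocysteine = 0.207,
    diet_score = 0.106, psychopathology = 0.111, smoking = 0.073,
    hypertensive_disorder = 0.007, education = 0.020, income = 0.088
  )
}

validate_config <- function(cfg) {
  if (cfg$n_families < 1L) stop_invalid("n_families must be >= 1")
  if (cfg$n_snps < 1L) stop_invalid("n_snps must be >= 1")
  if (cfg$n_cpgs < 1L) stop_invalid("n_cpgs must be >= 1")
  if (cfg$var_direct < 0 || cfg$var_indirect < 0) {
    stop_invalid("variance shares must be nonnegative")
  }
  sys_var <- systematic_bw_variance(cfg)
  if (sys_var > 1) {
    stop_invalid(
      "invalid configuration: systematic birthweight variance share ",
      round(sys_var, 3), " exceeds 1 (negative residual variance)"
    )
  }
  if (abs(cfg$ga_a) > 1) stop_invalid("|ga_a| must be <= 1 (SD units)")
  if (cfg$array_split <= 0 || cfg$array_split >= 1) {
    stop_invalid("array_split must be in (0, 1)")
  }
  if (any(cfg$missingness < 0 | cfg$missingness >= 1)) {
    stop_invalid("missingness rates must be in [0, 1)")
  }
  invisible(cfg)
}

# Variance share of the systematic birthweight components (SD units):
# direct + maternal path (unmediated + via GA) + GA's own residual effect
# + sex. Used both for calibration of the residual noise and for the
# decomposition audit.
systematic_bw_variance <- function(cfg) {
  k_total <- sqrt(cfg$var_indirect)
  # a null maternal architecture carries no gestational-age path either
  a_eff <- if (cfg$var_indirect > 0) cfg$ga_a else 0
  k_unmed <- k_total - cfg$ga_b * a_eff
  if (k_unmed < 0) {
    stop_invalid(
      "invalid configuration: ga_a * ga_b exceeds the total maternal ",
      "effect sqrt(var_indirect); implied unmediated path is negative"
    )
  }
  sex_sd <- cfg$sex_effect_g / cfg$bw_sd_g
  cfg$var_direct + cfg$var_indirect + cfg$ga_b^2 * (1 - a_eff^2) +
    0.25 * sex_sd^2
}

#' @export
print.triomethyl_config <- function(x, ...) {
  cat("Trio-cohort generator configuration\n")
  cat(sprintf(
    "  %d families, %d SNPs, %d CpGs, %d reference duos\n",
    x$n_families, x$n_snps, x$n_cpgs, x$n_reference_duos
  ))
  cat(sprintf(
    "  variance shares: direct %.3f, maternal indirect %.3f; GA path a=%.2f b=%.2f\n",
    x$var_direct, x$var_indirect, x$ga_a, x$ga_b
  ))
  cat(sprintf(
    "  birthweight %.2f (%.2f) g; gestational age %.2f (%.2f) wk\n",
    x$bw_mean_g, x$bw_sd_g, x$ga_mean_wk, x$ga_sd_wk
  ))
  invisible(x)
}
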