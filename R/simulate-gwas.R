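#' Construct a GWAS weight table
#'
#' @param panel a `snp_panel` supplying SNP ids and alleles.
#' @param weight per-SNP weight (grams of birthweight per effect allele).
#' @param se per-SNP standard error (> 0).
#' @param provenance one of `"own"`, `"fetal_effect"`, `"maternal_effect"`.
#' @return data.frame of class `"weight_set"` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `weight`, `se`, `provenance`.
#' @export
weight_set <- function(panel, weight, se, provenance) {
  provenance <- match.arg(provenance, c("own", "fetal_effect", "maternal_effect"))
  stopifnot(length(weight) == nrow(panel), length(se) == nrow(panel))
  if (any(se[!is.na(se)] <= 0)) stop_invalid("all weight-set ses must be > 0")
  ws <- data.frame(
    snp_id = panel$snp_id,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    weight = weight,
    se = se,
    provenance = provenance,
    stringsAsFactors = FALSE
  )
  class(ws) <- c("weight_set", "data.frame")
  ws
}

#' Noise-free weight sets from the generating architecture
#'
#' Returns the panel's generating effect sizes packaged as weight tables
#' (`own`, `fetal_effect`, `maternal_effect`). Useful for parameter-recovery
#' studies where estimation noise in the weights would attenuate scores.
#' The `se` column is a placeholder (1).
#'
#' @param panel a `snp_panel`.
#' @return named list of three `weight_set`s.
#' @export
true_weight_sets <- function(panel) {
  list(
    own = weight_set(panel, panel$beta_own, rep(1, nrow(panel)), "own"),
    fetal_effect = weight_set(panel, panel$beta_fetal, rep(1, nrow(panel)), "fetal_effect"),
    maternal_effect = weight_set(panel, panel$beta_maternal, rep(1, nrow(panel)), "maternal_effect")
  )
}

#' Simulate reference-cohort GWAS summary statistics
#'
#' Emulates how duo-design birthweight GWAS produce the three weight sets
#' this pipeline consumes. An independent reference population of
#' mother-child duos is simulated across two generations: grandmaternal
#' genotypes give mothers their own birthweights (so "own-birthweight"
#' weights absorb a transmitted fraction of the maternal indirect
#' effect), and mothers in turn have children. Three summary sets are
#' estimated per SNP:
#'
#' * `own`: simple regression of own birthweight on own dosage (mothers),
#' * `fetal_effect`: child-dosage coefficient from the bivariate
#'   regression of child birthweight on child and mother dosage jointly,
#' * `maternal_effect`: mother-dosage coefficient from the same fit.
#'
#' SNPs that are monomorphic in the reference sample (singular per-SNP
#' design) get `NA` weights and a warning; downstream scoring drops them.
#'
#' @param panel a `snp_panel`.
#' @param n_reference_duos number of duos (>= 100).
#' @param seed RNG seed.
#' @param config a [generator_config()] for phenotype calibration.
#' @return named list of three `weight_set`s
#'   (`own`, `fetal_effect`, `maternal_effect`).
#' @export
simulate_reference_gwas <- function(panel, n_reference_duos,
                                    seed = NULL,
                                    config = generator_config()) {
  stopifnot(inherits(panel, "snp_panel"))
  n <- as.integer(n_reference_duos)
  if (is.na(n) || n < 100L) {
    stop_invalid("n_reference_duos must be >= 100 so per-SNP fits are identified")
  }

  with_seed(seed, {
    p <- panel$freq
    # generation 0: grandmothers; generation 1: mothers; generation 2: children
    grandmother <- draw_hwe_genotypes(n, p)
    mother <- mendelian_child(grandmother) + draw_hwe_genotypes_hap(n, p)
    child <- mendelian_child(mother) + draw_hwe_genotypes_hap(n, p)

    bw_mother <- reference_birthweight(mother, grandmother, panel, config)
    bw_child <- reference_birthweight(child, mother, panel, config)

    own <- per_snp_simple_gwas(mother, bw_mother)
    duo <- per_snp_bivariate_gwas(child, mother, bw_child)

    n_bad <- sum(is.na(own$b) | is.na(duo$b1) | is.na(duo$b2))
    if (n_bad > 0L) {
      warning(
        n_bad, " SNP(s) monomorphic or collinear in the reference sample; ",
        "their weights are NA and will be dropped in scoring"
      )
    }

    list(
      own = weight_set(panel, own$b, own$se, "own"),
      fetal_effect = weight_set(panel, duo$b1, duo$se1, "fetal_effect"),
      maternal_effect = weight_set(panel, duo$b2, duo$se2, "maternal_effect")
    )
  })
}

# one haploid draw per SNP (allele contributed by an unobserved parent)
draw_hwe_genotypes_hap <- function(n, freq) {
  matrix(
    stats::rbinom(n * length(freq), 1L, rep(freq, each = n)),
    nrow = n, ncol = length(freq)
  )
}

# Birthweight of an individual given own and maternal dosage matrices,
# calibrated like the study cohort (no gestational-age refinement in the
# reference generation: the GA path is folded into the total maternal
# effect, which is what a duo GWAS sees).
reference_birthweight <- function(own_dosage, mother_dosage, panel, config) {
  z_d <- standardized_genetic_value(own_dosage, panel, panel$beta_fetal)
  z_m <- standardized_genetic_value(mother_dosage, panel, panel$beta_maternal)
  sys <- config$var_direct + config$var_indirect
  config$bw_mean_g + config$bw_sd_g * (
    sqrt(config$var_direct) * z_d + sqrt(config$var_indirect) * z_m +
      stats::rnorm(nrow(own_dosage), 0, sqrt(1 - sys))
  )
}

# Vectorized per-SNP simple regression y ~ x_j across all SNP columns.
per_snp_simple_gwas <- function(X, y) {
  n <- length(y)
  xbar <- colMeans(X)
  ybar <- mean(y)
  sxx <- colSums(X^2) - n * xbar^2
  sxy <- as.vector(crossprod(X, y)) - n * xbar * ybar
  syy <- sum((y - ybar)^2)
  ok <- sxx > 0
  b <- ifelse(ok, sxy / sxx, NA_real_)
  rss <- syy - b * sxy
  se <- ifelse(ok, sqrt(pmax(rss, 0) / ((n - 2) * sxx)), NA_real_)
  list(b = b, se = se)
}

# Vectorized per-SNP bivariate regression y ~ x1_j + x2_j across SNPs.
per_snp_bivariate_gwas <- function(X1, X2, y) {
  n <- length(y)
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  ybar <- mean(y)
  s11 <- colSums(X1^2) - n * m1^2
  s22 <- colSums(X2^2) - n * m2^2
  s12 <- colSums(X1 * X2) - n * m1 * m2
  s1y <- as.vector(crossprod(X1, y)) - n * m1 * ybar
  s2y <- as.vector(crossprod(X2, y)) - n * m2 * ybar
  syy <- sum((y - ybar)^2)
  det <- s11 * s22 - s12^2
  ok <- det > 1e-10 * pmax(s11 * s22, 1)
  b1 <- ifelse(ok, (s22 * s1y - s12 * s2y) / det, NA_real_)
  b2 <- ifelse(ok, (s11 * s2y - s12 * s1y) / det, NA_real_)
  rss <- pmax(syy - b1 * s1y - b2 * s2y, 0)
  sigma2 <- rss / (n - 3)
  se1 <- ifelse(ok, sqrt(sigma2 * s22 / det), NA_real_)
  se2 <- ifelse(ok, sqrt(sigma2 * s11 / det), NA_real_)
  list(b1 = b1, se1 = se1, b2 = b2, se2 = se2)
}
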