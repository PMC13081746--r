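#' Simulate a SNP panel with separable fetal and maternal effect
#' architectures
#'
#' Draws `n_snps` independent (linkage-equilibrium) biallelic SNPs with
#' effect-allele frequencies Uniform(0.05, 0.95) and, for each SNP,
#' independent fetal-direct and maternal-indirect birthweight effects
#' (grams per effect allele). Per-SNP effect variances are scaled so that
#' the expected variance of the aggregate genetic values matches the
#' configured shares of birthweight variance: with dosage variance
#' 2p(1-p) averaging 0.365 under the frequency distribution, the per-SNP
#' effect variance is `share * bw_sd^2 / (n_snps * 0.365)`.
#'
#' The "own-birthweight" architecture used for adults in the reference
#' cohort is `beta_own = beta_fetal + 0.5 * beta_maternal`: a person's own
#' genotype tags the genotype of their mother with correlation 1/2, so an
#' own-genotype GWAS of own birthweight absorbs half of the maternal
#' indirect effect. This is what makes a-priori and a-posteriori
#' adjustment differ downstream.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param config a [generator_config()]; its `var_direct`, `var_indirect`
#'   and `bw_sd_g` entries calibrate the effect-size distributions.
#' @param seed RNG seed; the same seed reproduces the panel exactly.
#'
#' @return a `data.frame` of class `"snp_panel"` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `freq`, `beta_fetal`,
#'   `beta_maternal`, `beta_own` and attributes `sigma2_fetal`,
#'   `sigma2_maternal` (the generating per-SNP effect variances).
#' @export
simulate_snp_panel <- function(n_snps, config = generator_config(), seed = NULL) {
  n_snps <- as.integer(n_snps)
  if (is.na(n_snps) || n_snps < 1L) stop_invalid("n_snps must be >= 1")

  # E[2p(1-p)] under p ~ U(0.05, 0.95)
  mean_dosage_var <- 2 * (0.5 - (0.9^2 / 12 + 0.25))

  sigma2_fetal <- config$var_direct * config$bw_sd_g^2 /
    (n_snps * mean_dosage_var)
  sigma2_maternal <- config$var_indirect * config$bw_sd_g^2 /
    (n_snps * mean_dosage_var)

  with_seed(seed, {
    freq <- stats::runif(n_snps, 0.05, 0.95)
    alleles <- c("A", "C", "G", "T")
    effect_allele <- sample(alleles, n_snps, replace = TRUE)
    other_allele <- vapply(
      effect_allele,
      function(a) sample(setdiff(alleles, a), 1L),
      character(1)
    )
    beta_fetal <- stats::rnorm(n_snps, 0, sqrt(sigma2_fetal))
    beta_maternal <- stats::rnorm(n_snps, 0, sqrt(sigma2_maternal))
    # rescale so the realized aggregate genetic variance hits the
    # configured share exactly: the betas are then the true grams-per-
    # allele effects of every downstream generating equation
    dosage_var <- 2 * freq * (1 - freq)
    rescale <- function(b, share) {
      target <- share * config$bw_sd_g^2
      realized <- sum(b^2 * dosage_var)
      if (realized == 0 || target == 0) return(b * 0)
      b * sqrt(target / realized)
    }
    beta_fetal <- rescale(beta_fetal, config$var_direct)
    beta_maternal <- rescale(beta_maternal, config$var_indirect)

    panel <- data.frame(
      snp_id = sprintf("rs%06d", seq_len(n_snps)),
      effect_allele = unname(effect_allele),
      other_allele = unname(other_allele),
      freq = freq,
      beta_fetal = beta_fetal,
      beta_maternal = beta_maternal,
      beta_own = beta_fetal + 0.5 * beta_maternal,
      stringsAsFactors = FALSE
    )
    attr(panel, "sigma2_fetal") <- sigma2_fetal
    attr(panel, "sigma2_maternal") <- sigma2_maternal
    class(panel) <- c("snp_panel", "data.frame")
    panel
  })
}

# Population mean and SD of an aggregate genetic value sum(beta * dosage)
# under HWE, given the panel frequencies. Used to standardize generating
# values without reference to any particular sample.
genetic_value_moments <- function(panel, betas) {
  p <- panel$freq
  list(
    mean = sum(betas * 2 * p),
    sd = sqrt(sum(betas^2 * 2 * p * (1 - p)))
  )
}

# Standardized aggregate genetic value; a null architecture (all betas
# zero) standardizes to the zero vector rather than 0/0.
standardized_genetic_value <- function(dosage, panel, betas) {
  mom <- genetic_value_moments(panel, betas)
  if (mom$sd == 0) return(numeric(nrow(dosage)))
  (as.vector(dosage %*% betas) - mom$mean) / mom$sd
}

#' Simulate mother-father-child trios by Mendelian transmission
#'
#' Parental genotypes are drawn Binomial(2, freq) per SNP (Hardy-Weinberg
#' equilibrium, random mating); each child receives one allele from each
#' parent by fair Mendelian segregation (an allele drawn
#' Bernoulli(dosage/2) from each parent). Genotypes are hard calls
#' {0, 1, 2} counting effect alleles, so every trio is
#' Mendelian-consistent by construction. One child per family, no twins.
#'
#' @param panel a [simulate_snp_panel()] panel.
#' @param n_families number of trios (>= 1).
#' @param seed RNG seed.
#'
#' @return list of class `"trio_cohort"` with `family_id`, integer
#'   matrices `dosage_child`, `dosage_mother`, `dosage_father`
#'   (families x SNPs, columns named by `snp_id`) and `sex_child`
#'   (female = 1).
#' @export
simulate_trios <- function(panel, n_families, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  n_families <- as.integer(n_families)
  if (is.na(n_families) || n_families < 1L) {
    stop_invalid("n_families must be >= 1")
  }
  n_snps <- nrow(panel)

  with_seed(seed, {
    dosage_mother <- draw_hwe_genotypes(n_families, panel$freq)
    dosage_father <- draw_hwe_genotypes(n_families, panel$freq)
    dosage_child <- mendelian_child(dosage_mother) +
      mendelian_child(dosage_father)
    sex_child <- stats::rbinom(n_families, 1L, 0.5)

    ids <- sprintf("fam%05d", seq_len(n_families))
    dimnames(dosage_child) <- dimnames(dosage_mother) <-
      dimnames(dosage_father) <- list(ids, panel$snp_id)

    structure(
      list(
        family_id = ids,
        dosage_child = dosage_child,
        dosage_mother = dosage_mother,
        dosage_father = dosage_father,
        sex_child = sex_child
      ),
      class = "trio_cohort"
    )
  })
}

draw_hwe_genotypes <- function(n, freq) {
  matrix(
    stats::rbinom(n * length(freq), 2L, rep(freq, each = n)),
    nrow = n, ncol = length(freq)
  )
}

# One transmitted allele per parent genotype: Bernoulli(g / 2).
mendelian_child <- function(parent_dosage) {
  matrix(
    stats::rbinom(length(parent_dosage), 1L, parent_dosage / 2),
    nrow = nrow(parent_dosage)
  )
}

#' Count Mendelian inconsistencies in a trio cohort
#'
#' A child genotype is inconsistent when it cannot be formed from one
#' maternal and one paternal transmitted allele (e.g. child 2 with a
#' parent of dosage 0).
#'
#' @param cohort a `trio_cohort`.
#' @return integer count of inconsistent (family, SNP) pairs.
#' @export
count_mendelian_errors <- function(cohort) {
  stopifnot(inherits(cohort, "trio_cohort"))
  # a parent of dosage 2 must transmit an effect allele; dosage 0 cannot
  lo <- (cohort$dosage_mother == 2) + (cohort$dosage_father == 2)
  hi <- 2L - (cohort$dosage_mother == 0) - (cohort$dosage_father == 0)
  sum(cohort$dosage_child < lo | cohort$dosage_child > hi)
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf(
    "Trio cohort: %d families x %d SNPs (%.1f%% female children)\n",
    length(x$family_id), ncol(x$dosage_child), 100 * mean(x$sex_child)
  ))
  invisible(x)
}
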