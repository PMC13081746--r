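#' Draw the CpG effect architecture of the simulated methylome
#'
#' The per-CpG biology and platform characteristics — baseline M-value,
#' direct and maternal-indirect genetic effect sizes, cell-composition
#' effects and the EPIC-vs-450K array shift — are properties of the
#' epigenome and assay, not of any one cohort. They are drawn once and
#' shared by every cohort simulated from the same panel (in particular
#' by the reference EWAS cohort and the analysis cohort, so EWAS weights
#' refer to the same CpG effects they will be applied to).
#'
#' A random `frac_effect_cpgs` subset of CpGs carries nonzero direct
#' effects and, independently, maternal-indirect effects
#' (N(0, `cpg_effect_sd`) in M-value units per SD of genetic value); the
#' rest are null.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return list of class `"cpg_architecture"`.
#' @export
cpg_architecture <- function(config = generator_config(), seed = NULL) {
  n_cpgs <- config$n_cpgs
  if (n_cpgs < 1L) stop_invalid("n_cpgs must be >= 1")
  cell_means <- c(
    B = 0.06, CD4T = 0.13, CD8T = 0.04, Gran = 0.51,
    Mono = 0.09, NK = 0.07, nRBC = 0.13
  )
  with_seed(seed, {
    has_d <- stats::rbinom(n_cpgs, 1L, config$frac_effect_cpgs)
    has_i <- stats::rbinom(n_cpgs, 1L, config$frac_effect_cpgs)
    structure(
      list(
        cpg_id = sprintf("cg%08d", seq_len(n_cpgs)),
        mu = stats::runif(n_cpgs, -1, 1.7),
        gamma_d = has_d * stats::rnorm(n_cpgs, 0, config$cpg_effect_sd),
        gamma_i = has_i * stats::rnorm(n_cpgs, 0, config$cpg_effect_sd),
        cell_eff = matrix(stats::rnorm(7 * n_cpgs), nrow = 7,
                          dimnames = list(names(cell_means), NULL)),
        array_shift = stats::rnorm(n_cpgs, 0, config$array_sd),
        cell_means = cell_means
      ),
      class = "cpg_architecture"
    )
  })
}

#' Simulate a two-array neonatal methylome
#'
#' Each CpG's latent M-value is
#' `mu_j + gamma_d[j] * z_d + gamma_i[j] * x_m + cell effects + array/plate
#' shifts + noise`, where `z_d` is the child's standardized direct genetic
#' value and `x_m` a maternal input routed partly through realized
#' gestational age: `x_m = (1 - w) * z_maternal + w * z_ga` with
#' `w = config$cpg_ga_weight`. Beta values are `2^M / (2^M + 1)`, hence
#' strictly in (0, 1).
#'
#' Families are split into a 450K-like and an EPIC-like array subcohort at
#' `config$array_split` (sizes `round(n * split)` and the remainder), with
#' plates of `config$plate_size` samples nested within array. Cord-blood
#' cell proportions (B, CD4T, CD8T, Gran, Mono, NK, nRBC) are drawn from a
#' Dirichlet centred on typical cord-blood composition and enter every
#' CpG with the architecture's per-cell-type effects, so cell composition
#' is a real confounder that downstream models must adjust for.
#'
#' @param cohort a `trio_cohort`.
#' @param phenotypes matching [simulate_phenotypes()] output.
#' @param panel the shared `snp_panel`.
#' @param config a [generator_config()].
#' @param seed RNG seed (cohort-specific draws: split, plates, cell
#'   proportions, noise).
#' @param architecture a [cpg_architecture()]; when `NULL` one is derived
#'   deterministically from `seed`. Pass the same object to every cohort
#'   that shares an epigenome (see [simulate_cohort()]).
#' @return list of class `"methylome"`: `beta` (samples x CpGs), `cpg_id`,
#'   `sample_id`, `array_label` (`"450K"`/`"EPIC"`), `plate`, `cell_props`
#'   (samples x 7, rows summing to 1); attribute `"truth"` holds the
#'   generating `gamma_d`, `gamma_i` per CpG.
#' @export
simulate_methylome <- function(cohort, phenotypes, panel,
                               config = generator_config(), seed = NULL,
                               architecture = NULL) {
  stopifnot(
    inherits(cohort, "trio_cohort"),
    inherits(phenotypes, "family_phenotypes")
  )
  if (!identical(phenotypes$family_id, cohort$family_id)) {
    stop_invalid("phenotypes must cover every family in the cohort, in order")
  }
  if (is.null(architecture)) {
    architecture <- cpg_architecture(config, seed = derive_seed(seed, 101))
  }
  stopifnot(inherits(architecture, "cpg_architecture"))
  arch <- architecture
  n_cpgs <- length(arch$cpg_id)
  n <- length(cohort$family_id)

  lat <- attr(phenotypes, "latents")
  z_d <- lat$z_direct
  z_ga <- (phenotypes$gestational_age - config$ga_mean_wk) / config$ga_sd_wk
  w <- config$cpg_ga_weight
  x_m <- (1 - w) * lat$z_maternal + w * z_ga

  with_seed(seed, {
    # array split and plates
    n_450k <- round(n * config$array_split)
    idx_450k <- sample.int(n, n_450k)
    array_label <- rep("EPIC", n)
    array_label[idx_450k] <- "450K"
    plate <- integer(n)
    for (arr in c("450K", "EPIC")) {
      sel <- which(array_label == arr)
      plate[sel] <- max(c(0L, plate)) +
        ceiling(seq_along(sel) / config$plate_size)
    }
    plate_id <- sprintf("plate%02d", plate)

    # cell proportions: Dirichlet around cord-blood composition
    g <- matrix(
      stats::rgamma(n * 7, shape = rep(config$cell_concentration *
                                         arch$cell_means, each = n)),
      nrow = n, ncol = 7,
      dimnames = list(cohort$family_id, names(arch$cell_means))
    )
    cell_props <- g / rowSums(g)

    # latent M-values
    M <- outer(z_d, arch$gamma_d) + outer(x_m, arch$gamma_i)
    M <- M + rep(arch$mu, each = n)
    M <- M + scale(cell_props, center = arch$cell_means, scale = FALSE) %*%
      arch$cell_eff
    M <- M + (array_label == "EPIC") %o% arch$array_shift
    n_plates <- max(plate)
    plate_shift <- matrix(
      stats::rnorm(n_plates * n_cpgs, 0, config$plate_sd), nrow = n_plates
    )
    M <- M + plate_shift[plate, , drop = FALSE]
    M <- M + matrix(stats::rnorm(n * n_cpgs, 0, config$cpg_noise_sd), nrow = n)

    beta <- m_to_beta(M)
    dimnames(beta) <- list(cohort$family_id, arch$cpg_id)

    structure(
      list(
        beta = beta,
        cpg_id = arch$cpg_id,
        sample_id = cohort$family_id,
        array_label = array_label,
        plate = plate_id,
        cell_props = cell_props
      ),
      truth = data.frame(cpg_id = arch$cpg_id, gamma_d = arch$gamma_d,
                         gamma_i = arch$gamma_i),
      class = "methylome"
    )
  })
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf(
    "Methylome: %d samples x %d CpGs (%d on 450K, %d on EPIC; %d plates)\n",
    nrow(x$beta), ncol(x$beta), sum(x$array_label == "450K"),
    sum(x$array_label == "EPIC"), length(unique(x$plate))
  ))
  invisible(x)
}

#' Simulate meta-EWAS weights for the birthweight methylation profile score
#'
#' Emulates a meta-analytic EWAS of birthweight: an independent cohort
#' sharing the same CpG architecture is simulated and each CpG's beta
#' value is regressed on birthweight; the returned weight is the per-CpG
#' regression coefficient of birthweight on beta (grams per unit beta),
#' the shape in which published EWAS weights are distributed. Like its
#' real counterparts, the table is restricted to CpGs reaching the
#' significance threshold in the reference EWAS (published profile
#' scores are built from genome-wide-significant probes); if fewer than
#' `min_keep` pass, the `min_keep` smallest p-values are kept so that
#' small simulations still yield a usable score.
#'
#' @param panel a `snp_panel`.
#' @param config a [generator_config()].
#' @param n_ewas reference-cohort size (default 8000, the scale of the
#'   cord-blood birthweight meta-EWAS).
#' @param sig_threshold per-CpG p-value cutoff for inclusion.
#' @param min_keep minimum number of CpGs retained.
#' @param seed RNG seed.
#' @param architecture the [cpg_architecture()] shared with the analysis
#'   cohort; when `NULL` one is derived from `seed` (only useful if the
#'   downstream methylome uses the same derivation).
#' @return data.frame of class `"ewas_weights"`: `cpg_id`, `weight`,
#'   `se`, `p` (only the selected CpGs).
#' @export
simulate_ewas_weights <- function(panel, config = generator_config(),
                                  n_ewas = 8000, sig_threshold = 1e-5,
                                  min_keep = 10, seed = NULL,
                                  architecture = NULL) {
  if (is.null(architecture)) {
    architecture <- cpg_architecture(config, seed = derive_seed(seed, 101))
  }
  with_seed(seed, {
    coh <- simulate_trios(panel, n_ewas)
    phen <- simulate_phenotypes(coh, panel, config)
    meth <- simulate_methylome(coh, phen, panel, config,
                               architecture = architecture)
    fit <- per_snp_simple_gwas(meth$beta, phen$birthweight)
    p <- 2 * stats::pt(-abs(fit$b / fit$se), n_ewas - 2)
    ww <- data.frame(
      cpg_id = meth$cpg_id, weight = fit$b, se = fit$se, p = p,
      stringsAsFactors = FALSE
    )
    keep <- which(ww$p <= sig_threshold)
    if (length(keep) < min_keep) {
      keep <- order(ww$p)[seq_len(min(min_keep, nrow(ww)))]
    }
    ww <- ww[sort(keep), , drop = FALSE]
    rownames(ww) <- NULL
    class(ww) <- c("ewas_weights", "data.frame")
    ww
  })
}
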