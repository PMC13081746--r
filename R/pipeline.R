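#' Simulate a complete study (panel, trios, weights, phenotypes, methylome)
#'
#' Convenience wrapper running every generator stage under one master
#' seed (deterministically split into per-stage substreams). The
#' reference GWAS weight sets and the EWAS weights are estimated in
#' independent simulated populations, as their real counterparts are.
#'
#' @param config a [generator_config()].
#' @param seed master seed.
#' @param weights `"estimated"` (reference-cohort GWAS) or `"true"`
#'   (noise-free generating effects).
#' @return list of class `"trio_study"`: `panel`, `cohort`, `phenotypes`,
#'   `methylome`, `weight_sets`, `ewas_weights`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1,
                            weights = c("estimated", "true")) {
  weights <- match.arg(weights)
  panel <- simulate_snp_panel(config$n_snps, config,
                              seed = derive_seed(seed, 1))
  cohort <- simulate_trios(panel, config$n_families,
                           seed = derive_seed(seed, 2))
  phenotypes <- simulate_phenotypes(cohort, panel, config,
                                    seed = derive_seed(seed, 3))
  architecture <- cpg_architecture(config, seed = derive_seed(seed, 40))
  methylome <- simulate_methylome(cohort, phenotypes, panel, config,
                                  seed = derive_seed(seed, 4),
                                  architecture = architecture)
  weight_sets <- if (weights == "true") {
    true_weight_sets(panel)
  } else {
    simulate_reference_gwas(panel, config$n_reference_duos,
                            seed = derive_seed(seed, 5), config = config)
  }
  ewas_weights <- simulate_ewas_weights(panel, config,
                                        seed = derive_seed(seed, 6),
                                        architecture = architecture)
  structure(
    list(
      panel = panel, cohort = cohort, phenotypes = phenotypes,
      methylome = methylome, weight_sets = weight_sets,
      ewas_weights = ewas_weights, architecture = architecture,
      config = config, seed = seed
    ),
    class = "trio_study"
  )
}

#' Load a study from files on disk
#'
#' Builds the same study object as [simulate_cohort()] from user-supplied
#' files in the package's standard shapes: trio dosage TSV, phenotype
#' TSV, methylation beta TSV + sample sheet, three GWAS weight-set TSVs
#' and an EWAS weight TSV. The SNP panel (ids, allele coding, frequency)
#' is reconstructed from the own-birthweight weight table and parental
#' allele frequencies.
#'
#' @param paths named list/vector with entries `dosages`, `phenotypes`,
#'   `methylome_beta`, `methylome_samples`, `weights_own`,
#'   `weights_fetal`, `weights_maternal`, `ewas_weights`.
#' @return a `trio_study` list.
#' @export
load_trio_study <- function(paths) {
  need <- c("dosages", "phenotypes", "methylome_beta", "methylome_samples",
            "weights_own", "weights_fetal", "weights_maternal",
            "ewas_weights")
  missing_keys <- setdiff(need, names(paths))
  if (length(missing_keys)) {
    stop_invalid("inputs block lacks entries: ",
                 paste(missing_keys, collapse = ", "))
  }
  for (k in need) {
    if (!file.exists(paths[[k]])) {
      stop_invalid("input file for '", k, "' not found: ", paths[[k]])
    }
  }
  cohort <- read_trio_dosages(paths[["dosages"]])
  phenotypes <- read_phenotypes(paths[["phenotypes"]])
  methylome <- read_methylome(paths[["methylome_beta"]],
                              paths[["methylome_samples"]])
  ws <- list(
    own = read_weight_set(paths[["weights_own"]]),
    fetal_effect = read_weight_set(paths[["weights_fetal"]]),
    maternal_effect = read_weight_set(paths[["weights_maternal"]])
  )
  ewas <- read_ewas_weights(paths[["ewas_weights"]])

  snp_id <- colnames(cohort$dosage_child)
  idx <- match(snp_id, ws$own$snp_id)
  if (anyNA(idx)) {
    stop_invalid("own-weight table does not cover all dosage SNPs")
  }
  freq <- (colMeans(cohort$dosage_mother) + colMeans(cohort$dosage_father)) / 4
  panel <- data.frame(
    snp_id = snp_id,
    effect_allele = ws$own$effect_allele[idx],
    other_allele = ws$own$other_allele[idx],
    freq = unname(freq),
    beta_fetal = NA_real_, beta_maternal = NA_real_, beta_own = NA_real_,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")

  structure(
    list(
      panel = panel, cohort = cohort, phenotypes = phenotypes,
      methylome = methylome, weight_sets = ws, ewas_weights = ewas,
      config = NULL, seed = NULL
    ),
    class = "trio_study"
  )
}

#' Assemble the per-family analysis table from a simulated study
#'
#' Computes the five polygenic scores (child/mother/father from the
#' own-birthweight weights; fetal-effect for the child and
#' maternal-effect for the mother from the a priori sets), z-scores each
#' and residualizes it on the first `pcs_k` genetic principal components
#' of the corresponding member's dosage matrix, converts the methylome
#' to M-values, and computes the MPS-BW z-scored within array.
#'
#' @param sim a [simulate_cohort()] result.
#' @param pcs_k number of genetic PCs (default 10; reduced automatically
#'   for small problems).
#' @param residualize residualize PGS on PCs (set `FALSE` to use plain
#'   z-scores, e.g. in simulations without population structure).
#' @return list: `data` (per-family data.frame with scores, phenotypes,
#'   array/plate/cell covariates and `mps`), `mvalues` (samples x CpGs).
#' @export
assemble_analysis_data <- function(sim, pcs_k = 10, residualize = TRUE) {
  stopifnot(inherits(sim, "trio_study"))
  panel <- sim$panel
  ws <- sim$weight_sets
  member_dosage <- list(
    child = sim$cohort$dosage_child,
    mother = sim$cohort$dosage_mother,
    father = sim$cohort$dosage_father
  )
  score_defs <- list(
    pgs_child = list(member = "child", set = "own"),
    pgs_mother = list(member = "mother", set = "own"),
    pgs_father = list(member = "father", set = "own"),
    pgs_fetal_effect = list(member = "child", set = "fetal_effect"),
    pgs_maternal_effect = list(member = "mother", set = "maternal_effect")
  )

  pcs <- list()
  if (residualize) {
    k <- min(pcs_k, length(sim$cohort$family_id) - 2L, nrow(panel) - 1L)
    pcs <- lapply(member_dosage, compute_genetic_pcs, k = k)
  }
  scores <- lapply(score_defs, function(d) {
    raw <- compute_pgs(member_dosage[[d$member]], ws[[d$set]], panel)
    if (residualize) {
      residualize_pgs(raw, pcs[[d$member]])
    } else {
      zscore(raw)
    }
  })

  mvalues <- beta_to_m(sim$methylome$beta)
  mps <- compute_mps(sim$methylome$beta, sim$ewas_weights,
                     sim$methylome$array_label)

  data <- data.frame(
    as.data.frame(sim$phenotypes),
    as.data.frame(scores),
    array_label = sim$methylome$array_label,
    plate = sim$methylome$plate,
    sim$methylome$cell_props,
    mps = mps$mps,
    stringsAsFactors = FALSE
  )
  list(data = data, mvalues = mvalues)
}

#' Maternal/fetal shares of the total genetic effect
#'
#' From the a priori GWAS-adjusted coefficients, each member's share of
#' the summed same-signed coefficients, rounded to the nearest percent
#' (e.g. maternal 105.8 and fetal 192.5 g/SD give a maternal share of
#' 105.8 / (105.8 + 192.5) = 35\%). Refuses (flags) when the
#' coefficients have opposite signs, where the share has no meaning.
#'
#' @param pooled a [pool_battery()] table (or battery table with
#'   `estimate` column) containing the adjusted model's two PGS terms.
#' @param model_id which model's coefficients to use (default 3).
#' @param outcome which outcome (default `"birthweight"`).
#' @return data.frame with `term`, `estimate`, `share_pct`, `refused`.
#' @export
summarize_effect_shares <- function(pooled, model_id = 3,
                                    outcome = "birthweight") {
  est_col <- if ("pooled_b" %in% names(pooled)) "pooled_b" else "estimate"
  sel <- pooled$model_id == model_id & pooled$outcome == outcome &
    !is.na(pooled$genetic_effect) &
    pooled$genetic_effect %in% c("direct", "indirect_maternal",
                                 "indirect_paternal")
  d <- pooled[sel, , drop = FALSE]
  if (nrow(d) < 2L) {
    stop_invalid("model ", model_id, " terms for outcome '", outcome,
                 "' not found in the results table")
  }
  est <- d[[est_col]]
  refused <- length(unique(sign(est))) > 1L
  share <- if (refused) rep(NA_real_, length(est)) else {
    round(100 * abs(est) / sum(abs(est)))
  }
  data.frame(
    term = d$term,
    genetic_effect = d$genetic_effect,
    estimate = est,
    share_pct = share,
    refused = refused,
    stringsAsFactors = FALSE
  )
}

# Forest-plot-ready table: member x adjusted/unadjusted estimates for one
# outcome, from the pooled results.
forest_table <- function(pooled, outcome) {
  est_col <- if ("pooled_b" %in% names(pooled)) "pooled_b" else "estimate"
  se_col <- if ("pooled_se" %in% names(pooled)) "pooled_se" else "se"
  member_of <- c(
    pgs_child = "child", pgs_fetal_effect = "child",
    pgs_mother = "mother", pgs_maternal_effect = "mother",
    pgs_father = "father"
  )
  model_name <- c("duo", "trio", "gwas_adjusted", "single", "single",
                  "single", "single", "single")
  d <- pooled[pooled$outcome == outcome &
                (!("scale" %in% names(pooled)) |
                   pooled$scale %in% c("raw", "mvalue")), , drop = FALSE]
  d <- d[d$term %in% names(member_of), , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)
  out <- data.frame(
    outcome = outcome,
    member = unname(member_of[d$term]),
    model = model_name[d$model_id],
    adjusted = ifelse(d$model_id %in% 1:3, "adjusted", "unadjusted"),
    weight_source = ifelse(
      d$term %in% c("pgs_fetal_effect", "pgs_maternal_effect"),
      "a_priori", "own"
    ),
    estimate = d[[est_col]],
    se = d[[se_col]],
    stringsAsFactors = FALSE
  )
  out$ci_lo <- out$estimate - 1.96 * out$se
  out$ci_hi <- out$estimate + 1.96 * out$se
  out[order(out$member, out$adjusted, out$model), ]
}

#' Run the whole pipeline end-to-end
#'
#' simulate -> scores -> model battery -> meta-analysis/FDR -> mediation,
#' from one declarative config, writing long-format and pooled result
#' tables, mediation tables, forest-plot-ready summaries and a JSON run
#' manifest (per-stage timings, seeds and output-file digests) to
#' `out_dir`.
#'
#' The config is a named list (or path to a YAML file) with blocks:
#' `simulate` ([generator_config()] arguments), and optional scalars
#' `models` (default 1:8), `boot` (mediation bootstrap replicates,
#' default 200), `pcs_k` (default 10), `n_top_cpgs` (CpG mediation
#' outcomes, default 7), `scales` (default `"mvalue"`).
#'
#' @param config named list or YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stochastic stage derives its stream
#'   from it.
#' @return the run manifest, invisibly; all tables are also returned in
#'   the `"results"` attribute.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_invalid("config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_invalid("config must be a list or a YAML path")
  if (!is.null(config$simulate) && !is.null(config$inputs)) {
    stop_invalid("config blocks 'simulate' and 'inputs' are mutually exclusive")
  }
  gen_cfg <- if (is.null(config$inputs)) {
    do.call(generator_config, config$simulate %||% list())
  } else {
    NULL
  }
  models <- config$models %||% 1:8
  boot <- config$boot %||% 200
  pcs_k <- config$pcs_k %||% 10
  n_top <- config$n_top_cpgs %||% 7
  scales <- config$scales %||% "mvalue"

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = list(), files = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2)
    )
    val
  }

  sim <- if (is.null(config$inputs)) {
    t_stage("simulate", simulate_cohort(gen_cfg, seed = seed))
  } else {
    t_stage("load", load_trio_study(config$inputs))
  }
  ad <- t_stage("scores", assemble_analysis_data(sim, pcs_k = pcs_k))

  outcomes <- c("birthweight", "mps", paste0("cpg:", sim$methylome$cpg_id))
  raw <- t_stage("models", run_model_battery(
    ad$data, outcomes, models = models, mvalues = ad$mvalues, scales = scales
  ))
  pooled <- t_stage("meta", pool_battery(raw))

  med <- t_stage("mediation", {
    med_tab <- impute_mediators(
      ad$data[, mediator_names()], seed = derive_seed(seed, 7)
    )
    mdat <- cbind(
      ad$data[, c("family_id", "sex", "birthweight", "mps",
                  "pgs_fetal_effect", "pgs_maternal_effect")],
      med_tab
    )
    exposures <- c("pgs_fetal_effect", "pgs_maternal_effect")
    # outcomes: birthweight, MPS, and the top FDR CpGs
    cpg_model <- if (3 %in% models) 3L else max(models)
    cpg_pool <- pooled[startsWith(pooled$outcome, "cpg:") &
                         pooled$model_id == cpg_model &
                         !is.na(pooled$q), ]
    top <- unique(cpg_pool$outcome[order(cpg_pool$q)])[
      seq_len(min(n_top, length(unique(cpg_pool$outcome))))
    ]
    fam_size <- enumerate_pathways(
      length(mediator_names()), length(exposures), length(top) + 2L
    )$count
    mv_res <- residualize_methylation(ad$mvalues, ad$data)
    fits <- list()
    fits[["birthweight"]] <- fit_multiple_mediation(
      mdat, exposures, mediator_names(), "birthweight",
      boot = boot, family_size = fam_size, seed = derive_seed(seed, 8)
    )
    fits[["mps"]] <- fit_multiple_mediation(
      mdat, exposures, mediator_names(), "mps",
      boot = boot, family_size = fam_size, seed = derive_seed(seed, 9)
    )
    for (oc in top) {
      cg <- sub("^cpg:", "", oc)
      mdat[[cg]] <- mv_res[, cg]
      fits[[oc]] <- fit_multiple_mediation(
        mdat, exposures, mediator_names(), cg,
        boot = boot, family_size = fam_size, seed = derive_seed(seed, 10)
      )
    }
    # reverse direction: MPS as mediator of genetic effects on birthweight
    fits[["dnam_as_mediator"]] <- fit_dnam_as_mediator(
      mdat, exposures, "mps", outcome = "birthweight",
      boot = boot, seed = derive_seed(seed, 11)
    )
    fits
  })

  med_tabs <- do.call(rbind, lapply(names(med), function(nm) {
    pw <- med[[nm]]$pathways
    pw$outcome <- nm
    pw
  }))
  med_totals <- do.call(rbind, lapply(names(med), function(nm) {
    tt <- med[[nm]]$totals
    tt$outcome <- nm
    tt
  }))

  shares <- if (3 %in% models) summarize_effect_shares(pooled) else NULL
  f_bw <- forest_table(pooled, "birthweight")
  f_mps <- forest_table(pooled, "mps")

  paths <- c(
    results_raw = "results_raw.tsv", results_pooled = "results_pooled.tsv",
    mediation = "mediation.tsv", mediation_totals = "mediation_totals.tsv",
    forest_birthweight = "forest_birthweight.tsv",
    forest_mps = "forest_mps.tsv"
  )
  tabs <- list(raw, pooled, med_tabs, med_totals, f_bw, f_mps)
  for (i in seq_along(paths)) {
    if (!is.null(tabs[[i]])) {
      write_tsv_exact(tabs[[i]], file.path(out_dir, paths[[i]]))
    }
  }
  if (!is.null(shares)) {
    write_tsv_exact(shares, file.path(out_dir, "effect_shares.tsv"))
    paths <- c(paths, effect_shares = "effect_shares.tsv")
  }
  resolved <- list(models = models, boot = boot, pcs_k = pcs_k,
                   n_top_cpgs = n_top, seed = seed)
  if (is.null(config$inputs)) {
    resolved$simulate <- unclass(gen_cfg)
  } else {
    resolved$inputs <- config$inputs
  }
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  paths <- c(paths, config = "config_resolved.yaml")

  manifest$files <- lapply(paths, function(p) {
    f <- file.path(out_dir, p)
    list(path = p, md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  attr(manifest, "results") <- list(
    raw = raw, pooled = pooled, mediation = med, shares = shares,
    forest_birthweight = f_bw, forest_mps = f_mps, sim = sim, analysis = ad
  )
  invisible(manifest)
}
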