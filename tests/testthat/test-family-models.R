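# Shared miniature analysis dataset for the model battery tests.
battery_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- tiny_study(seed = 70, missingness = 0)
      ad <- assemble_analysis_data(sim, pcs_k = 4)
      cache <<- list(sim = sim, data = ad$data, mvalues = ad$mvalues)
    }
    cache
  }
})

test_that("OLS fits match a brute-force normal-equations oracle", {
  set.seed(71)
  n <- 40
  dat <- data.frame(
    birthweight = rnorm(n, 3500, 500),
    pgs_child = rnorm(n),
    pgs_mother = rnorm(n),
    sex = rbinom(n, 1, 0.5)
  )
  fit <- fit_family_model(model_spec(1), dat)
  tab <- fit$coefficients

  X <- cbind(1, dat$pgs_child, dat$pgs_mother, dat$sex)
  XtXi <- solve(crossprod(X))
  b <- XtXi %*% crossprod(X, dat$birthweight)
  resid <- dat$birthweight - X %*% b
  s2 <- sum(resid^2) / (n - 4)
  se <- sqrt(diag(XtXi) * s2)
  tval <- b / se
  p <- 2 * pt(-abs(tval), n - 4)

  ord <- c("(Intercept)", "pgs_child", "pgs_mother", "sex")
  expect_equal(tab$estimate[match(ord, tab$term)], as.vector(b),
               tolerance = 1e-8)
  expect_equal(tab$se[match(ord, tab$term)], as.vector(se), tolerance = 1e-8)
  expect_equal(tab$p[match(ord, tab$term)], as.vector(p), tolerance = 1e-8)
  expect_equal(tab$n[1], n)
  # CI = estimate +/- t_{0.975, df} * se
  expect_equal(tab$ci_hi - tab$estimate, qt(0.975, n - 4) * tab$se,
               tolerance = 1e-10)
})

test_that("model specs enforce the battery design", {
  expect_error(model_spec(0), "1..8")
  expect_error(model_spec(9), "1..8")
  expect_identical(model_spec(2)$terms,
                   c(direct = "pgs_child", indirect_maternal = "pgs_mother",
                     indirect_paternal = "pgs_father"))
  expect_identical(unname(model_spec(8)$terms), "pgs_maternal_effect")

  fx <- battery_fixture()
  # methylation outcomes always carry plate + cell covariates
  cpg <- paste0("cpg:", fx$sim$methylome$cpg_id[1])
  dat <- cbind(fx$data, setNames(
    data.frame(fx$mvalues[, 1]), fx$sim$methylome$cpg_id[1]
  ))
  f <- fit_family_model(model_spec(1, cpg, subcohort = "450K"), dat)
  expect_true(all(cell_names <- c("B", "CD4T", "CD8T", "Gran", "Mono", "NK")
                  %in% f$coefficients$term))
  expect_false("nRBC" %in% f$coefficients$term)
  expect_true(any(grepl("^plate", f$coefficients$term)))
})

test_that("rank deficiency and insufficient n raise informative errors", {
  fx <- battery_fixture()
  dat <- fx$data
  dat$pgs_mother <- dat$pgs_child
  expect_error(fit_family_model(model_spec(1), dat), "collinear")
  expect_error(fit_family_model(model_spec(1), fx$data[1:4, ]),
               "insufficient")
  expect_error(fit_family_model(model_spec(1), fx$data[, -3]), "absent")
})

test_that("sex-interaction fits obey the stratum-slope identity", {
  fx <- battery_fixture()
  f <- fit_sex_interaction(model_spec(3), fx$data)
  tab <- f$coefficients
  expect_true("pgs_fetal_effect:sex" %in% tab$term)
  expect_true(all(c("pgs_fetal_effect", "pgs_maternal_effect") %in% tab$term))

  # female-stratum slope = main + interaction, exactly (linear identity,
  # checked on a saturated single-PGS design)
  d <- fx$data
  fit_int <- lm(birthweight ~ pgs_child * sex, data = d)
  fit_strat <- lm(birthweight ~ pgs_child, data = d[d$sex == 1, ])
  expect_equal(
    unname(coef(fit_int)["pgs_child"] + coef(fit_int)["pgs_child:sex"]),
    unname(coef(fit_strat)["pgs_child"]),
    tolerance = 1e-8
  )
})

test_that("interaction recovery: a female-only slope shows up as delta", {
  set.seed(73)
  n <- 3000
  pgs <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  delta <- 80
  y <- 3500 + 150 * pgs + delta * pgs * sex + rnorm(n, 0, 400)
  dat <- data.frame(birthweight = y, pgs_child = pgs, pgs_mother = rnorm(n),
                    sex = sex)
  f <- fit_sex_interaction(model_spec(1), dat)
  row <- f$coefficients[f$coefficients$term == "pgs_child:sex", ]
  expect_true(row$ci_lo <= delta && delta <= row$ci_hi)

  # equal effects in both sexes: interaction CI covers 0
  y0 <- 3500 + 150 * pgs + rnorm(n, 0, 400)
  dat0 <- dat
  dat0$birthweight <- y0
  f0 <- fit_sex_interaction(model_spec(1), dat0)
  row0 <- f0$coefficients[f0$coefficients$term == "pgs_child:sex", ]
  expect_true(row0$ci_lo <= 0 && 0 <= row0$ci_hi)
})

test_that("a null maternal effect gives nominal null coverage in the duo
           model", {
  cfg <- generator_config(n_families = 400, n_snps = 100, var_indirect = 0,
                          ga_a = 0, missingness = 0)
  panel <- simulate_snp_panel(100, cfg, seed = 75)
  ws <- true_weight_sets(panel)
  # the own-birthweight set is pure beta_fetal here; mother PGS is null
  covered <- logical(60)
  for (s in seq_len(60)) {
    coh <- simulate_trios(panel, 400, seed = 7500 + s)
    phen <- simulate_phenotypes(coh, panel, cfg, seed = 7600 + s)
    dat <- data.frame(
      birthweight = phen$birthweight, sex = phen$sex,
      pgs_child = zscore(compute_pgs(coh$dosage_child, ws$own, panel)),
      pgs_mother = zscore(compute_pgs(coh$dosage_mother, ws$own, panel))
    )
    tab <- fit_family_model(model_spec(1), dat)$coefficients
    r <- tab[tab$term == "pgs_mother", ]
    covered[s] <- r$ci_lo <= 0 && 0 <= r$ci_hi
  }
  expect_gte(mean(covered), 0.88) # 95% nominal, 60-replicate margin
})

test_that("the battery enumerates and reproduces requested fits", {
  fx <- battery_fixture()
  res <- run_model_battery(fx$data, "birthweight", models = 1:8)
  # 8 models, PGS terms only: 2 + 3 + 2 + 1*5 = 12 rows
  expect_identical(nrow(res), 12L)
  expect_identical(sort(unique(res$model_id)), 1:8)
  expect_true(all(res$subcohort == "pooled"))

  cpgs <- paste0("cpg:", fx$sim$methylome$cpg_id)
  res_cpg <- run_model_battery(
    fx$data, cpgs, models = 1, mvalues = fx$mvalues, scales = "mvalue"
  )
  # 12 CpGs x 2 PGS terms x 2 subcohorts
  expect_identical(nrow(res_cpg), length(cpgs) * 2L * 2L)
  expect_setequal(unique(res_cpg$subcohort), c("450K", "EPIC"))

  res_rep <- run_model_battery(
    fx$data, cpgs, models = 1, mvalues = fx$mvalues, scales = "mvalue"
  )
  expect_identical(res_rep, res_cpg)

  # both scales double the rows and agree in sign away from boundaries
  res2 <- run_model_battery(
    fx$data, cpgs, models = 1, mvalues = fx$mvalues
  )
  expect_identical(nrow(res2), 2L * nrow(res_cpg))
})

test_that("the shared-QR CpG fast path equals per-CpG lm fits", {
  fx <- battery_fixture()
  cpgs <- fx$sim$methylome$cpg_id[1:4]
  res <- run_model_battery(
    fx$data, paste0("cpg:", cpgs), models = 3, mvalues = fx$mvalues,
    scales = "mvalue"
  )
  for (cg in cpgs) {
    dat <- cbind(fx$data, setNames(data.frame(fx$mvalues[, cg]), cg))
    ref <- fit_family_model(
      model_spec(3, paste0("cpg:", cg), subcohort = "EPIC"), dat
    )$coefficients
    for (term in c("pgs_fetal_effect", "pgs_maternal_effect")) {
      got <- res[res$outcome == paste0("cpg:", cg) & res$term == term &
                   res$subcohort == "EPIC", ]
      want <- ref[ref$term == term, ]
      expect_equal(got$estimate, want$estimate, tolerance = 1e-10)
      expect_equal(got$se, want$se, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  }
})

test_that("single-PGS estimates exceed their mutually adjusted versions", {
  # with positively correlated family PGSs and same-signed effects the
  # unadjusted (single) coefficient absorbs part of the other member's
  sim <- simulate_cohort(
    generator_config(n_families = 1500, n_snps = 150, n_cpgs = 4,
                     n_reference_duos = 20000, missingness = 0),
    seed = 74
  )
  ad <- assemble_analysis_data(sim, pcs_k = 4)
  res <- run_model_battery(ad$data, "birthweight", models = c(1, 4, 5))
  est <- function(m, term) res$estimate[res$model_id == m & res$term == term]
  expect_gt(abs(est(4, "pgs_child")), abs(est(1, "pgs_child")) * 0.9)
  expect_gt(abs(est(5, "pgs_mother")), abs(est(1, "pgs_mother")))
})

test_that("adding an orthogonal covariate leaves PGS estimates unchanged", {
  fx <- battery_fixture()
  dat <- fx$data
  n <- nrow(dat)
  spec <- model_spec(3)
  base <- fit_family_model(spec, dat)$coefficients
  # build a covariate exactly orthogonal to the design columns
  X <- cbind(1, dat$pgs_fetal_effect, dat$pgs_maternal_effect, dat$sex)
  raw <- rnorm(n)
  dat$orth <- raw - X %*% solve(crossprod(X), crossprod(X, raw))
  refit <- lm(
    birthweight ~ pgs_fetal_effect + pgs_maternal_effect + sex + orth,
    data = dat
  )
  for (term in c("pgs_fetal_effect", "pgs_maternal_effect")) {
    expect_equal(unname(coef(refit)[term]),
                 base$estimate[base$term == term], tolerance = 1e-8)
  }
})

test_that("battery failures are recorded without aborting the batch", {
  fx <- battery_fixture()
  dat <- fx$data
  dat$pgs_father <- NULL # trio model cannot be fitted
  res <- run_model_battery(dat, "birthweight", models = c(1, 2, 3))
  expect_setequal(unique(res$model_id), c(1L, 3L))
  fails <- attr(res, "failures")
  expect_length(fails, 1L)
  expect_match(fails[[1]]$message, "pgs_father")
})
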