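test_that("pathway enumeration is the labelled cross product", {
  e <- enumerate_pathways(13, 2, 7)
  expect_identical(e$count, 182L)
  expect_identical(enumerate_pathways(1, 1, 1)$count, 1L)
  expect_identical(enumerate_pathways(13, 2, 8)$count, 208L)
  expect_identical(nrow(e$grid), 182L)
  expect_error(enumerate_pathways(0, 2, 7), ">= 1")
  # stable ordering and name support
  e2 <- enumerate_pathways(c("ga", "bmi"), c("fetal", "maternal"), "bw")
  expect_identical(e2$grid$mediator[1:2], c("ga", "bmi"))
  expect_identical(e2$count, 4L)
})

# a small linear mediation world with known paths
make_med_data <- function(n, seed, a = 0.5, b = 0.4, c_direct = 0.3) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  m1 <- a * x1 + rnorm(n)
  m2 <- rnorm(n)
  y <- c_direct * x1 + b * m1 + 0.2 * sex + rnorm(n)
  data.frame(x1 = x1, x2 = x2, sex = sex, m1 = m1, m2 = m2, y = y)
}

test_that("the all-linear estimator satisfies c = c' + sum(a*b) exactly", {
  dat <- make_med_data(300, seed = 80)
  fit <- fit_multiple_mediation(
    dat, exposures = c("x1", "x2"), mediators = c("m1", "m2"), outcome = "y",
    standardize = FALSE, adjust_a_for_sex = TRUE, links = "linear", boot = 0
  )
  tot <- fit$totals
  expect_equal(tot$c, tot$c_prime + tot$total_indirect, tolerance = 1e-8)

  # and against a direct OLS computation of each path
  a_or <- coef(lm(m1 ~ x1 + x2 + sex, dat))["x1"]
  b_or <- coef(lm(y ~ x1 + x2 + m1 + m2 + sex, dat))["m1"]
  pw <- fit$pathways
  got <- pw[pw$exposure == "x1" & pw$mediator == "m1", ]
  expect_equal(got$a, unname(a_or), tolerance = 1e-10)
  expect_equal(got$b, unname(b_or), tolerance = 1e-10)
  expect_equal(got$indirect, unname(a_or * b_or), tolerance = 1e-10)
})

test_that("bootstrap intervals recover the generating indirect effect", {
  dat <- make_med_data(1500, seed = 81)
  fit <- fit_multiple_mediation(
    dat, c("x1", "x2"), c("m1", "m2"), "y",
    standardize = FALSE, links = "linear", boot = 300, seed = 82
  )
  pw <- fit$pathways
  true_ind <- 0.5 * 0.4
  got <- pw[pw$exposure == "x1" & pw$mediator == "m1", ]
  expect_true(got$ci_lo <= true_ind && true_ind <= got$ci_hi)
  expect_lt(got$p, 0.01)
  # null pathway: CI covers 0
  null_row <- pw[pw$exposure == "x2" & pw$mediator == "m2", ]
  expect_true(null_row$ci_lo <= 0 && 0 <= null_row$ci_hi)
  # q-values are BH over the pathway family
  expect_equal(fit$pathways$q, bh_fdr(pmin(pmax(fit$pathways$p, 1e-300), 1)),
               tolerance = 1e-12)
  # proportion mediated = indirect / total effect
  tot <- fit$totals[fit$totals$exposure == "x1", ]
  expect_equal(tot$prop_mediated, tot$total_indirect / tot$c,
               tolerance = 1e-12)
})

test_that("mediation is reproducible under a seed and guards its inputs", {
  dat <- make_med_data(200, seed = 83)
  f1 <- fit_multiple_mediation(dat, "x1", c("m1", "m2"), "y",
                               boot = 50, seed = 7)
  f2 <- fit_multiple_mediation(dat, "x1", c("m1", "m2"), "y",
                               boot = 50, seed = 7)
  expect_identical(f1$pathways, f2$pathways)
  expect_error(
    fit_multiple_mediation(dat, "x1", c("m1", "m1"), "y"), "distinct"
  )
  expect_error(
    fit_multiple_mediation(dat, "x1", c("m1", "y"), "y"), "cannot also"
  )
  expect_error(
    fit_multiple_mediation(dat, "x1", "absent", "y"), "absent"
  )
})

test_that("binary mediators go through the probit a-path by default", {
  set.seed(84)
  n <- 2000
  x <- rnorm(n)
  mbin <- rbinom(n, 1, pnorm(-0.3 + 0.5 * x))
  y <- 0.4 * mbin + 0.2 * x + rnorm(n)
  dat <- data.frame(x = x, sex = rbinom(n, 1, 0.5), mbin = mbin, y = y)
  fit <- fit_multiple_mediation(dat, "x", "mbin", "y", boot = 0)
  expect_identical(fit$binary_mediators, "mbin")
  a_probit <- coef(glm(mbin ~ x, binomial("probit"), data = dat))["x"]
  expect_equal(fit$pathways$a, unname(a_probit), tolerance = 1e-8)
  # linear links can be forced
  fit_lin <- fit_multiple_mediation(dat, "x", "mbin", "y", boot = 0,
                                    links = "linear")
  a_lin <- coef(lm(mbin ~ x, dat))["x"]
  expect_equal(fit_lin$pathways$a, unname(a_lin), tolerance = 1e-8)
})

test_that("DNAm-as-mediator agrees with the general estimator", {
  sim <- tiny_study(seed = 85, missingness = 0)
  ad <- assemble_analysis_data(sim, pcs_k = 4)
  dat <- ad$data
  exposures <- c("pgs_fetal_effect", "pgs_maternal_effect")

  # single-mediator MPS case == general estimator with one mediator
  f_wrap <- fit_dnam_as_mediator(dat, exposures, "mps", boot = 0)
  f_gen <- fit_multiple_mediation(dat, exposures, "mps", "birthweight",
                                  boot = 0)
  expect_equal(f_wrap$pathways$indirect, f_gen$pathways$indirect,
               tolerance = 1e-12)

  # joint CpG mediators: invariant to mediator ordering
  mv <- residualize_methylation(ad$mvalues[, 1:5], dat)
  f_a <- fit_dnam_as_mediator(dat, exposures, mv, boot = 0)
  f_b <- fit_dnam_as_mediator(dat, exposures, mv[, 5:1], boot = 0)
  key_a <- paste(f_a$pathways$exposure, f_a$pathways$mediator)
  key_b <- paste(f_b$pathways$exposure, f_b$pathways$mediator)
  expect_equal(f_a$pathways$indirect,
               f_b$pathways$indirect[match(key_a, key_b)], tolerance = 1e-10)
  expect_equal(f_a$totals$total_indirect, f_b$totals$total_indirect,
               tolerance = 1e-10)
})

test_that("a null mediator world shows no mediation", {
  # generator with the GA link switched off and no other mediator links
  sim <- simulate_cohort(
    generator_config(n_families = 800, n_snps = 80, n_cpgs = 6, ga_a = 0,
                     n_reference_duos = 5000, missingness = 0),
    seed = 86
  )
  ad <- assemble_analysis_data(sim, pcs_k = 4)
  fit <- fit_multiple_mediation(
    ad$data, c("pgs_fetal_effect", "pgs_maternal_effect"),
    mediator_names(), "birthweight", boot = 200, seed = 87
  )
  covered <- fit$pathways$ci_lo <= 0 & 0 <= fit$pathways$ci_hi
  expect_gte(mean(covered), 0.9)
  expect_lt(max(abs(fit$totals$prop_mediated)), 0.15)
})
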