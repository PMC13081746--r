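test_that("polygenic scoring is the harmonized weighted dosage sum", {
  panel <- toy_panel()
  dos <- matrix(c(0, 1, 2, 1), nrow = 2,
                dimnames = list(c("s1", "s2"), c("rs1", "rs2")))
  ws <- weight_set(panel, weight = c(10, -5), se = c(1, 1), "own")

  expect_equal(compute_pgs(dos, ws, panel), c(-10, 5))

  # all-zero weights give all-zero scores
  ws0 <- weight_set(panel, weight = c(0, 0), se = c(1, 1), "own")
  expect_equal(compute_pgs(dos, ws0, panel), c(0, 0))

  # swapping effect/other alleles with a negated weight only shifts the
  # scores by a constant, so z-scores are unchanged
  ws_flip <- ws
  ws_flip$effect_allele[1] <- panel$other_allele[1]
  ws_flip$other_allele[1] <- panel$effect_allele[1]
  ws_flip$weight[1] <- -ws_flip$weight[1]
  dos4 <- rbind(dos, matrix(c(2, 0, 0, 2), nrow = 2,
                            dimnames = list(c("s3", "s4"), c("rs1", "rs2"))))
  z_ref <- scale(compute_pgs(dos4, ws, panel))[, 1]
  z_flip <- scale(compute_pgs(dos4, ws_flip, panel))[, 1]
  expect_equal(z_flip, z_ref, tolerance = 1e-12)
})

test_that("scoring rejects unresolvable alleles and duplicate SNPs", {
  panel <- toy_panel()
  dos <- matrix(c(0, 1, 2, 1), nrow = 2,
                dimnames = list(NULL, c("rs1", "rs2")))
  ws <- weight_set(panel, weight = c(1, 1), se = c(1, 1), "own")
  ws$effect_allele[2] <- "G" # neither orientation matches C/T
  expect_error(compute_pgs(dos, ws, panel), "rs2")

  ws_dup <- rbind(ws, ws[1, ])
  expect_error(compute_pgs(ws_dup$snp_id, ws_dup, panel), "duplicate")

  ws_extra <- weight_set(panel, weight = c(1, 1), se = c(1, 1), "own")
  ws_extra$snp_id[2] <- "rs_absent"
  expect_error(compute_pgs(dos, ws_extra, panel), "rs_absent")
})

test_that("genetic PCs reproduce a brute-force eigendecomposition", {
  set.seed(101)
  X <- matrix(rbinom(50 * 100, 2, 0.4), nrow = 50)
  colnames(X) <- paste0("rs", 1:100)
  pcs <- compute_genetic_pcs(X, k = 5)

  Xs <- scale(X)
  ev <- eigen(stats::cov(Xs), symmetric = TRUE)
  for (j in 1:5) {
    ref <- Xs %*% ev$vectors[, j]
    got <- pcs$scores[, j]
    if (sign(sum(ref * got)) < 0) ref <- -ref
    expect_lt(max(abs(got - ref)), 1e-8)
  }
  # pairwise orthogonality of score columns
  cp <- crossprod(pcs$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # unit-norm loadings
  expect_equal(unname(colSums(pcs$loadings^2)), rep(1, 5), tolerance = 1e-10)
  # sign convention: largest-magnitude loading positive
  for (j in 1:5) {
    l <- pcs$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("PC defaults and guards match the design", {
  expect_identical(formals(compute_genetic_pcs)$k, 10)
  set.seed(7)
  X <- matrix(rbinom(30 * 40, 2, 0.5), nrow = 30)
  expect_error(compute_genetic_pcs(X, k = 40), "at least k \\+ 1 samples")
  expect_error(compute_genetic_pcs(X[, 1:10], k = 10), "k must be")
  X[, 3] <- 1L
  expect_warning(compute_genetic_pcs(X, k = 2), "zero-variance")
})

test_that("PGS residualization equals the brute-force hat-matrix residual", {
  set.seed(11)
  n <- 30
  pcs <- matrix(rnorm(n * 4), n, 4)
  raw <- rnorm(n, 50, 10)

  res <- residualize_pgs(raw, pcs)
  X <- cbind(1, pcs)
  z <- (raw - mean(raw)) / sd(raw)
  oracle <- as.vector((diag(n) - X %*% solve(crossprod(X)) %*% t(X)) %*% z)
  expect_equal(unname(res), oracle / sd(oracle), tolerance = 1e-10)

  # orthogonal to every PC, idempotent
  expect_lt(max(abs(crossprod(pcs, res))), 1e-8)
  expect_equal(unname(residualize_pgs(res, pcs)), unname(res),
               tolerance = 1e-10)

  # PCs orthogonal to the score by construction: residual == z-score
  q <- qr.Q(qr(cbind(z, matrix(rnorm(n * 3), n))))[, 2:4]
  expect_equal(unname(residualize_pgs(raw, q)), unname(z), tolerance = 1e-10)

  expect_error(residualize_pgs(raw[-1], pcs), "different samples")
})

test_that("beta/M conversion matches the closed form and round-trips", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.75), log2(3), tolerance = 1e-12)
  grid <- seq(0.001, 0.999, length.out = 201)
  expect_equal(m_to_beta(beta_to_m(grid)), grid, tolerance = 1e-12)
  expect_error(beta_to_m(0), "strictly in")
  expect_error(beta_to_m(c(0.2, 1)), "strictly in")
})

test_that("KNN imputation averages the nearest CpG rows", {
  set.seed(21)
  B <- matrix(runif(6 * 5, 0.2, 0.8), nrow = 6,
              dimnames = list(paste0("cg", 1:6), paste0("s", 1:5)))
  expect_identical(knn_impute_methylation(B), B)

  Bm <- B
  Bm[2, 3] <- NA
  # oracle: exhaustive distance scan over the observed columns of row 2
  obs <- setdiff(1:5, 3)
  d <- apply(B[-2, obs, drop = FALSE], 1,
             function(r) sqrt(sum((r - B[2, obs])^2) / 4 * 5))
  nearest <- names(which.min(d))
  imp1 <- knn_impute_methylation(Bm, k = 1)
  expect_equal(imp1[2, 3], B[nearest, "s3"])
  # only the hole changes, and stays in (0,1)
  expect_identical(imp1[-2, ], Bm[-2, ])
  impk <- knn_impute_methylation(Bm, k = 3)
  expect_true(impk[2, 3] > 0 && impk[2, 3] < 1)

  Ball <- B
  Ball[4, ] <- NA
  expect_error(knn_impute_methylation(Ball), "cg4")
  Bheavy <- B
  Bheavy[5, 1:4] <- NA
  expect_error(knn_impute_methylation(Bheavy), "ceiling")
})

test_that("MPS is the z-scored weighted beta sum over shared CpGs", {
  B <- matrix(c(0.2, 0.4, 0.8, 0.6), nrow = 2,
              dimnames = list(c("s1", "s2"), c("cgA", "cgB")))
  ww <- data.frame(cpg_id = c("cgA", "cgB"), weight = c(1, -1))
  mps <- compute_mps(B, ww)
  expect_equal(mps$raw, c(-0.6, -0.2), tolerance = 1e-12)
  # sample (n-1) SD convention: sd = sqrt(0.08)
  expect_equal(mps$mps, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_identical(attr(mps, "n_cpgs_used"), 2L)

  # weights for absent CpGs are dropped; the intersection is recorded
  ww3 <- rbind(ww, data.frame(cpg_id = "cgC", weight = 99))
  mps3 <- compute_mps(B, ww3)
  expect_identical(attr(mps3, "n_cpgs_used"), 2L)
  expect_equal(mps3$mps, mps$mps)

  # invariant to CpG order and to zero-weight additions
  set.seed(3)
  B2 <- matrix(runif(40, 0.1, 0.9), nrow = 4,
               dimnames = list(paste0("s", 1:4), paste0("cg", 1:10)))
  ww2 <- data.frame(cpg_id = paste0("cg", 1:10), weight = rnorm(10))
  ref <- compute_mps(B2, ww2)$mps
  expect_equal(compute_mps(B2, ww2[sample(10), ])$mps, ref, tolerance = 1e-12)
  ww2z <- rbind(ww2, data.frame(cpg_id = "cgZ", weight = 0))
  expect_equal(compute_mps(B2[, sample(10)], ww2z)$mps, ref, tolerance = 1e-12)

  # degenerate cases error
  ww0 <- data.frame(cpg_id = c("cgA", "cgB"), weight = c(0, 0))
  expect_error(compute_mps(B, ww0), "degenerate")
  expect_error(compute_mps(B, data.frame(cpg_id = "cgX", weight = 1)),
               "no CpGs shared")
  expect_error(compute_mps(B, rbind(ww, ww[1, ])), "duplicate")
})

test_that("MPS z-scoring is applied within each array subcohort", {
  set.seed(5)
  B <- matrix(runif(12 * 6, 0.2, 0.8), nrow = 12,
              dimnames = list(paste0("s", 1:12), paste0("cg", 1:6)))
  ww <- data.frame(cpg_id = paste0("cg", 1:6), weight = rnorm(6))
  arr <- rep(c("450K", "EPIC"), each = 6)
  mps <- compute_mps(B, ww, arr)
  for (a in unique(arr)) {
    expect_equal(mean(mps$mps[arr == a]), 0, tolerance = 1e-9)
    expect_equal(sd(mps$mps[arr == a]), 1, tolerance = 1e-9)
  }
})
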