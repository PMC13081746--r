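---
title: "Methods: family-based genetic effects on neonatal DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based genetic effects on neonatal DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimands

A birthweight-associated variant can influence a newborn's phenotype by
two routes. Transmitted to the child, it acts through the child's own
physiology (a *direct* or fetal effect). Carried by the mother — whether
or not transmitted — it can shape the in-utero environment
(a *maternal indirect* effect). `triomethyl` estimates both routes for
outcomes measured at birth (birthweight itself, single-CpG cord-blood
DNA methylation, and a methylation profile score), using two
complementary identification strategies:

* **A posteriori adjustment**: polygenic scores built from an
  own-genotype/own-birthweight GWAS for child, mother and father, with
  family members' scores mutually adjusted in one regression (the duo
  and trio models). Because parent and child scores correlate at ~0.5
  by transmission, each coefficient isolates one member's contribution.
* **A priori adjustment**: scores built from a duo-design GWAS that
  already partitioned SNP effects into fetal (child genotype adjusted
  for mother) and maternal (mother adjusted for child) components, so a
  single regression of the outcome on fetal-effect and maternal-effect
  scores separates the routes at the weight level.

The two strategies are not interchangeable: an own-genotype weight
absorbs part of the maternal effect (a person's genotype tags their
mother's at r = 1/2), so residualizing a traditional maternal PGS on
the child PGS removes shared transmitted variation but cannot recover
the SNP-level partition. The simulator encodes exactly this mechanism
(`beta_own = beta_fetal + 0.5 * beta_maternal`), which is why the
package can reproduce the qualitative contrast — a priori maternal
scores predict methylation outcomes more strongly than a posteriori
residualized ones — as a testable property rather than an anecdote.

# The generator and its calibration

The synthetic cohort is the package's test bed; its defaults are fixed
study conditions, not tuning knobs.

**Genetics.** SNPs are independent biallelic loci with effect-allele
frequencies Uniform(0.05, 0.95); parental genotypes are Binomial(2, p)
(Hardy–Weinberg, random mating) and children receive one fair
Mendelian draw per parent. Per-SNP fetal and maternal effects are
independent normals, rescaled once so the aggregate genetic values
explain exactly the configured shares of birthweight variance — the
betas are then true grams-per-allele effects, which keeps
parameter-recovery truths exact. Linkage disequilibrium is deliberately
absent, so no shrinkage re-weighting of scores is needed; this is a
simplification relative to real GWAS weights.

**Phenotype model.** On the standardized scale,

> bw = √0.15 · z_d + (√0.04 − 0.12·0.46) · z_m + 0.46 · z_GA + sex + ε,
> z_GA = 0.12 · z_m + noise,

scaled to mean 3534.61 g, SD 509.91 g (gestational age 40.10 ± 1.48
weeks; females, coded 1, 100 g lighter). The shares were chosen once:
a direct share of 0.15 (≈ 0.39 SD per SD of score, matching the
190–230 g/SD direct estimates such cohorts report) and a total
maternal share of 0.04 (0.2 SD ≈ 102 g/SD). With the gestational-age
paths a = 0.12 and b = 0.46, these defaults *imply* a proportion
mediated of 0.12·0.46/0.2 = 27.6% — the mediation benchmark is a
consequence of the architecture, not a separately tuned constant. The
twelve remaining prenatal mediators (parity, BMI, maternal age,
insulin, folate, homocysteine, diet score, psychopathology, smoking,
hypertensive disorders, education, income) are drawn with realistic
cohort means, SDs, prevalences and item-non-response rates
(log-normals for skewed biomarkers, latent-normal thresholds for
binary/ordinal items) and are independent of genotype by default; all
links are config-exposed.

**Weights.** Reference GWAS weight sets are estimated, not copied from
the truth: an independent two-generation population of mother–child
duos is simulated (grandmothers give mothers their own birthweights),
and per-SNP regressions produce the own-birthweight set (simple
regression) and the fetal/maternal-effect sets (bivariate regression
on child and mother dosage jointly). Estimation noise attenuates
score–outcome slopes by roughly √(v/(v+e)) with v the per-SNP effect
variance and e the sampling variance; at the default 50,000 duos and a
300-SNP panel this factor is ≈ 0.95, small enough that recovery checks
against generating values are meaningful. `true_weight_sets()` provides
the noise-free alternative for harnesses where attenuation would bias
coverage.

**Methylome.** The CpG architecture — baseline M-values, which CpGs
carry direct and/or maternal effects and how large, cell-type effects,
and the EPIC-vs-450K shift — is drawn once per study
(`cpg_architecture()`) and shared by every cohort simulated from the
same panel. This mirrors reality (an EWAS and a target cohort measure
the same biology) and matters: weights estimated against one
architecture are meaningless applied to another. Maternal input to a
CpG is routed mostly (weight 0.89) through realized gestational age,
so gestational age also mediates maternal effects on methylation.
Cell proportions are Dirichlet draws centred on cord-blood composition
(Gran 0.51, nRBC 0.13, ...); plates of 96 samples nested in array
carry random shifts. Meta-EWAS weights for the MPS-BW are per-CpG
regressions of birthweight on beta in an independent cohort of 8000,
restricted — like their published counterparts — to CpGs passing a
significance cutoff (1e-5 here; a floor of 10 CpGs keeps toy
simulations usable).

# Statistical machinery

**Scoring.** Allele harmonization flips dosages (d → 2 − d) when the
weight file's effect allele is the panel's other allele; mismatches in
both orientations are errors, never guessed strand flips. PGS are
z-scored (n − 1 SD) and residualized on the first 10 genetic PCs
(SVD of the column-standardized dosage matrix, component signs fixed by
the largest loading). The wording of PC adjustment in cohort studies is
sometimes inverted; what the residual usage requires, and what is
implemented, is the regression of the z-scored PGS *on* the PCs. The
MPS z-scores within array subcohort (the two arrays differ in mean
level by construction); z-scoring uses the sample SD throughout.

**Models.** Ordinary least squares with intercept and classical SEs;
t-based CIs and p-values on residual df; complete cases per fit with n
reported. Methylation outcomes adjust for plate (dummy-coded) and six
of seven cell proportions — nRBC omitted as the reference to avoid the
sum-to-one collinearity. CpG batteries with a common design are fitted
through one QR decomposition with a matrix response, which is exactly
per-CpG OLS (a test asserts equality to 1e-10). Beta-scale companion
fits are produced for reporting; the M-value scale is the inferential
one.

**Meta-analysis and FDR.** Fixed-effect inverse-variance pooling with
normal-reference p-values (the convention of GWAS/EWAS meta tools);
Benjamini–Hochberg step-up q-values within each (model, term) family
across CpGs; MPS and birthweight are single tests, uncorrected.
Heterogeneity statistics are available (`cochran_q()`) but not
computed by default. Under a global null the chance that BH makes at
least one discovery equals the Simes global-test level (5% with
independent continuous p-values) — the long-run zero-discovery rate is
95%, with binomial noise around it in any finite replicate set.

**Mediation.** The estimator is product-of-coefficients with all
mediators entered simultaneously: a-paths regress each mediator on both
exposures jointly (probit link for binary mediators, approximating a
latent-response treatment, with a linear-probability fallback on
non-convergence); one outcome regression on exposures + mediators + sex
gives the b-paths and c′; the same regression without mediators gives
c. Sex adjusts b and c; a-paths are unadjusted by default (a flag adds
sex, and with linear links and a common covariate set the exact OLS
identity c = c′ + Σ a·b holds, which a test asserts to 1e-8). Intervals
are percentile bootstrap over families (default 1000 replicates,
seeded); pathway p-values use the bootstrap-SE normal approximation and
BH across the enumerated pathway family (13 mediators × 2 effect types
× k outcomes). The proportion mediated divides by the total effect c
and is flagged, not clipped, outside [0, 1]. DNA methylation enters the
reverse-direction models residualized for plate and cell composition.
Whether the motivating analyses sex-adjusted their a-paths is not
documented; the default follows the letter of "b and c paths".

**Mediator imputation.** Missing mediators are imputed by iterative SVD
on the FAMD-standardized mixed encoding (continuous/ordinal columns
standardized; binary columns indicator-coded, scaled by inverse root
frequency); the rank is chosen by 10-fold cross-validation over masked
observed cells (rank 0 = mean imputation is a legal winner — with
mutually independent mediators there is no low-rank structure to
exploit); binary/ordinal cells return to valid levels by
nearest-level rounding. Constant-but-incomplete columns impute to the
constant with a warning.

# Numerical and design choices

* Dosages are hard calls {0, 1, 2} on output; fractional imputed
  dosages (e.g. VCF `DS` fields) are accepted on input.
* kNN methylation imputation: k = 10 rows (CpGs), Euclidean distance
  over shared observed samples rescaled to the full sample count,
  applied per array; per-CpG missingness above 50% is an error.
* One master seed per run is split deterministically into per-stage
  substreams (recorded in the pipeline manifest); same seed ⇒
  byte-identical outputs, verified by digest in the tests.
* Writers print doubles with 17 significant digits so TSV round-trips
  are bit-exact.
* Rank-deficient designs error out naming the collinear columns rather
  than silently dropping terms.
* The command-line surface is R itself: `run_pipeline()` takes a
  declarative YAML or list config; no shell binary is shipped.

# Problem sizes used in the test suite

The packaged checks run at desk scale, chosen for statistical
informativeness per CPU-second: calibration checks at n = 2000–5000
families; CI-coverage of the trio and GWAS-adjusted models over 100
replicates at n = 1500 (coverage pooled over models × effect types
against a 93% floor); gestational-age path recovery and the
proportion-mediated interval over 50 replicates at n = 2116 with one
fixed estimated weight set; FDR control over 100 replicates of a
500-CpG global-null methylome; and the a-priori-vs-a-posteriori
contrast over 20 replicates at n = 800 with 150 CpGs. Mediation
recovery runs on complete mediator data; the imputation scheme is
validated separately against masked-cell ground truth.

# What passing simulations do and do not show

The generator reproduces the *statistical structure* the analysis
assumes: Mendelian transmission, separable effect architectures,
calibrated birthweight moments, a two-array methylome with batch and
cell-composition nuisance. It does not emulate linkage disequilibrium,
genotyping or imputation error, probe-level artefacts, non-random
missingness (MCAR only by default), population stratification (the PC
adjustment is exercised, not challenged), assortative mating, or
selection into the cohort. Green tests therefore certify the
estimators and their wiring — not robustness of the scientific
conclusions to those real-data complications, and causal language
about mediation remains as assumption-laden here as in any
observational design.
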