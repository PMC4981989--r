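# Covariate adjustment, inverse rank-normal transform, linear dose
# association and the family GEE.

test_that("covariate adjustment gives least-squares residuals", {
  set.seed(1)
  covar <- simulate_covariates(500)
  trait <- 2 + 0.01 * covar$age - 2e-4 * covar$age^2 + 0.3 * covar$sex +
    1.5 * covar$height + rnorm(500, 0, 0.3)
  res <- adjust_phenotype(trait, covar)
  expect_equal(attr(res, "n_used"), 500)
  # identical to an lm oracle
  o <- residuals(lm(trait ~ age + I(age^2) + sex + height + I(height^2),
                    data = covar))
  expect_equal(as.numeric(res), unname(o), tolerance = 1e-10)
  # residuals orthogonal to every covariate column
  for (v in list(covar$age, covar$age^2, covar$sex, covar$height,
                 covar$height^2))
    expect_lt(abs(cor(res, v)), 1e-10)
  # trait independent of covariates: residuals ~ trait - mean(trait)
  t2 <- rnorm(500)
  r2 <- adjust_phenotype(t2, covar)
  expect_gt(cor(as.numeric(r2), t2 - mean(t2)), 0.99)
})

test_that("adjustment drops incomplete cases and collinear columns", {
  covar <- simulate_covariates(100, seed = 2)
  trait <- rnorm(100)
  covar$age[3] <- NA; trait[7] <- NA
  res <- adjust_phenotype(trait, covar)
  expect_true(is.na(res[3]) && is.na(res[7]))
  expect_equal(attr(res, "n_used"), 98)
  covar$sex <- 1                                   # single-sex subset
  expect_warning(adjust_phenotype(trait, covar), "collinear")
})

test_that("adjustment uses ancestry PCs when present", {
  set.seed(3)
  covar <- simulate_covariates(400)
  covar$PC1 <- rnorm(400); covar$PC2 <- rnorm(400)
  covar$PC3 <- rnorm(400); covar$PC4 <- rnorm(400)
  trait <- 3 * covar$PC1 + rnorm(400, 0, 0.1)
  res <- adjust_phenotype(trait, covar)
  expect_lt(abs(cor(res, covar$PC1)), 1e-10)
  expect_lt(sd(res), 0.2)                          # PC effect removed
})

test_that("inverse rank-normal transform follows the Blom convention", {
  expect_equal(inverse_normal_transform(c(3, 7)), c(-1, 1) * qnorm(1.625 / 2.25))
  # scipy.stats.norm.ppf oracle for n=5 Blom scores
  expect_equal(inverse_normal_transform(c(10, 20, 30, 40, 50)),
               c(-1.1797611176, -0.4972005707, 0, 0.4972005707, 1.1797611176),
               tolerance = 1e-9)
  set.seed(4)
  z <- inverse_normal_transform(rexp(1000))
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sd(z), 1, tolerance = 0.01)
  # idempotence on tie-free input
  expect_lt(max(abs(inverse_normal_transform(z) - z)), 1e-6)
  # ties share average ranks
  zt <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(zt[1], zt[2])
  expect_error(inverse_normal_transform(rep(1, 5)), "equal")
  expect_error(inverse_normal_transform(2), "at least 2")
})

test_that("linear dose association is exact on noiseless data", {
  dose <- runif(100)
  r <- suppressWarnings(
    linear_dose_association(2 * dose, dose, cnvr_id = "cv", trait = "FEV1"))
  expect_equal(r$beta, 2, tolerance = 1e-10)
  expect_lt(r$p, 1e-100)
  expect_equal(r$direction, "+")
  z <- linear_dose_association(rnorm(100), rep(1, 100))
  expect_equal(z$direction, ".")
  expect_true(is.na(z$beta))
  few <- linear_dose_association(rnorm(10), runif(10))
  expect_true(is.na(few$beta))                     # below min_n
})

test_that("association is invariant to affine relabelling of the dose", {
  set.seed(5)
  dose <- rbinom(300, 2, 0.3)
  y <- 0.2 * dose + rnorm(300, 0, 0.5)
  r0 <- linear_dose_association(y, dose)
  r_shift <- linear_dose_association(y, dose + 5)
  expect_equal(r_shift$beta, r0$beta)
  expect_equal(r_shift$se, r0$se)
  expect_equal(r_shift$p, r0$p)
  r_scale <- linear_dose_association(y, dose * 2)
  expect_equal(r_scale$beta, r0$beta / 2)
  expect_equal(r_scale$p, r0$p)
})

test_that("null P-values are uniform under permutation", {
  set.seed(6)
  dose <- rbinom(200, 2, 0.3)
  y <- rnorm(200)
  p <- replicate(400, linear_dose_association(sample(y), dose)$p)
  mc_se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * mc_se)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("GEE equals OLS on singleton clusters", {
  set.seed(7)
  dose <- rbinom(200, 2, 0.3)
  y <- 0.1 * dose + rnorm(200)
  g <- gee_dose_association(y, dose, family_id = rep(NA, 200))
  o <- lm(y ~ dose)
  expect_equal(g$beta, unname(coef(o)[2]), tolerance = 1e-8)
  # robust SE matches the HC0 cluster sandwich
  if (requireNamespace("sandwich", quietly = TRUE)) {
    v <- sandwich::vcovCL(o, cluster = seq_len(200), type = "HC0",
                          cadjust = FALSE)
    expect_equal(g$se, sqrt(v[2, 2]), tolerance = 1e-6)
  }
})

test_that("GEE recovers a spiked effect in correlated family data", {
  set.seed(8)
  n_fam <- 150; k <- 4; n <- n_fam * k
  fam <- rep(sprintf("F%03d", 1:n_fam), each = k)
  dose <- rep(rbinom(n_fam, 2, 0.3), each = k)     # genotype shared in family
  icc <- 0.5
  y <- 0.2 * dose + rep(rnorm(n_fam, 0, sqrt(icc)), each = k) +
    rnorm(n, 0, sqrt(1 - icc))
  g <- gee_dose_association(y, dose, fam)
  expect_lt(abs(g$beta - 0.2), 2 * g$se)
  expect_equal(g$direction, "+")
  # the exchangeable working correlation is picked up
  fit <- cnvgwas:::gee_gaussian(y, cbind(1, dose), fam)
  expect_gt(fit$alpha, 0.3)
  # robust SE exceeds the naive OLS SE that ignores clustering
  o <- summary(lm(y ~ dose))$coefficients[2, 2]
  expect_gt(g$se, o)
})

test_that("direction is the sign of beta and zero-variance dose yields none", {
  set.seed(9)
  dose <- rbinom(100, 2, 0.4)
  neg <- linear_dose_association(-0.5 * dose + rnorm(100, 0, 0.1), dose)
  expect_equal(neg$direction, "-")
  g0 <- gee_dose_association(rnorm(100), rep(2, 100), rep(NA, 100))
  expect_equal(g0$direction, ".")
})

test_that("associate_cohort stacks per-CNVR per-trait results", {
  set.seed(10)
  n <- 300
  covar <- simulate_covariates(n)
  cls <- simulate_cnv_classes("deletion", 3, 0.3, n)
  pheno <- covar
  pheno$family_id <- NA_character_
  for (tr in c("FEV1", "FVC", "RATIO"))
    pheno[[tr]] <- simulate_phenotypes(
      cls, covar, beta = ifelse(tr == "FVC", 0.3, 0),
      coefs = cnvgwas:::default_trait_coefs(tr), residual_sd = 0.3)$value
  calls <- list(cv1 = data.frame(sample_id = covar$sample_id,
                                 dose = as.numeric(cls)))
  a <- associate_cohort(calls, pheno, cohort = "A")
  expect_equal(nrow(a), 3)
  expect_true(all(a$method == "lm"))
  expect_lt(a$p[a$trait == "FVC"], 1e-6)
  expect_gt(min(a$p[a$trait != "FVC"]), 0.0001)
  # family ids switch the GEE path on
  pheno$family_id <- rep(sprintf("F%03d", 1:50), each = 6)
  ag <- associate_cohort(calls, pheno, cohort = "A")
  expect_true(all(ag$method == "gee"))
})
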