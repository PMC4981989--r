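# Synthetic-data generator: Hardy-Weinberg class structure, intensity model,
# phenotype model, tag-SNP LD calibration, and whole-study determinism.

test_that("class frequencies follow Hardy-Weinberg algebra", {
  f3 <- hwe_class_freqs("deletion", 3, 0.3)
  expect_equal(as.numeric(f3), c(0.09, 0.42, 0.49))    # q^2, 2q(1-q), (1-q)^2
  expect_equal(attr(f3, "copy"), 0:2)

  f2 <- hwe_class_freqs("deletion", 2, 0.1)            # merged non-deleted states
  expect_equal(as.numeric(f2), c(0.01, 0.99))

  fa <- hwe_class_freqs("amplification", 3, 0.2)
  expect_equal(as.numeric(fa), c(0.64, 0.32, 0.04))
  expect_equal(attr(fa, "copy"), 2:4)

  fm <- hwe_class_freqs("multiallelic", 4, 0.25)
  expect_equal(sum(fm), 1)
  expect_length(fm, 4)

  expect_error(hwe_class_freqs("deletion", 5, 0.3), "K must be")
  expect_error(hwe_class_freqs("deletion", 3, 1.2), "in \\(0, 1\\)")
  expect_error(simulate_cnv_classes("deletion", 3, 0, 10), "in \\(0, 1\\)")
})

test_that("empirical class frequencies converge to the theoretical ones", {
  for (spec in list(list("deletion", 3L, 0.3), list("amplification", 3L, 0.2),
                    list("multiallelic", 4L, 0.25))) {
    cls <- simulate_cnv_classes(spec[[1]], spec[[2]], spec[[3]], 10000, seed = 11)
    f <- attr(cls, "freq")
    obs <- tabulate(cls + 1L, nbins = spec[[2]])
    gof <- stats::chisq.test(obs, p = f)
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("intensity model is exact at zero noise and injects missingness as asked", {
  cls <- structure(0:2, copy = 0:2)
  x <- simulate_intensities(cls, probe_count = 3, noise_sd = 0, seed = 1)
  expect_equal(unname(x[, 1]), c(log2(0.125), -1, 0))  # log2(max(c,.25)/2)
  expect_equal(unname(x[, 2]), unname(x[, 1]))
  expect_false(anyNA(x))

  x2 <- simulate_intensities(cls, 50, noise_sd = 0.1, missing_rate = 0.3,
                             seed = 2)
  expect_gt(mean(is.na(x2)), 0.15)
  expect_error(simulate_intensities(cls, 3, class_means = c(0, 0, 1)),
               "strictly increasing")
  expect_error(simulate_intensities(cls, 3, noise_sd = -1), "non-negative")
})

test_that("per-sample mean of p probes has standard error noise_sd/sqrt(p)", {
  cls <- structure(rep(1L, 4000), copy = 0:2)
  x <- simulate_intensities(cls, 10, noise_sd = 0.1, seed = 3)
  expect_equal(stats::sd(rowMeans(x)), 0.1 / sqrt(10), tolerance = 0.05)
})

test_that("phenotypes are exact functions of covariates at zero noise", {
  covar <- simulate_covariates(50, seed = 4)
  ph <- simulate_phenotypes(rep(0, 50), covar, beta = 0, residual_sd = 0)
  co <- default_trait_coefs <- cnvgwas:::default_trait_coefs("FEV1")
  mu <- co[["intercept"]] + co[["age"]] * covar$age +
    co[["age2"]] * covar$age^2 + co[["sex"]] * covar$sex +
    co[["height"]] * covar$height + co[["height2"]] * covar$height^2
  expect_equal(ph$value, mu)
  expect_equal(attr(ph, "true_beta"), 0)
  expect_error(simulate_phenotypes(rep(0, 50), covar, residual_sd = -1),
               "residual_sd")
})

test_that("a spiked dose effect is recovered by downstream association", {
  set.seed(5)
  n <- 5000
  cls <- simulate_cnv_classes("deletion", 3, 0.3, n)
  covar <- simulate_covariates(n)
  ph <- simulate_phenotypes(cls, covar, beta = 0.05, residual_sd = 0.4)
  adj <- adjust_phenotype(ph$value, covar)
  res <- linear_dose_association(adj, as.numeric(cls))
  expect_lt(abs(res$beta - 0.05), 2 * res$se)
})

test_that("family spec induces the requested intraclass correlation", {
  set.seed(6)
  n <- 2000
  covar <- simulate_covariates(n)
  fam <- list(fraction = 1, sizes = 4, icc = 0.5)
  ph <- simulate_phenotypes(rep(0, n), covar, beta = 0, residual_sd = 1,
                            family_spec = fam)
  eps <- ph$value - simulate_phenotypes(rep(0, n), covar, beta = 0,
                                        residual_sd = 0)$value
  d <- data.frame(eps = eps, fam = ph$family_id)
  fit <- stats::aov(eps ~ fam, data = d)
  ms <- summary(fit)[[1]]$`Mean Sq`
  k <- 4
  icc <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  expect_equal(icc, 0.5, tolerance = 0.12)
})

test_that("tag-SNP LD calibration hits its target r-squared", {
  cls <- simulate_cnv_classes("deletion", 3, 0.3, 5000, seed = 7)
  d1 <- simulate_tag_snp(cls, 1)
  expect_equal(stats::cor(d1, cls)^2, 1)
  d0 <- simulate_tag_snp(cls, 0, seed = 8)
  expect_lt(stats::cor(d0, cls)^2, 0.01)
  d94 <- simulate_tag_snp(cls, 0.94, seed = 9)
  r2 <- stats::cor(d94, cls)^2
  expect_gt(r2, 0.89); expect_lt(r2, 0.99)
  mult <- simulate_cnv_classes("multiallelic", 4, 0.25, 100, seed = 10)
  expect_error(simulate_tag_snp(mult, 0.9), "generating allele")
})

test_that("whole-study simulation is deterministic and keeps its bookkeeping", {
  cfg <- sim_config(cohorts = c("A", "B"), sizes = c(60, 40),
                    noise_sd = c(0.1, 0.2), probes_per_cnvr = c(5, 4),
                    dialect = c("LRR", "XY"), child = c(FALSE, TRUE),
                    family_cohort = "A", n_cnvr = 4, seed = 12)
  ds1 <- simulate_multi_cohort_study(cfg)
  ds2 <- simulate_multi_cohort_study(cfg)
  expect_identical(ds1, ds2)
  expect_equal(nrow(ds1$cohorts$A$phenotypes), 60)
  expect_equal(nrow(ds1$cohorts$B$phenotypes), 40)
  expect_equal(nrow(ds1$regions), 4)
  expect_true(all(ds1$regions$start < ds1$regions$end))
  # default config mirrors the emulated study's cohort sizes
  expect_equal(sim_config()$sizes, c(3084, 2492, 1765, 5062))
  expect_error(sim_config(sizes = c(10, 20)), "length")
})

test_that("tripling the noise never resolves more CNVRs", {
  count_resolved <- function(noise, seed) {
    cfg <- sim_config(cohorts = "A", sizes = 400, noise_sd = noise,
                      probes_per_cnvr = 6, dialect = "LRR", child = FALSE,
                      family_cohort = NA, n_cnvr = 6, seed = seed)
    ds <- simulate_multi_cohort_study(cfg)
    co <- ds$cohorts$A
    sum(vapply(seq_len(6), function(j) {
      s <- summarize_cnvr(co$intensities, co$probes, ds$regions[j, ])
      sel <- select_classes(s$values, K_max = 4, seed = 1, n_restarts = 3)
      sel$polymorphic
    }, logical(1)))
  }
  expect_gte(count_resolved(0.10, 13), count_resolved(0.45, 13))
})
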