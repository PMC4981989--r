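# Meta-analysis (IVW, sample-size-weighted Z), thresholds, tag-SNP LD and
# tag-based replication.

test_that("IVW meta-analysis obeys its closed-form identities", {
  one <- ivw_meta(0.5, 0.1)
  expect_equal(one$beta, 0.5)
  expect_equal(one$se, 0.1)

  sym <- ivw_meta(c(1, -1), c(1, 1))
  expect_equal(sym$beta, 0)
  expect_equal(sym$se, 1 / sqrt(2))

  # m identical studies: beta unchanged, SE / sqrt(m)
  m5 <- ivw_meta(rep(0.3, 5), rep(0.12, 5))
  expect_equal(m5$beta, 0.3)
  expect_equal(m5$se, 0.12 / sqrt(5))
  expect_equal(m5$direction, "+++++")

  # independent cross-check against metafor fixed-effect
  if (requireNamespace("metafor", quietly = TRUE)) {
    b <- c(0.0084, 0.0040, 0.0072); se <- rep(0.007, 3)
    mine <- ivw_meta(b, se)
    ref <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(mine$beta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$p, ref$pval, tolerance = 1e-10)
  }
  expect_error(ivw_meta(numeric(0), numeric(0)), "no study")
})

test_that("Z-score meta-analysis uses sqrt-N Stouffer weights", {
  one <- stouffer_meta(0.05, "+", 1000)
  expect_equal(one$p, 0.05, tolerance = 1e-12)

  two <- stouffer_meta(c(0.05, 0.05), c("+", "+"), c(500, 500))
  expect_equal(two$z, qnorm(0.975) * sqrt(2), tolerance = 1e-9)
  expect_equal(two$p, 0.005574596681, tolerance = 1e-9)   # scipy oracle

  # m identical studies: Z scales by sqrt(m)
  z1 <- stouffer_meta(0.01, "+", 100)$z
  z4 <- stouffer_meta(rep(0.01, 4), rep("+", 4), rep(100, 4))$z
  expect_equal(z4, z1 * 2, tolerance = 1e-9)

  opp <- stouffer_meta(c(0.05, 0.05), c("+", "-"), c(500, 500))
  expect_equal(opp$z, 0, tolerance = 1e-12)
  expect_equal(opp$direction, "+-")

  expect_error(stouffer_meta(c(0, 0.5), c("+", "+"), c(10, 10)), "strictly")
  expect_error(stouffer_meta(1, "+", 10), "strictly")
})

test_that("z to P to z round-trips below 1e-8 up to |z| = 8", {
  z <- seq(0.1, 8, by = 0.25)
  p <- 2 * pnorm(-abs(z))
  back <- qnorm(p / 2, lower.tail = FALSE)
  expect_lt(max(abs(back - z)), 1e-8)
  r <- stouffer_meta(p[20], "+", 100)
  expect_equal(r$z, z[20], tolerance = 1e-8)
})

test_that("Bonferroni thresholds and suggestive selection are strict", {
  expect_equal(bonferroni_threshold(0.05, 1962), 0.05 / 1962)
  expect_equal(signif(bonferroni_threshold(0.05, 1962), 2), 2.5e-5)
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(bonferroni_threshold(0.07, 1), 0.07)
  expect_error(bonferroni_threshold(0.05, 0))

  tbl <- data.frame(cnvr_id = sprintf("c%d", 1:100), trait = "FEV1",
                    p = c(0.001, runif(87, 0.0011, 1), runif(12, 1e-6, 9e-4)))
  out <- select_suggestive(tbl, 0.001)
  expect_equal(nrow(out), 12)                    # P = 0.001 exactly excluded
  expect_true(all(out$p < 0.001))
  expect_equal(nrow(select_suggestive(tbl[0, ], 0.001)), 0)
})

test_that("tag_r2 finds the best SNP in the window with allele bookkeeping", {
  set.seed(1)
  cls <- simulate_cnv_classes("deletion", 3, 0.3, 2000)
  dose <- stats::setNames(as.numeric(cls), sprintf("S%04d", 1:2000))
  mk_snps <- function(ds, pos) list(
    info = data.frame(snp_id = sprintf("rs%d", seq_along(pos)),
                      chrom = "chr1", pos = pos,
                      effect_allele = "B", other_allele = "A"),
    dosage = matrix(ds, nrow = length(pos), byrow = TRUE,
                    dimnames = list(sprintf("rs%d", seq_along(pos)),
                                    names(dose))))
  region <- list(chrom = "chr1", start = 1e6, end = 1.1e6, cnvr_id = "cv")

  perfect <- tag_r2(dose, mk_snps(as.numeric(cls), 1.05e6), region)
  expect_equal(perfect$r2, 1)
  expect_true(perfect$tagged)
  expect_equal(perfect$align_sign, 1)

  indep <- tag_r2(dose, mk_snps(rbinom(2000, 2, 0.4), 1.2e6), region)
  expect_lt(indep$r2, 0.01)
  expect_false(indep$tagged)

  # window: SNP 2 Mb away is invisible
  far <- tag_r2(dose, mk_snps(as.numeric(cls), 3.2e6), region)
  expect_true(is.na(far$snp_id))
  expect_false(far$tagged)

  # flipped allele: r2 invariant, alignment sign negative
  flipped <- mk_snps(2 - as.numeric(cls), 1.05e6)
  flipped$info$effect_allele <- "A"; flipped$info$other_allele <- "B"
  fr <- tag_r2(dose, flipped, region)
  expect_equal(fr$r2, 1)
  expect_equal(fr$align_sign, -1)

  # tie-break toward the lowest genomic position
  two <- mk_snps(rep(as.numeric(cls), 2), c(1.08e6, 1.02e6))
  tr <- tag_r2(dose, two, region)
  expect_equal(tr$snp_id, "rs2")
})

test_that("strict r2 threshold: 0.766 tags, 0.7 does not", {
  fake <- function(r2) data.frame(cnvr_id = "cv", snp_id = "rs1", r2 = r2,
                                  tagged = r2 > 0.7)
  expect_true(fake(0.766)$tagged)
  expect_false(fake(0.7)$tagged)
  # end-to-end through tag_r2 with calibrated LD
  cls <- simulate_cnv_classes("deletion", 3, 0.3, 5000, seed = 2)
  snp <- simulate_tag_snp(cls, 0.766, seed = 3)
  r2 <- cor(as.numeric(cls), snp)^2
  expect_gt(r2, 0.7)
})

test_that("replication aligns alleles, meta-analyses by trait and thresholds", {
  suggestive <- data.frame(cnvr_id = c("cv1", "cv2"),
                           trait = c("FVC", "FEV1"))
  tags <- data.frame(cnvr_id = c("cv1", "cv2"), snp_id = c("rs1", "rs2"),
                     r2 = c(0.94, 0.81), align_sign = c(1, 1),
                     effect_allele = "B", other_allele = "A",
                     tagged = c(TRUE, TRUE), n = 1000)
  st <- function(beta, se, n) data.frame(
    snp_id = c("rs1", "rs2"), effect_allele = "B", other_allele = "A",
    beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), n = n)
  studies <- list(s1 = st(c(0.05, 0.01), c(0.01, 0.01), 48201),
                  s2 = st(c(0.04, 0.012), c(0.012, 0.01), 48943))
  rep1 <- replicate_tags(suggestive, tags, studies)
  expect_equal(attr(rep1, "n_tests"), 2L)
  expect_equal(unique(rep1$threshold), 0.025)
  expect_equal(rep1$method[rep1$trait == "FVC"], "Z")
  expect_equal(rep1$method[rep1$trait == "FEV1"], "IVW")
  expect_true(rep1$replicated[rep1$cnvr_id == "cv1"])

  # allele flip in one study leaves the aligned result invariant
  studies_f <- studies
  studies_f$s2$effect_allele <- "A"; studies_f$s2$other_allele <- "B"
  studies_f$s2$beta <- -studies_f$s2$beta
  rep2 <- replicate_tags(suggestive, tags, studies_f)
  expect_equal(rep1$p, rep2$p, tolerance = 1e-12)
  expect_equal(rep1$direction, rep2$direction)

  # a negatively-aligned tag SNP flips the study effects once more
  tags_neg <- tags; tags_neg$align_sign <- c(-1, -1)
  rep3 <- replicate_tags(suggestive, tags_neg, studies)
  expect_equal(rep3$p, rep1$p, tolerance = 1e-12)
  expect_equal(rep3$direction[1], chartr("+-", "-+", rep1$direction[1]))

  # missing study entry: dot in direction, study dropped
  studies_m <- studies
  studies_m$s2 <- studies_m$s2[studies_m$s2$snp_id != "rs1", ]
  rep4 <- replicate_tags(suggestive, tags, studies_m)
  expect_match(rep4$direction[rep4$cnvr_id == "cv1"], "\\.")

  # single study: replication P equals the study P (Z mode)
  rep5 <- replicate_tags(suggestive[1, , drop = FALSE], tags,
                         list(s1 = studies$s1))
  expect_equal(rep5$p, studies$s1$p[1], tolerance = 1e-9)
})

test_that("meta_associations combines cohort tables and sorts by P", {
  assoc <- rbind(
    assoc_row <- data.frame(cnvr_id = "cv1", trait = "FEV1", cohort = "A",
                            beta = 0.2, se = 0.05, p = 6e-5, n = 1000,
                            direction = "+", method = "lm"),
    data.frame(cnvr_id = "cv1", trait = "FEV1", cohort = "B", beta = 0.1,
               se = 0.05, p = 0.045, n = 800, direction = "+", method = "lm"),
    data.frame(cnvr_id = "cv2", trait = "FEV1", cohort = "A", beta = 0,
               se = 0.05, p = 1, n = 1000, direction = "+", method = "lm"))
  m <- meta_associations(assoc)
  expect_equal(nrow(m), 2)
  expect_equal(m$cnvr_id[1], "cv1")                  # sorted by P
  expect_equal(m$direction[1], "++")
  expect_equal(m$n[1], 1800)
  mine <- ivw_meta(c(0.2, 0.1), c(0.05, 0.05))
  expect_equal(m$beta[1], mine$beta)
})
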