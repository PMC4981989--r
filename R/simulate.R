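# Synthetic multi-cohort CNV study generator.
#
# Emulates the statistical structure the calling/association pipeline assumes:
# several cohorts genotyped on distinct "platforms" (different probe densities
# and intensity noise), a shared catalogue of copy-number-variable regions
# (CNVRs) of deletion / amplification / multiallelic type with Hardy-Weinberg
# class frequencies, quantitative lung-function traits driven by
# age/sex/height covariates plus optional spiked CNV effects, family
# structure in one cohort, and tag SNPs in controlled LD with each CNVR.

#' Hardy-Weinberg copy-number class frequencies
#'
#' Theoretical class frequencies for a CNVR of the given type, ordered by
#' ascending copy number (the same ordering the mixture caller uses for its
#' class means).  Biallelic deletions and amplifications follow Hardy-Weinberg
#' genotype frequencies \eqn{(1-q)^2, 2q(1-q), q^2} for a variant allele at
#' frequency `q`; a two-class deletion merges the one- and two-copy states
#' into a single class, and a two-class amplification merges the gained
#' states.  A multiallelic region is composed of two independent biallelic
#' duplication variants truncated to four classes.
#'
#' @param type one of `"deletion"`, `"amplification"`, `"multiallelic"`.
#' @param K number of copy-number classes (2-4; multiallelic requires 4).
#' @param q variant allele frequency, strictly inside (0, 1).
#' @return numeric vector of length `K` summing to 1, with a `"copy"`
#'   attribute giving the representative integer copy number of each class.
#' @export
hwe_class_freqs <- function(type = c("deletion", "amplification", "multiallelic"),
                            K, q) {
  type <- match.arg(type)
  if (q <= 0 || q >= 1) stop("allele frequency q must be in (0, 1)")
  if (!K %in% 2:4) stop("K must be 2, 3 or 4")
  g <- stats::dbinom(0:2, 2, q)              # 0, 1, 2 copies of the variant allele
  if (type == "deletion") {
    # variant allele deletes one copy: genotypes (0,1,2) del alleles -> copies (2,1,0)
    if (K == 3) {
      f <- c(g[3], g[2], g[1]); copy <- 0:2
    } else if (K == 2) {
      # merge the non-zero-copy states (het and hom non-deleted) into one class
      f <- c(g[3], g[2] + g[1]); copy <- c(0L, 2L)
    } else stop("deletion CNVRs support K = 2 or 3")
  } else if (type == "amplification") {
    # variant allele adds one copy: genotypes (0,1,2) dup alleles -> copies (2,3,4)
    if (K == 3) {
      f <- g; copy <- 2:4
    } else if (K == 2) {
      f <- c(g[1], g[2] + g[3]); copy <- c(2L, 3L)
    } else stop("amplification CNVRs support K = 2 or 3")
  } else {
    if (K != 4) stop("multiallelic CNVRs are simulated with K = 4")
    # sum of two independent biallelic duplications, copies 2 + g1 + g2 in 2..6,
    # truncated so copies >= 5 fall in the top class
    conv <- stats::convolve(g, rev(g), type = "open")   # P(g1 + g2 = 0..4)
    f <- c(conv[1:3], sum(conv[4:5])); copy <- 2:5
  }
  f <- f / sum(f)
  attr(f, "copy") <- as.integer(copy)
  f
}

#' Simulate true copy-number classes for one CNVR
#'
#' Draws `n` class labels `0..K-1` (ordered by ascending copy number) from the
#' Hardy-Weinberg class frequencies of [hwe_class_freqs()].  For biallelic
#' types the underlying count of the copy-increasing allele is attached as
#' attribute `"allele1"` so that tag SNPs can be simulated in LD with the
#' region; multiallelic regions have no single generating allele.
#'
#' @inheritParams hwe_class_freqs
#' @param n number of samples.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return integer vector of class labels with attributes `"freq"` (theoretical
#'   class frequencies), `"copy"` (class -> copy-number map) and, for
#'   biallelic types, `"allele1"` (per-sample copy-increasing allele count).
#' @export
simulate_cnv_classes <- function(type, K, q, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- hwe_class_freqs(type, K, q)
  type <- match.arg(type, c("deletion", "amplification", "multiallelic"))
  if (type == "multiallelic") {
    g1 <- stats::rbinom(n, 2, q); g2 <- stats::rbinom(n, 2, q)
    cls <- pmin(g1 + g2, 3L)
    allele1 <- NULL
  } else {
    g <- stats::rbinom(n, 2, q)   # variant-allele count
    if (type == "deletion") {
      copies <- 2L - g
      cls <- if (attr(f, "copy")[1] == 0L && length(f) == 2L)
        as.integer(copies > 0) else copies
      allele1 <- 2L - g           # copy-increasing (non-deleted) allele count
    } else {
      copies <- 2L + g
      cls <- if (length(f) == 2L) as.integer(copies > 2) else copies - 2L
      allele1 <- g                # copy-increasing (duplicated) allele count
    }
  }
  cls <- as.integer(cls)
  attr(cls, "freq") <- as.numeric(f)
  attr(cls, "copy") <- attr(f, "copy")
  if (!is.null(allele1)) attr(cls, "allele1") <- as.integer(allele1)
  cls
}

#' Default class intensity means
#'
#' The expected Log R Ratio for copy number `c` is `log2(c / 2)`; zero copies
#' are floored at 0.25 copies before the log so the mean stays finite.
#'
#' @param copy integer vector of copy numbers.
#' @return numeric vector of LRR class means.
#' @export
lrr_class_means <- function(copy) log2(pmax(copy, 0.25) / 2)

#' Simulate probe intensities for one CNVR
#'
#' Each probe value is the sample's class mean plus independent Gaussian noise;
#' missingness is injected completely at random at `missing_rate`.
#'
#' @param classes integer class labels `0..K-1` (as from
#'   [simulate_cnv_classes()]).
#' @param probe_count number of probes in the region.
#' @param class_means per-class mean LRR, strictly increasing with class
#'   index.  Default: `lrr_class_means()` of the classes' `"copy"` attribute,
#'   or of the class labels themselves when no copy map is attached.
#' @param noise_sd per-probe Gaussian noise SD (LRR units), `>= 0`.
#' @param missing_rate probability an entry is set `NA`.
#' @param seed optional integer seed.
#' @return numeric samples x probes matrix of LRR values.
#' @export
simulate_intensities <- function(classes, probe_count, class_means = NULL,
                                 noise_sd = 0.1, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  K <- max(classes) + 1L
  if (is.null(class_means)) {
    copy <- attr(classes, "copy")
    if (is.null(copy)) copy <- seq_len(K) - 1L
    class_means <- lrr_class_means(copy)
  }
  if (length(class_means) < K) stop("need one class mean per class")
  if (any(diff(class_means) <= 0)) stop("class means must be strictly increasing")
  n <- length(classes)
  mu <- class_means[classes + 1L]
  x <- matrix(mu, n, probe_count) +
    matrix(stats::rnorm(n * probe_count, 0, noise_sd), n, probe_count)
  if (missing_rate > 0)
    x[matrix(stats::runif(n * probe_count) < missing_rate, n, probe_count)] <- NA_real_
  rownames(x) <- sprintf("S%04d", seq_len(n))
  colnames(x) <- sprintf("P%04d", seq_len(probe_count))
  x
}

#' Simulate covariates within realistic adult/child ranges
#'
#' @param n number of samples.
#' @param age_range,height_range uniform sampling ranges (years, metres).
#' @param seed optional integer seed.
#' @return data.frame with `sample_id`, `age` (yrs), `sex` (0/1), `height` (m).
#' @export
simulate_covariates <- function(n, age_range = c(16.5, 97.3),
                                height_range = c(1.39, 1.97), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = stats::runif(n, age_range[1], age_range[2]),
    sex = stats::rbinom(n, 1, 0.5),
    height = stats::runif(n, height_range[1], height_range[2]),
    stringsAsFactors = FALSE
  )
}

# Default covariate coefficients per trait; chosen so simulated means sit in
# the range typical of adult spirometry (FEV1 ~ 3.1 L, FVC ~ 4.0 L,
# FEV1/FVC ~ 0.8 at age 50, height 1.70 m).
default_trait_coefs <- function(trait = c("FEV1", "FVC", "RATIO")) {
  trait <- match.arg(trait)
  switch(trait,
    FEV1  = c(intercept = -7.2, age = 0.02, age2 = -4e-4, sex = 0.25,
              height = 9.0, height2 = -1.5),
    FVC   = c(intercept = -7.0, age = 0.015, age2 = -3e-4, sex = 0.35,
              height = 10.0, height2 = -1.6),
    RATIO = c(intercept = 0.95, age = -0.001, age2 = -5e-6, sex = -0.01,
              height = -0.05, height2 = 0))
}

#' Simulate a quantitative trait with covariate, CNV and family effects
#'
#' trait = intercept + age + age^2 + sex + height + height^2 terms
#' + `beta` x copy class + family random effect + Gaussian noise.  When a
#' family spec is given, a fraction of samples is grouped into families that
#' share a random effect inducing the requested intraclass correlation of the
#' trait residual.
#'
#' @param classes_or_dose numeric vector: true copy class or dose per sample.
#' @param covariates data.frame from [simulate_covariates()].
#' @param beta trait units per copy class.
#' @param coefs named covariate coefficient vector
#'   (`intercept, age, age2, sex, height, height2`).
#' @param residual_sd total residual SD (must be `> 0` unless exactly 0 for
#'   noise-free checks).
#' @param family_spec `NULL`, or `list(fraction=, sizes=, icc=)`: fraction of
#'   samples placed in families, vector of family sizes to sample from, and
#'   intraclass correlation of the residual within families.  Alternatively
#'   `list(ids=, icc=)` with a pre-assigned family-id vector (`NA` =
#'   singleton) so several traits can share one family structure.
#' @param seed optional integer seed.
#' @return data.frame `sample_id, value, family_id` with attribute
#'   `"true_beta"`.
#' @export
simulate_phenotypes <- function(classes_or_dose, covariates, beta = 0,
                                coefs = default_trait_coefs("FEV1"),
                                residual_sd = 0.4, family_spec = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (residual_sd < 0) stop("residual_sd must be positive (or 0 for noise-free checks)")
  n <- nrow(covariates)
  stopifnot(length(classes_or_dose) == n)
  mu <- coefs[["intercept"]] +
    coefs[["age"]] * covariates$age + coefs[["age2"]] * covariates$age^2 +
    coefs[["sex"]] * covariates$sex +
    coefs[["height"]] * covariates$height + coefs[["height2"]] * covariates$height^2 +
    beta * as.numeric(classes_or_dose)
  fam_id <- rep(NA_character_, n)
  eps <- numeric(n)
  if (!is.null(family_spec) && residual_sd > 0) {
    if (is.null(family_spec$ids))
      family_spec$ids <- assign_families(n, family_spec$fraction, family_spec$sizes)
    fam_id <- family_spec$ids
    icc <- family_spec$icc
    in_fam <- !is.na(fam_id)
    fam <- match(fam_id[in_fam], unique(fam_id[in_fam]))
    b <- stats::rnorm(max(fam, 0), 0, residual_sd * sqrt(icc))
    eps[in_fam] <- b[fam] + stats::rnorm(sum(in_fam), 0, residual_sd * sqrt(1 - icc))
    eps[!in_fam] <- stats::rnorm(sum(!in_fam), 0, residual_sd)
  } else if (residual_sd > 0) {
    eps <- stats::rnorm(n, 0, residual_sd)
  }
  out <- data.frame(sample_id = covariates$sample_id, value = mu + eps,
                    family_id = fam_id, stringsAsFactors = FALSE)
  attr(out, "true_beta") <- beta
  out
}

#' Assign samples to families
#'
#' The first `fraction * n` samples are grouped into families with sizes drawn
#' from `sizes`; the remainder are singletons (`NA` family id).
#'
#' @param n number of samples.
#' @param fraction fraction of samples placed in families.
#' @param sizes family sizes sampled from (with replacement).
#' @return character vector of family ids, `NA` for singletons.
#' @export
assign_families <- function(n, fraction = 0.6, sizes = 2:5) {
  fam_id <- rep(NA_character_, n)
  n_fam <- round(fraction * n)
  if (n_fam >= 2) {
    sz <- c()
    while (sum(sz) < n_fam)
      sz <- c(sz, sizes[sample.int(length(sizes), 1)])
    fam_id[seq_len(n_fam)] <- sprintf("F%04d", rep(seq_along(sz), sz)[seq_len(n_fam)])
  }
  fam_id
}

#' Simulate a tag SNP in controlled LD with a biallelic CNVR
#'
#' The SNP dosage starts as an exact copy of the CNVR's copy-increasing
#' allele count; each sample's genotype is then independently replaced by a
#' fresh Hardy-Weinberg draw with probability `1 - sqrt(target_r2)`, which
#' makes the expected correlation with the allele count exactly
#' `sqrt(target_r2)` and hence the expected r-squared equal to the target.
#'
#' @param classes classes from [simulate_cnv_classes()] (biallelic: the
#'   `"allele1"` attribute must be present), or any integer vector if
#'   `allele` is supplied explicitly.
#' @param target_r2 target squared correlation in `[0, 1]`.
#' @param seed optional integer seed.
#' @param allele per-sample copy-increasing allele count (0/1/2); defaults to
#'   `attr(classes, "allele1")`.
#' @return numeric dosage vector in `[0, 2]` with attribute `"effect_allele"`
#'   = `"B"` (the allele positively correlated with increased copy number)
#'   and `"other_allele"` = `"A"`.
#' @export
simulate_tag_snp <- function(classes, target_r2, seed = NULL,
                             allele = attr(classes, "allele1")) {
  if (!is.null(seed)) set.seed(seed)
  if (target_r2 < 0 || target_r2 > 1) stop("target_r2 must be in [0, 1]")
  if (is.null(allele))
    stop("multiallelic classes have no generating allele; supply `allele`")
  n <- length(allele)
  q <- mean(allele) / 2
  p_flip <- 1 - sqrt(target_r2)
  dosage <- as.numeric(allele)
  flip <- stats::runif(n) < p_flip
  dosage[flip] <- stats::rbinom(sum(flip), 2, q)
  attr(dosage, "effect_allele") <- "B"
  attr(dosage, "other_allele") <- "A"
  dosage
}

#' Configuration for a synthetic multi-cohort CNV study
#'
#' Defaults emulate a four-cohort study: three adult cohorts (the first with
#' family structure and the least intensity noise, serving as the reference /
#' best-performing cohort) and one child cohort on a sparser platform using
#' the summed X+Y intensity dialect.  Cohort sizes default to the
#' per-cohort phenotyped sample counts of the emulated study design
#' (3084, 2492, 1765, 5062).
#'
#' @param cohorts cohort ids.
#' @param sizes per-cohort sample counts.
#' @param noise_sd per-cohort per-probe LRR noise SD.
#' @param probes_per_cnvr per-cohort probe density inside each CNVR.
#' @param dialect per-cohort intensity dialect, `"LRR"` or `"XY"`.
#' @param child logical per cohort: child cohort (different age/height ranges).
#' @param family_cohort id of the single cohort with family structure, or
#'   `NA` for none.
#' @param family_spec see [simulate_phenotypes()].
#' @param cnvr_specs data.frame with columns `type, K, q` (one row per CNVR);
#'   default: a mix of deletions, amplifications and multiallelic regions.
#' @param n_cnvr number of CNVRs when `cnvr_specs` is `NULL`.
#' @param spike `NULL` or `list(cnvr=, trait=, beta=)`: spiked per-class trait
#'   effect at one CNVR.
#' @param residual_sd named residual SDs per trait.
#' @param tag_r2 target tag-SNP r-squared for biallelic CNVRs.
#' @param missing_rate probe missingness rate.
#' @param seed integer seed driving the whole study.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(cohorts = c("cohortA", "cohortB", "cohortC", "cohortD"),
                       sizes = c(3084, 2492, 1765, 5062),
                       noise_sd = c(0.10, 0.14, 0.12, 0.20),
                       probes_per_cnvr = c(20, 12, 16, 8),
                       dialect = c("LRR", "LRR", "LRR", "XY"),
                       child = c(FALSE, FALSE, FALSE, TRUE),
                       family_cohort = cohorts[1],
                       family_spec = list(fraction = 0.6, sizes = 2:5, icc = 0.5),
                       cnvr_specs = NULL, n_cnvr = 20,
                       spike = NULL,
                       residual_sd = c(FEV1 = 0.4, FVC = 0.5, RATIO = 0.06),
                       tag_r2 = 0.9, missing_rate = 0.002, seed = 1) {
  n_coh <- length(cohorts)
  if (length(sizes) != n_coh || length(noise_sd) != n_coh ||
      length(probes_per_cnvr) != n_coh || length(dialect) != n_coh ||
      length(child) != n_coh)
    stop("per-cohort spec vectors must all have length ", n_coh)
  if (any(sizes < 1) || any(noise_sd <= 0)) stop("invalid sizes or noise SDs")
  if (is.null(cnvr_specs)) {
    type <- rep(c("deletion", "deletion", "amplification", "multiallelic"),
                length.out = n_cnvr)
    K <- ifelse(type == "multiallelic", 4L, ifelse(seq_len(n_cnvr) %% 4 == 1, 3L, 3L))
    K[type == "deletion" & seq_len(n_cnvr) %% 8 == 2] <- 2L
    q <- rep(c(0.3, 0.1, 0.2, 0.25), length.out = n_cnvr)
    cnvr_specs <- data.frame(type = type, K = K, q = q, stringsAsFactors = FALSE)
  }
  cnvr_specs$cnvr_id <- sprintf("CNVR%03d.1", seq_len(nrow(cnvr_specs)))
  structure(list(
    cohorts = cohorts, sizes = sizes, noise_sd = noise_sd,
    probes_per_cnvr = probes_per_cnvr, dialect = dialect, child = child,
    family_cohort = family_cohort, family_spec = family_spec,
    cnvr_specs = cnvr_specs, spike = spike, residual_sd = residual_sd,
    tag_r2 = tag_r2, missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a full multi-cohort CNV association study
#'
#' Generates, for each cohort: an intensity matrix over all CNVR probes plus
#' background probes, true copy classes per CNVR, phenotypes for FEV1 (L),
#' FVC (L) and FEV1/FVC with age/sex/height effects and any spiked CNV
#' effect, and (reference cohort only) tag-SNP dosages per biallelic CNVR.
#' Identical configs (including the seed) give identical datasets.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_dataset`: list with `regions` (CNVR
#'   catalogue), `probes` (manifest), per-cohort `cohorts[[id]]` holding
#'   `intensities`, `truth` (sample x CNVR true class matrix), `phenotypes`,
#'   and for the reference cohort `snps` (dosage table) — plus the `config`.
#' @export
simulate_multi_cohort_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  specs <- config$cnvr_specs
  n_cnvr <- nrow(specs)
  # CNVR catalogue: spread over autosomes, non-overlapping per chromosome
  chrom <- rep_len(paste0("chr", 1:22), n_cnvr)
  start <- 1e6 + (seq_len(n_cnvr) %/% 22) * 5e6 +
    round(stats::runif(n_cnvr, 0, 1e6))
  width <- round(stats::runif(n_cnvr, 5e3, 5e4))
  regions <- data.frame(chrom = chrom, start = start, end = start + width,
                        cnvr_id = specs$cnvr_id, type = specs$type,
                        stringsAsFactors = FALSE)
  cohorts <- list()
  n_background <- 150   # probes outside any CNVR, shared across cohorts
  for (ci in seq_along(config$cohorts)) {
    id <- config$cohorts[ci]
    n <- config$sizes[ci]
    np <- config$probes_per_cnvr[ci]
    sample_ids <- sprintf("%s_S%05d", id, seq_len(n))
    # probe manifest for this cohort: np probes inside each CNVR + background
    probe_rows <- do.call(rbind, lapply(seq_len(n_cnvr), function(j) {
      pos <- sort(round(seq(regions$start[j], regions$end[j] - 1, length.out = np)))
      data.frame(probe_id = sprintf("%s_%s_p%02d", id, specs$cnvr_id[j], seq_len(np)),
                 chrom = regions$chrom[j], pos = pos, stringsAsFactors = FALSE)
    }))
    bg <- data.frame(probe_id = sprintf("%s_bg_p%03d", id, seq_len(n_background)),
                     chrom = rep_len(paste0("chr", 1:22), n_background),
                     pos = 5e5 + seq_len(n_background) * 101,
                     stringsAsFactors = FALSE)
    probes <- rbind(probe_rows, bg)
    truth <- matrix(NA_integer_, n, n_cnvr,
                    dimnames = list(sample_ids, specs$cnvr_id))
    allele1 <- matrix(NA_integer_, n, n_cnvr,
                      dimnames = list(sample_ids, specs$cnvr_id))
    X <- matrix(NA_real_, n, nrow(probes),
                dimnames = list(sample_ids, probes$probe_id))
    for (j in seq_len(n_cnvr)) {
      cls <- simulate_cnv_classes(specs$type[j], specs$K[j], specs$q[j], n)
      truth[, j] <- cls
      if (!is.null(attr(cls, "allele1"))) allele1[, j] <- attr(cls, "allele1")
      xx <- simulate_intensities(cls, np, noise_sd = config$noise_sd[ci],
                                 missing_rate = config$missing_rate)
      X[, (j - 1) * np + seq_len(np)] <- xx
    }
    X[, n_cnvr * np + seq_len(n_background)] <-
      stats::rnorm(n * n_background, 0, config$noise_sd[ci])
    if (config$dialect[ci] == "XY") {
      # affine dialect: scale + offset on the LRR scale; readers median-centre
      X <- 1500 * 2^X + 200
    }
    covar <- simulate_covariates(
      n,
      age_range = if (config$child[ci]) c(7.4, 10.3) else c(16.5, 97.3),
      height_range = if (config$child[ci]) c(1.13, 1.59) else c(1.39, 1.97))
    covar$sample_id <- sample_ids
    fam <- NULL
    if (identical(id, config$family_cohort)) {
      fam <- config$family_spec
      fam$ids <- assign_families(n, fam$fraction, fam$sizes)
    }
    pheno <- covar
    pheno$family_id <- if (is.null(fam)) NA_character_ else fam$ids
    for (tr in c("FEV1", "FVC", "RATIO")) {
      beta <- 0
      if (!is.null(config$spike) && config$spike$trait == tr)
        beta <- config$spike$beta
      dose <- if (!is.null(config$spike))
        truth[, config$spike$cnvr] else rep(0, n)
      ph <- simulate_phenotypes(dose, covar, beta = beta,
                                coefs = default_trait_coefs(tr),
                                residual_sd = config$residual_sd[[tr]],
                                family_spec = fam)
      pheno[[tr]] <- ph$value
    }
    cohort <- list(id = id, dialect = config$dialect[ci],
                   intensities = X, probes = probes, truth = truth,
                   phenotypes = pheno)
    if (ci == 1) {
      # tag SNPs measured in the reference cohort only (LD panel)
      snp_rows <- list()
      dosages <- list()
      for (j in seq_len(n_cnvr)) {
        if (all(is.na(allele1[, j]))) next    # multiallelic: no tag
        d <- simulate_tag_snp(NULL, config$tag_r2, allele = allele1[, j])
        snp_id <- sprintf("rs%05d", j * 7 + 10000)
        snp_rows[[length(snp_rows) + 1]] <- data.frame(
          snp_id = snp_id, chrom = regions$chrom[j],
          pos = regions$end[j] + 1000L, effect_allele = "B", other_allele = "A",
          cnvr_id = specs$cnvr_id[j], stringsAsFactors = FALSE)
        dosages[[snp_id]] <- d
      }
      cohort$snps <- list(info = do.call(rbind, snp_rows),
                          dosage = do.call(rbind, dosages))
      if (!is.null(cohort$snps$dosage))
        colnames(cohort$snps$dosage) <- sample_ids
    }
    cohorts[[id]] <- cohort
  }
  structure(list(regions = regions, cohorts = cohorts, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic multi-cohort CNV study\n")
  cat("  CNVRs:", nrow(x$regions), "\n")
  for (co in x$cohorts)
    cat(sprintf("  %s: %d samples, %d probes (%s)\n", co$id,
                nrow(co$intensities), ncol(co$intensities), co$dialect))
  invisible(x)
}
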