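# Sample-level quality control before copy-number calling: replicate removal,
# intensity-noise filtering, and ancestry principal-component outlier
# exclusion.

#' Per-sample intensity noise metric
#'
#' The standard deviation (population convention, divisor n) of a sample's
#' autosomal LRR values, ignoring missing probes.  High values indicate noisy
#' intensity data that degrades mixture clustering.
#'
#' @param lrr numeric vector of a sample's autosomal probe LRR values.
#' @param sample_id id used in error messages.
#' @param min_probes minimum non-missing probes required (default 100).
#' @return non-negative scalar noise metric.
#' @export
intensity_noise_metric <- function(lrr, sample_id = "sample", min_probes = 100) {
  x <- lrr[!is.na(lrr)]
  if (length(x) < min_probes)
    stop(sprintf("%s: only %d non-missing probes (need >= %d) for noise metric",
                 sample_id, length(x), min_probes))
  sqrt(mean((x - mean(x))^2))
}

#' Intensity-noise filter
#'
#' Retains samples whose noise metric does not exceed the threshold.
#'
#' @param metrics named numeric vector of per-sample noise metrics.
#' @param threshold retain iff `metric <= threshold` (LRR units).
#' @return character vector of retained sample ids.
#' @export
noise_filter <- function(metrics, threshold = 0.30) {
  if (threshold <= 0) stop("noise threshold must be positive")
  names(metrics)[metrics <= threshold]
}

#' Ancestry-informative principal component scores
#'
#' PCA of a SNP dosage matrix with the usual GWAS normalization: each SNP is
#' centred at its mean dosage and scaled by `sqrt(2 p (1-p))` with `p` the
#' empirical allele frequency; monomorphic SNPs are dropped.
#'
#' @param dosage numeric samples x SNPs matrix, values in `[0, 2]`.
#' @param n_components number of leading components to return.
#' @return samples x `n_components` score matrix (columns `PC1..`), zero-mean.
#' @export
pca_ancestry_scores <- function(dosage, n_components = 4) {
  stopifnot(is.matrix(dosage))
  if (any(dosage < -1e-6 | dosage > 2 + 1e-6, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (ncol(dosage) < n_components)
    stop(sprintf("only %d SNPs for %d components", ncol(dosage), n_components))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  scores <- matrix(0, nrow(dosage), n_components,
                   dimnames = list(rownames(dosage),
                                   paste0("PC", seq_len(n_components))))
  if (sum(keep) == 0) return(scores)      # all samples identical: zero scores
  X <- dosage[, keep, drop = FALSE]
  X <- sweep(X, 2, 2 * p[keep])
  X <- sweep(X, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  X[is.na(X)] <- 0
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  scores[, seq_len(k)] <- pr$x[, seq_len(k)]
  scores
}

#' Principal-component ancestry outlier filter
#'
#' Removes samples whose score on any of the first `n_components` axes lies
#' strictly more than `sd_threshold` standard deviations from that axis'
#' mean.  The boundary (exactly at the threshold) is retained.  Mean and SD
#' are computed once over all samples (single pass); `iterative = TRUE`
#' recomputes them after each round of removals until no sample is flagged.
#'
#' @param scores samples x PCs score matrix (rownames = sample ids).
#' @param sd_threshold SD multiple defining an outlier (default 6).
#' @param n_components leading components tested (default 4).
#' @param iterative recompute mean/SD after each removal round.
#' @return character vector of retained sample ids.
#' @export
pc_outlier_filter <- function(scores, sd_threshold = 6, n_components = 4,
                              iterative = FALSE) {
  k <- min(n_components, ncol(scores))
  S <- scores[, seq_len(k), drop = FALSE]
  keep <- rep(TRUE, nrow(S))
  repeat {
    mu <- colMeans(S[keep, , drop = FALSE])
    sdv <- apply(S[keep, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- Inf                      # constant axis: nothing is an outlier
    z <- abs(sweep(sweep(S, 2, mu), 2, sdv, "/"))
    out <- keep & apply(z > sd_threshold, 1, any)
    if (!iterative || !any(out)) {
      keep <- keep & !apply(z > sd_threshold, 1, any)
      break
    }
    keep <- keep & !out
  }
  rownames(S)[keep]
}

#' Sample quality-control report
#'
#' Runs the full sample QC: declared-replicate removal (first occurrence of a
#' duplicated sample id is kept), intensity-noise filtering, and PC ancestry
#' outlier exclusion.  A sample is retained iff no flag is set.
#'
#' @param intensities samples x probes LRR matrix (rownames = sample ids).
#' @param dosage optional samples x SNPs dosage matrix for ancestry PCA;
#'   `NULL` skips the PC filter.
#' @param noise_threshold see [noise_filter()].
#' @param pc_sd see [pc_outlier_filter()].
#' @param n_components PCs used for the outlier filter.
#' @return data.frame of class `sample_qc_report`: one row per input sample
#'   with `sample_id, noise, PC1..PC4, flag_replicate, flag_noise,
#'   flag_pc_outlier, retained`.
#' @export
sample_qc <- function(intensities, dosage = NULL, noise_threshold = 0.30,
                      pc_sd = 6, n_components = 4) {
  ids <- rownames(intensities)
  if (is.null(ids)) stop("intensity matrix must have sample-id rownames")
  flag_rep <- duplicated(ids)
  noise <- vapply(seq_len(nrow(intensities)), function(i)
    intensity_noise_metric(intensities[i, ], ids[i]), numeric(1))
  flag_noise <- noise > noise_threshold
  rep <- data.frame(sample_id = ids, noise = noise, stringsAsFactors = FALSE)
  flag_pc <- rep(FALSE, length(ids))
  if (!is.null(dosage) && ncol(dosage) >= 1) {
    n_components <- min(n_components, ncol(dosage))
    scores <- pca_ancestry_scores(dosage[ids, , drop = FALSE], n_components)
    kept <- pc_outlier_filter(scores, pc_sd, n_components)
    flag_pc <- !(ids %in% kept)
    rep <- cbind(rep, as.data.frame(scores))
  }
  rep$flag_replicate <- flag_rep
  rep$flag_noise <- flag_noise
  rep$flag_pc_outlier <- flag_pc
  rep$retained <- !(flag_rep | flag_noise | flag_pc)
  class(rep) <- c("sample_qc_report", "data.frame")
  rep
}
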