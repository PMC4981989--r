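# Combining evidence across cohorts: fixed-effect inverse-variance-weighted
# meta-analysis, sample-size-weighted Z-score (Stouffer) meta-analysis,
# Bonferroni thresholds, suggestive-signal selection, tag-SNP LD, and
# replication of CNVR signals through tag-SNP summary statistics.

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' `beta = sum(b_i / SE_i^2) / sum(1 / SE_i^2)`,
#' `SE = (sum SE_i^-2)^(-1/2)`, two-sided `P = 2 Phi(-|beta/SE|)`.
#' Studies with missing or non-positive SE are rejected (a dot in the
#' direction string).
#'
#' @param beta study effect estimates.
#' @param se study standard errors.
#' @return list of class `meta_result`: `method="IVW", beta, se, z, p,
#'   direction, n_studies`.
#' @export
ivw_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  ok <- !is.na(beta) & !is.na(se) & se > 0
  if (!any(ok)) stop("no study with finite positive SE")
  if (any(!is.na(se) & se == 0)) message("study with zero SE rejected")
  w <- 1 / se[ok]^2
  b <- sum(w * beta[ok]) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  structure(list(method = "IVW", beta = b, se = s, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 direction = direction_string(sign(beta), ok),
                 n_studies = sum(ok)),
            class = "meta_result")
}

#' Sample-size-weighted Z-score (Stouffer) meta-analysis
#'
#' Signed study z-scores `z_i = sign_i * qnorm(1 - P_i/2)` are combined with
#' weights `w_i = sqrt(N_i)`: `Z = sum(w_i z_i) / sqrt(sum w_i^2)`,
#' two-sided `P = 2 Phi(-|Z|)`.  Used when study effect scales differ (e.g.
#' one study analysed the untransformed trait).
#'
#' @param p two-sided study P-values, strictly inside (0, 1).
#' @param sign study effect signs (+1 / -1, or "+" / "-").
#' @param n study sample sizes.
#' @return list of class `meta_result`: `method="Z", z, p, direction,
#'   n_studies` (no combined beta).
#' @export
stouffer_meta <- function(p, sign, n) {
  if (is.character(sign)) sign <- ifelse(sign == "+", 1, -1)
  stopifnot(length(p) == length(sign), length(p) == length(n))
  ok <- !is.na(p) & !is.na(sign) & !is.na(n)
  if (any(p[ok] <= 0 | p[ok] >= 1))
    stop("study P-values must be strictly inside (0, 1)")
  if (!any(ok)) stop("no usable study")
  # upper-tail inversion keeps precision for very small P
  z_i <- sign[ok] * stats::qnorm(p[ok] / 2, lower.tail = FALSE)
  w <- sqrt(n[ok])
  z <- sum(w * z_i) / sqrt(sum(w^2))
  structure(list(method = "Z", beta = NA_real_, se = NA_real_, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 direction = direction_string(sign, ok),
                 n_studies = sum(ok)),
            class = "meta_result")
}

direction_string <- function(sign, ok) {
  ch <- ifelse(!ok | is.na(sign), ".", ifelse(sign >= 0, "+", "-"))
  paste(ch, collapse = "")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s meta-analysis of %d studies: ", x$method, x$n_studies))
  if (x$method == "IVW")
    cat(sprintf("beta=%.4g (SE %.4g), ", x$beta, x$se))
  cat(sprintf("Z=%.3f, P=%.3g, direction=%s\n", x$z, x$p, x$direction))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of independent tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Select suggestive signals
#'
#' Rows of an association/meta table with `P` strictly below the threshold.
#'
#' @param results data.frame with a P-value column.
#' @param p_threshold suggestive threshold (default 0.001).
#' @param p_col P-value column name (default `"p"`).
#' @return filtered data.frame.
#' @export
select_suggestive <- function(results, p_threshold = 0.001, p_col = "p") {
  stopifnot(p_col %in% names(results))
  results[!is.na(results[[p_col]]) & results[[p_col]] < p_threshold, ,
          drop = FALSE]
}

#' Best tag SNP for a CNVR
#'
#' Squared Pearson correlation between the CNVR's copy class/dose and the
#' dosage of every SNP within `window` bp of the region's start and end
#' positions; the best SNP (ties broken toward the lowest genomic position)
#' is reported with its allele-alignment sign.  A CNVR is "tagged" iff
#' `r2 > r2_threshold` (strict).
#'
#' @param dose named numeric vector of copy classes or doses (names = sample
#'   ids).
#' @param snps list with `info` (data.frame `snp_id, chrom, pos,
#'   effect_allele, other_allele`) and `dosage` (SNPs x samples matrix).
#' @param region list/row with `chrom, start, end, cnvr_id`.
#' @param window flanking window in bp (default 1e6).
#' @param r2_threshold tagging threshold (default 0.7).
#' @return one-row data.frame of class `tag_snp_result`: `cnvr_id, snp_id,
#'   r2, align_sign, effect_allele, other_allele, tagged, n` — or a
#'   "no tag available" row (`snp_id` NA) when no SNP is in the window.
#' @export
tag_r2 <- function(dose, snps, region, window = 1e6, r2_threshold = 0.7) {
  no_tag <- data.frame(cnvr_id = region$cnvr_id, snp_id = NA_character_,
                       r2 = NA_real_, align_sign = NA_real_,
                       effect_allele = NA_character_,
                       other_allele = NA_character_,
                       tagged = FALSE, n = 0L, stringsAsFactors = FALSE)
  class(no_tag) <- c("tag_snp_result", "data.frame")
  if (is.null(snps) || is.null(snps$info) || nrow(snps$info) == 0) return(no_tag)
  info <- snps$info
  in_win <- info$chrom == region$chrom &
    info$pos >= region$start - window & info$pos <= region$end + window
  if (!any(in_win)) return(no_tag)
  info <- info[in_win, , drop = FALSE]
  samp <- intersect(names(dose), colnames(snps$dosage))
  if (length(samp) < 3) return(no_tag)
  r2 <- vapply(info$snp_id, function(s) {
    d <- snps$dosage[s, samp]
    if (stats::var(d) == 0 || stats::var(dose[samp]) == 0) return(NA_real_)
    stats::cor(dose[samp], d)^2
  }, numeric(1))
  if (all(is.na(r2))) return(no_tag)
  best_r2 <- max(r2, na.rm = TRUE)
  cand <- which(!is.na(r2) & r2 == best_r2)
  best <- cand[which.min(info$pos[cand])]   # tie-break: lowest position
  sgn <- sign(stats::cor(dose[samp], snps$dosage[info$snp_id[best], samp]))
  out <- data.frame(cnvr_id = region$cnvr_id, snp_id = info$snp_id[best],
                    r2 = best_r2, align_sign = sgn,
                    effect_allele = info$effect_allele[best],
                    other_allele = info$other_allele[best],
                    tagged = best_r2 > r2_threshold,
                    n = length(samp), stringsAsFactors = FALSE)
  class(out) <- c("tag_snp_result", "data.frame")
  out
}

#' Replicate suggestive CNVR signals through tag-SNP summary statistics
#'
#' For each suggestive, tagged CNVR-trait pair: looks the tag SNP up in each
#' external study's summary statistics, aligns effects to the
#' copy-number-increasing allele (flipping `beta` when the study's effect
#' allele is the other allele, and again when the tag SNP itself is
#' negatively correlated with copy number), meta-analyses by the trait's
#' method (IVW for FEV1 and FEV1/FVC, sample-size-weighted Z for FVC), and
#' compares the meta P to the Bonferroni threshold for the number of tagged
#' tests.  A missing study contributes a dot to the direction string.
#'
#' @param suggestive data.frame with `cnvr_id, trait` (and optionally the
#'   discovery direction) — typically from [select_suggestive()].
#' @param tags data.frame of [tag_r2()] rows for the same CNVRs.
#' @param studies named list of per-study summary-stat data.frames with
#'   columns `snp_id, effect_allele, other_allele, beta, se, p, n`.
#' @param alpha family-wise error rate for the replication threshold.
#' @param method_map named character: trait -> `"IVW"` or `"Z"`.
#' @return data.frame: one row per tagged suggestive pair with
#'   `cnvr_id, trait, snp_id, r2, method, beta, se, z, p, direction,
#'   threshold, replicated`; attribute `"n_tests"` holds the Bonferroni m.
#' @export
replicate_tags <- function(suggestive, tags, studies, alpha = 0.05,
                           method_map = c(FEV1 = "IVW", FVC = "Z",
                                          RATIO = "IVW")) {
  merged <- merge(suggestive, tags, by = "cnvr_id")
  merged <- merged[merged$tagged %in% TRUE, , drop = FALSE]
  m <- nrow(merged)
  if (m == 0) {
    out <- data.frame()
    attr(out, "n_tests") <- 0L
    return(out)
  }
  thr <- bonferroni_threshold(alpha, m)
  rows <- list()
  for (i in seq_len(m)) {
    snp <- merged$snp_id[i]
    trait <- merged$trait[i]
    eff <- merged$effect_allele[i]       # allele + correlated with copy number
    flip_tag <- if (!is.na(merged$align_sign[i]) && merged$align_sign[i] < 0)
      -1 else 1
    b <- se <- p <- n <- sg <- rep(NA_real_, length(studies))
    for (j in seq_along(studies)) {
      st <- studies[[j]]
      hit <- st[st$snp_id == snp, , drop = FALSE]
      if (nrow(hit) == 0) next
      flip <- if (hit$effect_allele[1] == eff) 1
              else if (hit$other_allele[1] == eff) -1
              else next                  # allele mismatch: drop study
      b[j] <- flip * flip_tag * hit$beta[1]
      se[j] <- hit$se[1]
      p[j] <- hit$p[1]
      n[j] <- hit$n[1]
      sg[j] <- sign(b[j])
    }
    method <- method_map[[trait]] %||% "IVW"
    meta <- if (method == "Z") stouffer_meta(p, sg, n) else ivw_meta(b, se)
    rows[[i]] <- data.frame(
      cnvr_id = merged$cnvr_id[i], trait = trait, snp_id = snp,
      r2 = merged$r2[i], method = meta$method, beta = meta$beta,
      se = meta$se, z = meta$z, p = meta$p, direction = meta$direction,
      threshold = thr, replicated = meta$p < thr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- m
  out
}

#' Meta-analyse a cohort-level association table
#'
#' Fixed-effect IVW (default, shared trait units) or Z-score combination of
#' per-cohort results for every CNVR-trait pair.
#'
#' @param assoc data.frame of stacked `association_result` rows (several
#'   cohorts).
#' @param method `"IVW"` or `"Z"`.
#' @return data.frame: `cnvr_id, trait, n_studies, n, beta, se, z, p,
#'   direction`.
#' @export
meta_associations <- function(assoc, method = c("IVW", "Z")) {
  method <- match.arg(method)
  key <- interaction(assoc$cnvr_id, assoc$trait, drop = TRUE)
  rows <- lapply(split(assoc, key), function(d) {
    d <- d[order(d$cohort), , drop = FALSE]
    res <- tryCatch(
      if (method == "IVW") ivw_meta(d$beta, d$se)
      else stouffer_meta(d$p, sign(d$beta), d$n),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(cnvr_id = d$cnvr_id[1], trait = d$trait[1],
               n_studies = res$n_studies, n = sum(d$n[!is.na(d$beta)]),
               beta = res$beta, se = res$se, z = res$z, p = res$p,
               direction = res$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}
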