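# End-to-end orchestration: QC -> per-CNVR summarization -> free-K calling in
# the reference cohort and fixed-K re-clustering elsewhere -> class-frequency
# harmonization -> per-cohort dose association -> IVW meta-analysis ->
# suggestive-signal selection -> tag-SNP LD -> (optional) replication against
# external summary statistics.  Every stage logs its sample/CNVR accounting.

#' Run the full multi-cohort CNV association pipeline
#'
#' Accepts either a `sim_dataset` from [simulate_multi_cohort_study()] or an
#' equivalent list: `regions` (CNVR catalogue) plus `cohorts`, a named list
#' in which each cohort has `intensities` (samples x probes), `probes`
#' (manifest), `phenotypes` (may be `NULL` for calling-only cohorts) and
#' optionally `snps` (dosage panel, reference cohort).  When `out_dir` is
#' given every stage writes its TSV there.
#'
#' @param study study bundle as above.
#' @param reference reference (best-performing) cohort id; default the first.
#' @param traits trait columns to test.
#' @param studies optional named list of external summary-stat data.frames
#'   (see [replicate_tags()]).
#' @param noise_threshold,pc_sd sample QC thresholds.
#' @param alpha class-frequency compatibility level.
#' @param suggestive_p suggestive-signal threshold.
#' @param tag_r2_threshold tagging r-squared threshold.
#' @param bonferroni_alpha family-wise error rate for replication.
#' @param seed integer seed for clustering restarts.
#' @param out_dir optional output directory for stage TSVs.
#' @param K_max largest class count considered in free selection.
#' @param n_restarts EM restarts per mixture fit.
#' @return object of class `cnv_pipeline_result`: list with `qc`, `harmony`,
#'   `calls`, `assoc`, `meta`, `suggestive`, `tags`, `replication`, `log`.
#' @export
run_pipeline <- function(study, reference = names(study$cohorts)[1],
                         traits = c("FEV1", "FVC", "RATIO"),
                         studies = NULL, noise_threshold = 0.30, pc_sd = 6,
                         alpha = 0.05, suggestive_p = 0.001,
                         tag_r2_threshold = 0.7, bonferroni_alpha = 0.05,
                         seed = 1, out_dir = NULL, K_max = 6,
                         n_restarts = 10) {
  stopifnot(reference %in% names(study$cohorts))
  log <- list()
  note <- function(...) {
    msg <- sprintf(...)
    log[[length(log) + 1]] <<- msg
    message(msg)
  }
  regions <- study$regions

  ## stage 1: sample QC per cohort.  The noise metric is computed over
  ## probes outside any catalogued CNVR so that genuine copy-number signal
  ## is not mistaken for intensity noise.
  qc <- list()
  for (id in names(study$cohorts)) {
    co <- study$cohorts[[id]]
    dosage <- if (!is.null(co$snps)) t(co$snps$dosage) else NULL
    bg <- background_probes(co$probes, regions)
    X_qc <- co$intensities
    if (sum(colnames(X_qc) %in% bg) >= 100)
      X_qc <- X_qc[, colnames(X_qc) %in% bg, drop = FALSE]
    rep <- sample_qc(X_qc, dosage = dosage,
                     noise_threshold = noise_threshold, pc_sd = pc_sd)
    qc[[id]] <- rep
    note("qc %s: %d samples in, %d retained (%d replicate, %d noise, %d PC outlier)",
         id, nrow(rep), sum(rep$retained), sum(rep$flag_replicate),
         sum(rep$flag_noise), sum(rep$flag_pc_outlier))
  }

  ## stage 2: per-CNVR 1-D intensity summaries over QC-passing samples
  summaries <- list()
  for (id in names(study$cohorts)) {
    co <- study$cohorts[[id]]
    keep <- qc[[id]]$sample_id[qc[[id]]$retained]
    X <- co$intensities[rownames(co$intensities) %in% keep, , drop = FALSE]
    summaries[[id]] <- lapply(seq_len(nrow(regions)), function(j)
      summarize_cnvr(X, co$probes, regions[j, ]))
    names(summaries[[id]]) <- regions$cnvr_id
  }

  ## stage 3: free-K calling in reference, fixed-K elsewhere, compatibility
  harmony <- harmonize_cohorts(summaries, reference, alpha = alpha,
                               seed = seed, K_max = K_max,
                               n_restarts = n_restarts)
  note("harmonize: %d CNVRs polymorphic in %s, %d admitted to >=2 cohorts",
       nrow(harmony$admitted), reference,
       sum(harmony$admitted$n_compatible >= 2))

  ## stage 4: posterior doses for every admitted cohort-CNVR pair
  calls <- list()
  for (id in names(harmony$models)) {
    calls[[id]] <- list()
    for (cv in names(harmony$models[[id]]))
      calls[[id]][[cv]] <- posterior_doses(harmony$models[[id]][[cv]], cv)
  }

  ## stage 5: per-cohort per-trait dose association
  assoc <- list()
  for (id in names(study$cohorts)) {
    ph <- study$cohorts[[id]]$phenotypes
    if (is.null(ph) || length(calls[[id]]) == 0) next
    ph <- ph[ph$sample_id %in% qc[[id]]$sample_id[qc[[id]]$retained], ,
             drop = FALSE]
    assoc[[id]] <- associate_cohort(calls[[id]], ph, traits = traits,
                                    cohort = id)
  }
  assoc_all <- do.call(rbind, assoc)
  note("association: %d cohort-CNVR-trait results", NROW(assoc_all))

  ## stage 6: IVW meta-analysis over cohorts (shared trait units)
  meta <- meta_associations(assoc_all, method = "IVW")
  meta <- meta[meta$n_studies >= 1, , drop = FALSE]

  ## stage 7: suggestive signals and tag SNPs (LD panel = reference cohort)
  suggestive <- select_suggestive(meta, p_threshold = suggestive_p)
  note("meta: %d CNVR-trait pairs, %d suggestive at P<%g",
       nrow(meta), nrow(suggestive), suggestive_p)
  snps <- study$cohorts[[reference]]$snps
  tags <- NULL
  if (nrow(suggestive) > 0) {
    tag_rows <- lapply(unique(suggestive$cnvr_id), function(cv) {
      cc <- calls[[reference]][[cv]]
      if (is.null(cc)) return(NULL)
      dose <- stats::setNames(cc$dose, cc$sample_id)
      tag_r2(dose, snps, regions[regions$cnvr_id == cv, ],
             r2_threshold = tag_r2_threshold)
    })
    tags <- do.call(rbind, tag_rows[!vapply(tag_rows, is.null, logical(1))])
    if (!is.null(tags))
      note("tagging: %d/%d suggestive CNVRs tagged at r2>%g",
           sum(tags$tagged), nrow(tags), tag_r2_threshold)
  }

  ## stage 8: replication through external summary statistics
  replication <- NULL
  if (!is.null(studies) && !is.null(tags) && nrow(suggestive) > 0) {
    replication <- replicate_tags(suggestive, tags, studies,
                                  alpha = bonferroni_alpha)
    note("replication: %d tagged tests, threshold %g, %d replicated",
         attr(replication, "n_tests"),
         if (NROW(replication)) replication$threshold[1] else NA,
         sum(replication$replicated %in% TRUE))
  }

  out <- structure(list(qc = qc, harmony = harmony, calls = calls,
                        assoc = assoc_all, meta = meta,
                        suggestive = suggestive, tags = tags,
                        replication = replication,
                        log = unlist(log), seed = seed),
                   class = "cnv_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# rbind data.frames whose posterior columns differ in K, padding with NA
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA_real_
    d[, cols, drop = FALSE]
  }))
}

# probe ids not inside any catalogued CNVR (used for the noise metric)
background_probes <- function(probes, regions) {
  inside <- rep(FALSE, nrow(probes))
  for (j in seq_len(nrow(regions))) {
    inside <- inside | (probes$chrom == regions$chrom[j] &
                          probes$pos >= regions$start[j] &
                          probes$pos < regions$end[j])
  }
  probes$probe_id[!inside]
}

#' Write every pipeline stage table to a directory
#' @param result a `cnv_pipeline_result`.
#' @param out_dir directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- result$seed
  for (id in names(result$qc))
    write_result_tsv(result$qc[[id]],
                     file.path(out_dir, sprintf("qc_%s.tsv", id)), seed)
  write_result_tsv(result$harmony$report,
                   file.path(out_dir, "harmonization.tsv"), seed)
  write_result_tsv(result$harmony$admitted,
                   file.path(out_dir, "admitted.tsv"), seed)
  for (id in names(result$calls)) {
    if (length(result$calls[[id]]) == 0) next
    write_result_tsv(rbind_fill(result$calls[[id]]),
                     file.path(out_dir, sprintf("calls_%s.tsv", id)), seed)
  }
  write_result_tsv(result$assoc, file.path(out_dir, "association.tsv"), seed)
  write_result_tsv(result$meta, file.path(out_dir, "meta.tsv"), seed)
  if (NROW(result$suggestive))
    write_result_tsv(result$suggestive,
                     file.path(out_dir, "suggestive.tsv"), seed)
  if (NROW(result$tags))
    write_result_tsv(result$tags, file.path(out_dir, "tags.tsv"), seed)
  if (NROW(result$replication))
    write_result_tsv(result$replication,
                     file.path(out_dir, "replication.tsv"), seed)
  writeLines(result$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' @export
print.cnv_pipeline_result <- function(x, ...) {
  cat("CNV association pipeline result\n")
  for (line in x$log) cat(" ", line, "\n")
  if (NROW(x$meta)) {
    cat("top meta-analysis signals:\n")
    print(utils::head(x$meta[, c("cnvr_id", "trait", "n_studies", "beta",
                                 "se", "p", "direction")], 5), row.names = FALSE)
  }
  invisible(x)
}
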