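# Cross-cohort harmonization: anchor the class count to the best-performing
# (reference) cohort, re-cluster other cohorts at the reference K, test
# class-frequency compatibility by Pearson chi-square, and classify CNVR type.

#' MAP class counts for one fitted CNVR
#'
#' @param model a fitted `cnv_mixture`.
#' @return integer vector of MAP-class tallies (length `K`).
#' @export
class_counts <- function(model) {
  stopifnot(inherits(model, "cnv_mixture"), !isTRUE(model$uncallable))
  map <- max.col(model$gamma, ties.method = "first")
  tabulate(map, nbins = model$K)
}

# Pool classes whose expected count (under pooled margins) is below 1 with
# the adjacent class, so the chi-square approximation stays valid.
pool_sparse_classes <- function(ref, test, min_expected = 1) {
  repeat {
    K <- length(ref)
    if (K <= 1) break
    tot <- ref + test
    exp_ref <- tot * sum(ref) / sum(ref + test)
    exp_test <- tot * sum(test) / sum(ref + test)
    bad <- which(pmin(exp_ref, exp_test) < min_expected)
    if (length(bad) == 0) break
    j <- bad[1]
    nb <- if (j == 1) 2L else j - 1L           # pool with the adjacent class
    ref[nb] <- ref[nb] + ref[j]; test[nb] <- test[nb] + test[j]
    ref <- ref[-j]; test <- test[-j]
  }
  list(ref = ref, test = test)
}

#' Class-frequency compatibility between two cohorts
#'
#' Pearson chi-square test on the 2 x K contingency table of MAP-class
#' counts.  Cohorts with different class counts are incompatible by
#' construction (no test is run).  Classes with expected count below 1 are
#' pooled with the adjacent class before testing.  Compatible iff
#' `P >= alpha`.
#'
#' @param counts_ref,counts_test integer class-count vectors.
#' @param alpha compatibility significance level (default 0.05).
#' @return list of class `compatibility_result`: `chisq, df, p, compatible,
#'   reason`.
#' @export
class_frequency_compatibility <- function(counts_ref, counts_test, alpha = 0.05) {
  if (length(counts_ref) != length(counts_test)) {
    return(structure(list(chisq = NA_real_, df = NA_integer_, p = NA_real_,
                          compatible = FALSE, reason = "class-count mismatch"),
                     class = "compatibility_result"))
  }
  pooled <- pool_sparse_classes(counts_ref, counts_test)
  if (length(pooled$ref) < 2) {
    # everything pooled into one class: identical degenerate distributions
    return(structure(list(chisq = 0, df = 0L, p = 1, compatible = TRUE,
                          reason = "single pooled class"),
                     class = "compatibility_result"))
  }
  tab <- rbind(pooled$ref, pooled$test)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(chisq = unname(ct$statistic), df = unname(ct$parameter),
                 p = unname(ct$p.value),
                 compatible = unname(ct$p.value) >= alpha, reason = NA_character_),
            class = "compatibility_result")
}

#' Classify CNVR type from a fitted mixture
#'
#' The modal class (largest weight) is taken as the diploid anchor; classes
#' with smaller mean are losses, classes with larger mean gains.  Losses only
#' gives `"deletion"`, gains only `"amplification"`, both — or more than 3
#' classes — `"multiallelic"`; a single class is `"non-polymorphic"`.
#'
#' @param model a fitted `cnv_mixture`.
#' @return character type label.
#' @export
classify_cnvr <- function(model) {
  stopifnot(inherits(model, "cnv_mixture"))
  if (model$K == 1) return("non-polymorphic")
  if (model$K > 3) return("multiallelic")
  modal <- which.max(model$pi)
  losses <- modal > 1
  gains <- modal < model$K
  if (losses && gains) "multiallelic"
  else if (losses) "deletion"
  else "amplification"
}

#' Harmonize copy-number calls across cohorts
#'
#' For each CNVR: (1) the reference cohort's freely selected class count
#' `K_ref` is the best estimate of the true class count; (2) every other
#' cohort is re-clustered at `K_ref` when its free selection differed
#' (the re-cluster worklist); (3) the re-clustered calls are tested for
#' class-frequency compatibility with the reference; (4) the CNVR is
#' admitted to meta-analysis for exactly the compatible cohorts (the
#' reference is always compatible with itself).
#'
#' @param summaries named list (cohort -> named list of `cnvr_summary`
#'   objects, one per CNVR).
#' @param reference reference (best-performing) cohort id.
#' @param alpha compatibility level.
#' @param seed clustering seed.
#' @param K_max,min_class_count forwarded to the caller.
#' @param ... further arguments for [fit_mixture()] (e.g. `n_restarts`).
#' @return object of class `harmonization`: list with
#'   * `report`: data.frame `cnvr_id, cohort, K_free, K_ref, reclustered,
#'     chisq, p, compatible, type`;
#'   * `models`: cohort -> cnvr -> fitted `cnv_mixture` at the harmonized K;
#'   * `admitted`: data.frame `cnvr_id, n_compatible` over reference-polymorphic
#'     CNVRs;
#'   * `excluded`: CNVRs not polymorphic (or uncallable) in the reference.
#' @export
harmonize_cohorts <- function(summaries, reference, alpha = 0.05, seed = 1,
                              K_max = 6, min_class_count = 3, ...) {
  stopifnot(reference %in% names(summaries))
  cnvr_ids <- names(summaries[[reference]])
  report <- list(); models <- lapply(summaries, function(x) list())
  admitted <- list(); excluded <- list()
  for (cv in cnvr_ids) {
    ref_sum <- summaries[[reference]][[cv]]
    if (isTRUE(ref_sum$uncallable) || length(ref_sum$values) < 30) {
      excluded[[cv]] <- "uncallable in reference"
      next
    }
    sel <- select_classes(ref_sum$values, K_max = K_max, seed = seed,
                          min_class_count = min_class_count, ...)
    if (!sel$polymorphic) {
      excluded[[cv]] <- "not polymorphic in reference"
      next
    }
    K_ref <- sel$K
    models[[reference]][[cv]] <- sel$model
    ref_counts <- class_counts(sel$model)
    n_compat <- 1L
    report[[length(report) + 1]] <- data.frame(
      cnvr_id = cv, cohort = reference, K_free = K_ref, K_ref = K_ref,
      reclustered = FALSE, chisq = 0, p = 1, compatible = TRUE,
      type = classify_cnvr(sel$model), stringsAsFactors = FALSE)
    for (co in setdiff(names(summaries), reference)) {
      s <- summaries[[co]][[cv]]
      if (is.null(s) || isTRUE(s$uncallable) || length(s$values) < 5 * K_ref) {
        report[[length(report) + 1]] <- data.frame(
          cnvr_id = cv, cohort = co, K_free = NA_integer_, K_ref = K_ref,
          reclustered = FALSE, chisq = NA_real_, p = NA_real_,
          compatible = FALSE, type = NA_character_, stringsAsFactors = FALSE)
        next
      }
      free <- select_classes(s$values, K_max = K_max, seed = seed,
                             min_class_count = min_class_count, ...)
      recl <- free$K != K_ref
      model <- if (recl)
        call_with_fixed_k(s$values, K_ref, seed = seed,
                          min_class_count = min_class_count, ...)
      else free$model
      cmp <- class_frequency_compatibility(ref_counts, class_counts(model),
                                           alpha = alpha)
      if (cmp$compatible) {
        n_compat <- n_compat + 1L
        models[[co]][[cv]] <- model
      }
      report[[length(report) + 1]] <- data.frame(
        cnvr_id = cv, cohort = co, K_free = free$K, K_ref = K_ref,
        reclustered = recl, chisq = cmp$chisq, p = cmp$p,
        compatible = cmp$compatible, type = classify_cnvr(model),
        stringsAsFactors = FALSE)
    }
    admitted[[length(admitted) + 1]] <- data.frame(
      cnvr_id = cv, K = K_ref, n_compatible = n_compat, stringsAsFactors = FALSE)
  }
  structure(list(
    report = do.call(rbind, report),
    models = models,
    admitted = if (length(admitted)) do.call(rbind, admitted) else
      data.frame(cnvr_id = character(0), K = integer(0),
                 n_compatible = integer(0)),
    excluded = data.frame(cnvr_id = names(excluded),
                          reason = unlist(excluded, use.names = FALSE),
                          stringsAsFactors = FALSE),
    reference = reference, alpha = alpha
  ), class = "harmonization")
}

#' @export
print.harmonization <- function(x, ...) {
  cat(sprintf("Harmonization against '%s' (alpha=%g)\n", x$reference, x$alpha))
  cat(sprintf("  %d CNVRs polymorphic in reference, %d excluded\n",
              nrow(x$admitted), nrow(x$excluded)))
  if (nrow(x$admitted))
    print(table(`compatible cohorts` = x$admitted$n_compatible))
  invisible(x)
}
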