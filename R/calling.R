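# Per-CNVR copy-number genotype calling: 1-D intensity summarization,
# EM Gaussian mixture clustering with BIC class-number selection, fixed-K
# re-clustering, and posterior copy-number dose.
#
# Classes are labelled 0..K-1 by ascending mean intensity; absolute copy
# anchoring is not attempted — dose-based association is invariant to an
# affine relabelling of the classes.

#' Summarize a CNVR to one intensity value per sample
#'
#' Mean LRR over the probes falling inside the region (BED convention:
#' a probe at position `p` is in-region iff `start <= p < end` on the same
#' chromosome).  Samples with any missing in-region probe are excluded.
#'
#' @param intensities samples x probes matrix (colnames = probe ids,
#'   rownames = sample ids).
#' @param probes manifest data.frame with `probe_id, chrom, pos`.
#' @param region list or one-row data.frame with `chrom, start, end, cnvr_id`.
#' @return object of class `cnvr_summary`: list with `cnvr_id`, `values`
#'   (named numeric vector over included samples), `excluded` (data.frame of
#'   excluded sample ids and reasons), `n_probes`, and `uncallable` flag
#'   (TRUE when no probe maps inside the region).
#' @export
summarize_cnvr <- function(intensities, probes, region) {
  in_region <- probes$chrom == region$chrom &
    probes$pos >= region$start & probes$pos < region$end
  probe_ids <- intersect(probes$probe_id[in_region], colnames(intensities))
  if (length(probe_ids) == 0)
    return(structure(list(cnvr_id = region$cnvr_id, values = numeric(0),
                          excluded = data.frame(), n_probes = 0L,
                          uncallable = TRUE),
                     class = "cnvr_summary"))
  X <- intensities[, probe_ids, drop = FALSE]
  any_na <- apply(X, 1, anyNA)
  values <- rowMeans(X[!any_na, , drop = FALSE])
  excluded <- data.frame(sample_id = rownames(X)[any_na],
                         reason = rep("missing in-region probe", sum(any_na)),
                         stringsAsFactors = FALSE)
  structure(list(cnvr_id = region$cnvr_id, values = values,
                 excluded = excluded, n_probes = length(probe_ids),
                 uncallable = FALSE),
            class = "cnvr_summary")
}

# One EM run from a given initialization; returns fit with log-likelihood
# trace.  Free per-component variances with a floor; log-space E-step.
em_gmm_once <- function(x, pi0, mu0, sigma20, max_iter = 500, tol = 1e-8,
                        var_floor = 1e-6) {
  n <- length(x); K <- length(mu0)
  pi_k <- pi0; mu <- mu0; sigma2 <- pmax(sigma20, var_floor)
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  gamma <- matrix(0, n, K)
  dev <- matrix(0, n, K)                   # (x - mu_k)^2 workspace
  for (iter in seq_len(max_iter)) {
    for (k in seq_len(K)) dev[, k] <- (x - mu[k])^2
    logd <- sweep(dev, 2, -2 * sigma2, "/")
    logd <- sweep(logd, 2,
                  log(pi_k) - 0.5 * log(2 * pi * sigma2), "+")
    m <- logd[, 1]
    if (K > 1) for (k in 2:K) m <- pmax(m, logd[, k])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    gamma <- exp(logd - lse)
    ll_trace[iter] <- ll
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    nk <- colSums(gamma)
    alive <- nk > 1e-10
    pi_k <- nk / n
    mu[alive] <- colSums(gamma * x)[alive] / nk[alive]
    for (k in which(alive))
      sigma2[k] <- max(sum(gamma[, k] * (x - mu[k])^2) / nk[k], var_floor)
  }
  list(pi = pi_k, mu = mu, sigma2 = sigma2, gamma = gamma,
       loglik = ll, ll_trace = ll_trace[seq_len(iter)], iters = iter)
}

#' Fit a K-component Gaussian mixture to CNVR intensity summaries
#'
#' Maximum-likelihood EM with 10 restarts (quantile-based means plus random
#' perturbations), convergence when the relative log-likelihood change falls
#' below `tol` (default 1e-8) or after `max_iter` iterations, per-component
#' variances floored at `var_floor`, and components relabelled by ascending
#' mean.  Model-selection score is BIC (`-2 logL + (3K-1) log n`; smaller is
#' better).
#'
#' @param x numeric summary values (one per sample; names kept).
#' @param K number of classes (`>= 1`).
#' @param seed integer seed for the restart ladder.
#' @param n_restarts number of EM restarts (default 10).
#' @param max_iter,tol,var_floor EM controls.
#' @return object of class `cnv_mixture`: `K, pi, mu, sigma2, gamma`
#'   (samples x K posterior matrix), `loglik, bic, ll_trace, degenerate`.
#' @export
fit_mixture <- function(x, K, seed = 1, n_restarts = 10, max_iter = 500,
                        tol = 1e-8, var_floor = 1e-6) {
  stopifnot(K >= 1)
  nm <- names(x); x <- as.numeric(x); n <- length(x)
  if (n < 5 * K) stop(sprintf("need n >= 5K (n=%d, K=%d)", n, K))
  if (diff(range(x)) < 1e-12) {
    # degenerate data: all mass in one class regardless of requested K
    gamma <- matrix(0, n, K); gamma[, 1] <- 1
    rownames(gamma) <- nm
    return(structure(list(K = K, pi = c(1, rep(0, K - 1)),
                          mu = rep(x[1], K), sigma2 = rep(var_floor, K),
                          gamma = gamma, loglik = sum(stats::dnorm(
                            x, x[1], sqrt(var_floor), log = TRUE)),
                          bic = NA_real_, ll_trace = numeric(0),
                          degenerate = TRUE),
                     class = "cnv_mixture"))
  }
  set.seed(seed)
  qmu <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  pooled <- stats::var(x) / max(K, 2)
  spread <- diff(range(x))
  # short EM from each restart, then run the best start to full convergence
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu0 <- if (r == 1) qmu else qmu + stats::rnorm(K, 0, 0.1 * spread)
    fit <- em_gmm_once(x, rep(1 / K, K), sort(mu0), rep(pooled, K),
                       max_iter = min(50, max_iter), tol = tol,
                       var_floor = var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  polish <- em_gmm_once(x, best$pi, best$mu, best$sigma2,
                        max_iter = max_iter, tol = tol, var_floor = var_floor)
  if (polish$loglik >= best$loglik) {
    polish$ll_trace <- c(best$ll_trace, polish$ll_trace[-1])
    best <- polish
  }
  ord <- order(best$mu)
  gamma <- best$gamma[, ord, drop = FALSE]
  rownames(gamma) <- nm
  structure(list(K = K, pi = best$pi[ord], mu = best$mu[ord],
                 sigma2 = best$sigma2[ord], gamma = gamma,
                 loglik = best$loglik,
                 bic = -2 * best$loglik + (3 * K - 1) * log(n),
                 ll_trace = best$ll_trace, degenerate = FALSE),
            class = "cnv_mixture")
}

#' @export
print.cnv_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K=%d, logL=%.3f, BIC=%.3f%s\n", x$K,
              x$loglik, x$bic, if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  print(round(data.frame(pi = x$pi, mu = x$mu, sigma = sqrt(x$sigma2)), 4))
  invisible(x)
}

#' Select the number of copy-number classes by BIC
#'
#' Fits `K = 1..K_max` mixtures and keeps the minimum-BIC model (ties broken
#' toward smaller K).  The CNVR is polymorphic iff the selected `K >= 2` and
#' every class has expected count `pi_k * n >= min_class_count`.
#'
#' @inheritParams fit_mixture
#' @param K_max largest class count considered (default 6).
#' @param min_class_count minimum expected class count for a polymorphic call.
#' @return list `K` (selected), `model` (`cnv_mixture`), `polymorphic`
#'   (logical), `bic` (vector over K).
#' @export
select_classes <- function(x, K_max = 6, seed = 1, min_class_count = 3, ...) {
  if (length(x) < 30) stop("need at least 30 samples for class selection")
  fits <- list(); bics <- rep(NA_real_, K_max)
  for (k in seq_len(K_max)) {
    if (length(x) < 5 * k) break
    fits[[k]] <- fit_mixture(x, k, seed = seed, ...)
    bics[k] <- fits[[k]]$bic
    if (isTRUE(fits[[k]]$degenerate)) break   # constant data: K=1 only
  }
  bics_ok <- ifelse(is.na(bics), Inf, bics)
  best_k <- which.min(bics_ok)                # ties resolve to smaller K
  if (all(!is.finite(bics_ok))) best_k <- 1L
  model <- fits[[best_k]]
  n <- nrow(model$gamma)
  poly <- best_k >= 2 && all(model$pi * n >= min_class_count)
  list(K = as.integer(best_k), model = model, polymorphic = poly, bic = bics)
}

#' Re-cluster with the class count fixed to a reference cohort's K
#'
#' As [fit_mixture()] with `K` forced to `K_ref`.  The fit is flagged
#' low-quality when any class has expected count below `min_class_count`, and
#' uncallable when there are fewer than `5 * K_ref` samples.
#'
#' @inheritParams fit_mixture
#' @param K_ref class count from the reference (best-performing) cohort.
#' @param min_class_count minimum expected class count.
#' @return `cnv_mixture` with extra fields `low_quality` and `uncallable`.
#' @export
call_with_fixed_k <- function(x, K_ref, seed = 1, min_class_count = 3, ...) {
  stopifnot(K_ref >= 1)
  if (length(x) < 5 * K_ref) {
    return(structure(list(K = K_ref, uncallable = TRUE, low_quality = TRUE),
                     class = "cnv_mixture"))
  }
  model <- fit_mixture(x, K_ref, seed = seed, ...)
  model$low_quality <- any(model$pi * nrow(model$gamma) < min_class_count)
  model$uncallable <- FALSE
  model
}

#' Posterior copy-number calls and doses
#'
#' MAP class (`argmax_k gamma_ik`, labels `0..K-1` ordered by ascending
#' mean), continuous dose `d_i = sum_k k * gamma_ik`, and call confidence
#' `max_k gamma_ik`.
#'
#' @param model a fitted `cnv_mixture`.
#' @param cnvr_id optional CNVR id carried into the output.
#' @return data.frame of class `copy_number_calls`: `sample_id, cnvr_id,
#'   map_class, dose, confidence` plus one `postK` column per class.
#' @export
posterior_doses <- function(model, cnvr_id = NA_character_) {
  stopifnot(inherits(model, "cnv_mixture"), !isTRUE(model$uncallable))
  g <- model$gamma
  k_idx <- seq_len(model$K) - 1L
  out <- data.frame(
    sample_id = rownames(g) %||% sprintf("S%04d", seq_len(nrow(g))),
    cnvr_id = cnvr_id,
    map_class = as.integer(max.col(g, ties.method = "first") - 1L),
    dose = as.numeric(g %*% k_idx),
    confidence = apply(g, 1, max),
    stringsAsFactors = FALSE)
  post <- as.data.frame(g)
  names(post) <- paste0("post", k_idx)
  out <- cbind(out, post)
  rownames(out) <- NULL
  class(out) <- c("copy_number_calls", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
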