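# Trait association with copy-number dose: two-stage covariate adjustment
# (residual-then-regress), optional inverse rank-normal transform, linear
# dose association for unrelated samples, and a Gaussian GEE with
# exchangeable working correlation and sandwich standard errors for
# family-structured cohorts.

#' Covariate-adjust a quantitative trait
#'
#' Residuals from least squares of the trait on intercept + age + age^2 +
#' sex + height + height^2 + the first `n_pcs` ancestry principal
#' components (when present as `PC1..` columns).  Samples missing the trait
#' or any covariate are dropped (returned as `NA` residuals); collinear
#' covariate columns are dropped with a warning.
#'
#' @param trait numeric trait vector (aligned with `covariates` rows).
#' @param covariates data.frame with `age, sex, height` and optional
#'   `PC1..PCn` columns.
#' @param n_pcs number of PC columns to use if present (default 4).
#' @return numeric residual vector (NA where the sample was dropped), with
#'   attribute `"n_used"`.
#' @export
adjust_phenotype <- function(trait, covariates, n_pcs = 4) {
  stopifnot(length(trait) == nrow(covariates))
  M <- data.frame(age = covariates$age, age2 = covariates$age^2,
                  sex = covariates$sex, height = covariates$height,
                  height2 = covariates$height^2)
  pc_cols <- intersect(paste0("PC", seq_len(n_pcs)), names(covariates))
  for (pc in pc_cols) M[[pc]] <- covariates[[pc]]
  ok <- stats::complete.cases(M) & !is.na(trait)
  X <- cbind(`(Intercept)` = 1, as.matrix(M[ok, , drop = FALSE]))
  # drop constant / collinear columns (e.g. single-sex subsets)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear covariate(s): ", paste(drop, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  fit <- stats::lm.fit(X, trait[ok])
  res <- rep(NA_real_, length(trait))
  res[ok] <- fit$residuals
  attr(res, "n_used") <- sum(ok)
  res
}

#' Inverse rank inverse-normal transform
#'
#' Maps the value with rank `r` among `n` to `qnorm((r - 3/8) / (n + 1/4))`
#' (Blom offset); ties share their average rank.  `NA`s are preserved.
#'
#' @param values numeric vector (`n >= 2`, not all equal).
#' @return numeric vector of normal scores.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2) stop("need at least 2 non-missing values")
  if (diff(range(x)) == 0) stop("all values equal: no rank information")
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

assoc_result <- function(cnvr_id, trait, cohort, beta, se, p, n, method) {
  structure(data.frame(
    cnvr_id = cnvr_id, trait = trait, cohort = cohort,
    beta = beta, se = se, p = p, n = n,
    direction = if (is.na(beta)) "." else if (beta >= 0) "+" else "-",
    method = method, stringsAsFactors = FALSE),
    class = c("association_result", "data.frame"))
}

#' Linear association of an adjusted trait with copy-number dose
#'
#' Least-squares slope of the adjusted trait on dose, with a two-sided P
#' from the slope's t statistic.  Pairs with missing trait or dose are
#' dropped; fewer than `min_n` complete pairs, or zero dose variance, gives
#' a no-result row (direction ".").
#'
#' @param adjusted numeric adjusted trait vector.
#' @param dose numeric dose vector (same length).
#' @param cnvr_id,trait,cohort identifiers carried into the result.
#' @param min_n minimum complete pairs (default 30).
#' @return one-row data.frame of class `association_result`:
#'   `cnvr_id, trait, cohort, beta, se, p, n, direction, method`.
#' @export
linear_dose_association <- function(adjusted, dose, cnvr_id = NA, trait = NA,
                                    cohort = NA, min_n = 30) {
  stopifnot(length(adjusted) == length(dose))
  ok <- !is.na(adjusted) & !is.na(dose)
  n <- sum(ok)
  if (n < min_n || stats::var(dose[ok]) == 0)
    return(assoc_result(cnvr_id, trait, cohort, NA_real_, NA_real_, NA_real_,
                        n, "lm"))
  fit <- stats::lm(adjusted[ok] ~ dose[ok])
  s <- summary(fit)$coefficients["dose[ok]", ]
  assoc_result(cnvr_id, trait, cohort, s[["Estimate"]], s[["Std. Error"]],
               s[["Pr(>|t|)"]], n, "lm")
}

# Gaussian GEE with identity link.  Exchangeable working correlation: the
# common correlation alpha is estimated from within-cluster products of
# Pearson residuals; independence reduces to OLS.  Robust (sandwich)
# covariance in both cases.
gee_gaussian <- function(y, X, id, corstr = c("exchangeable", "independence"),
                         max_iter = 25, tol = 1e-10) {
  corstr <- match.arg(corstr)
  p <- ncol(X); N <- length(y)
  cl <- split(seq_len(N), id)
  beta <- qr.solve(crossprod(X), crossprod(X, y))   # OLS start
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    e <- as.numeric(y - X %*% beta)
    phi <- sum(e^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni > 1) {
          s <- sum(e[ix])
          num <- num + (s^2 - sum(e[ix]^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (npairs > p) num / phi / (npairs - p) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    if (corstr == "independence" || alpha == 0) { beta_new <- beta; if (iter > 1) break }
    # GLS update with V_i = phi * [(1-alpha) I + alpha J]; closed-form inverse
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in cl) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]; yi <- y[ix]
      c1 <- 1 / (1 - alpha)
      c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      XtVi <- c1 * t(Xi) + c2 * tcrossprod(colSums(Xi), rep(1, ni))
      A <- A + XtVi %*% Xi
      b <- b + XtVi %*% yi
    }
    beta_new <- qr.solve(A, b)
    if (max(abs(beta_new - beta)) < tol * (max(abs(beta)) + 1)) { beta <- beta_new; break }
    beta <- beta_new
  }
  # sandwich covariance: B^{-1} M B^{-1}
  e <- as.numeric(y - X %*% beta)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]; ei <- e[ix]
    if (corstr == "exchangeable" && alpha != 0) {
      c1 <- 1 / (1 - alpha)
      c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      XtVi <- c1 * t(Xi) + c2 * tcrossprod(colSums(Xi), rep(1, ni))
    } else XtVi <- t(Xi)
    B <- B + XtVi %*% Xi
    u <- XtVi %*% ei
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vcov <- Binv %*% M %*% Binv
  list(beta = as.numeric(beta), vcov = vcov, alpha = alpha,
       n = N, n_clusters = length(cl))
}

#' GEE association of an adjusted trait with dose in family data
#'
#' Gaussian generalized-estimating-equation regression of the adjusted trait
#' on dose with an exchangeable working correlation within families and
#' robust (sandwich) standard errors; two-sided P from the Wald z.  With
#' singleton-only clusters the estimate equals OLS.
#'
#' @inheritParams linear_dose_association
#' @param family_id cluster (family) identifier per sample; `NA` values are
#'   treated as singleton clusters.
#' @param corstr working correlation, `"exchangeable"` (default) or
#'   `"independence"`.
#' @return one-row `association_result` data.frame (method `"gee"`).
#' @export
gee_dose_association <- function(adjusted, dose, family_id, cnvr_id = NA,
                                 trait = NA, cohort = NA, min_n = 30,
                                 corstr = "exchangeable") {
  stopifnot(length(adjusted) == length(dose), length(dose) == length(family_id))
  ok <- !is.na(adjusted) & !is.na(dose)
  n <- sum(ok)
  if (n < min_n || stats::var(dose[ok]) == 0)
    return(assoc_result(cnvr_id, trait, cohort, NA_real_, NA_real_, NA_real_,
                        n, "gee"))
  id <- as.character(family_id[ok])
  id[is.na(family_id[ok])] <- paste0(".singleton", seq_len(sum(is.na(family_id[ok]))))
  X <- cbind(1, dose[ok])
  fit <- gee_gaussian(adjusted[ok], X, id, corstr = corstr)
  beta <- fit$beta[2]; se <- sqrt(fit$vcov[2, 2])
  p <- 2 * stats::pnorm(-abs(beta / se))
  assoc_result(cnvr_id, trait, cohort, beta, se, p, n, "gee")
}

#' Per-cohort CNVR-trait association table
#'
#' Runs [adjust_phenotype()] once per trait and then
#' [linear_dose_association()] (or [gee_dose_association()] when the cohort
#' has family structure) for every CNVR's dose vector.
#'
#' @param calls named list (cnvr -> `copy_number_calls` data.frame).
#' @param phenotypes data.frame with `sample_id`, trait columns, covariates
#'   and optional `family_id`.
#' @param traits trait column names to test.
#' @param cohort cohort id carried into results.
#' @param use_gee force the GEE path; default: used iff any non-`NA`
#'   `family_id` is present.
#' @param transform apply [inverse_normal_transform()] to adjusted traits.
#' @return data.frame of stacked `association_result` rows.
#' @export
associate_cohort <- function(calls, phenotypes, traits = c("FEV1", "FVC", "RATIO"),
                             cohort = NA, use_gee = NULL, transform = FALSE) {
  if (is.null(use_gee))
    use_gee <- "family_id" %in% names(phenotypes) &&
      any(!is.na(phenotypes$family_id))
  adj <- lapply(traits, function(tr) {
    a <- adjust_phenotype(phenotypes[[tr]], phenotypes)
    if (transform) a <- inverse_normal_transform(a)
    a
  })
  names(adj) <- traits
  out <- list()
  for (cv in names(calls)) {
    cc <- calls[[cv]]
    dose <- cc$dose[match(phenotypes$sample_id, cc$sample_id)]
    for (tr in traits) {
      out[[length(out) + 1]] <- if (use_gee)
        gee_dose_association(adj[[tr]], dose, phenotypes$family_id,
                             cnvr_id = cv, trait = tr, cohort = cohort)
      else
        linear_dose_association(adj[[tr]], dose, cnvr_id = cv, trait = tr,
                                cohort = cohort)
    }
  }
  do.call(rbind, out)
}
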