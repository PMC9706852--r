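#' McFadden's pseudo-R-squared
#'
#' Fits `labels ~ signature + covariates` by logistic regression and returns
#' `1 - lnL(model) / lnL(null)`. The null model is intercept-only by default
#' (the standard definition); set `null = "covariates"` to measure the
#' signature's contribution beyond the adjustment set instead.
#'
#' @param labels binary 0/1 outcome vector.
#' @param signature numeric exposure score, same length.
#' @param covariates optional data.frame of adjustment variables (e.g. age
#'   and sex), same rows.
#' @param null `"intercept"` or `"covariates"`.
#' @return pseudo-R-squared in \[0, 1).
#' @export
mcfadden_r2 <- function(labels, signature, covariates = NULL,
                        null = c("intercept", "covariates")) {
  null <- match.arg(null)
  stopifnot(all(labels %in% 0:1), length(unique(labels)) == 2)
  df <- data.frame(y = labels, signature = signature)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit1 <- stats::glm(y ~ ., data = df, family = stats::binomial())
  if (!fit1$converged) stop("logistic model did not converge")
  fit0 <- if (null == "intercept")
    stats::glm(y ~ 1, data = df, family = stats::binomial())
  else
    stats::glm(y ~ . - signature, data = df, family = stats::binomial())
  1 - as.numeric(stats::logLik(fit1)) / as.numeric(stats::logLik(fit0))
}

#' Area under the ROC curve with confidence interval
#'
#' Discrimination of a score for a binary label: the probability that a
#' randomly drawn case scores higher than a randomly drawn control, ties
#' counting one half (the Mann-Whitney statistic scaled by the number of
#' case-control pairs). The 95% CI uses the DeLong method by default, or a
#' stratified bootstrap.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels (1 = case), same length.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed seed for the bootstrap.
#' @return list with `auc` and `ci95 = c(lo, hi)`.
#' @export
signature_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                          boot_n = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2)
    stop("both classes must be non-empty")
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  # degenerate (perfect-separation) curves make the CI methods warn; the
  # interval they return is still the right answer
  ci <- if (ci_method == "delong") {
    suppressWarnings(pROC::ci.auc(roc, method = "delong"))
  } else {
    set.seed(seed)
    suppressWarnings(pROC::ci.auc(roc, method = "bootstrap", boot.n = boot_n,
                                  boot.stratified = TRUE, progress = "none"))
  }
  list(auc = as.numeric(pROC::auc(roc)),
       ci95 = c(as.numeric(ci[1]), as.numeric(ci[3])))
}

#' Adjusted R-squared for a continuous exposure outcome
#'
#' Ordinary least squares of a continuous outcome (e.g. weekly alcohol
#' units) on the signature plus adjustment covariates, reporting the
#' standard adjusted R-squared.
#'
#' @param outcome continuous outcome vector.
#' @param signature numeric score, same length.
#' @param covariates optional adjustment data.frame.
#' @export
linear_r2_adjusted <- function(outcome, signature, covariates = NULL) {
  df <- data.frame(y = outcome, signature = signature)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  summary(stats::lm(y ~ ., data = df))$adj.r.squared
}

# internal: variance-inflation factors from a design matrix (no intercept)
vif_from_design <- function(X) {
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  v <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
  stats::setNames(v, colnames(X))
}

#' Association between a standardized signature and disease history
#'
#' Logistic regression of a binary outcome on the standardized signature
#' plus adjustment covariates; the exposure estimate is reported as an odds
#' ratio per one standard deviation with a Wald 95% CI. Non-complete cases
#' on the model variables are dropped with a message. Diagnostics: maximum
#' Cook's distance, per-term variance-inflation factors, and a linearity
#' check comparing the linear exposure term against exposure-quartile
#' indicators by likelihood ratio.
#'
#' @param cohort cohort data.frame containing the outcome and covariates.
#' @param signature standardized score vector aligned to `cohort` rows.
#' @param outcome name of the binary outcome column (values `"yes"`/`"no"`
#'   or 0/1); default `"cvd_history"`.
#' @param covariates character vector of covariate column names.
#' @param weights optional observation weights (e.g. from [ipw_weights()]),
#'   aligned to `cohort` rows; weighted fits use a quasibinomial likelihood
#'   so the point estimates equal the weighted ML solution.
#' @return an `association_result`: `or` (per 1 SD), `ci95`, `p_value`,
#'   `n_used`, `n_dropped`, `diagnostics`, `weighting`.
#' @export
cvd_association <- function(cohort, signature, outcome = "cvd_history",
                            covariates = c("age", "sex", "bmi", "education"),
                            weights = NULL) {
  y <- cohort[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "yes")
  stopifnot(all(y %in% 0:1))
  df <- data.frame(y = y, signature = signature)
  for (cv in covariates) df[[cv]] <- cohort[[cv]]
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message(n_dropped, " sample(s) dropped for missing covariates")
  df <- df[cc, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights[cc]

  fam <- if (is.null(weights)) stats::binomial() else stats::quasibinomial()
  fit <- stats::glm(y ~ ., data = df, family = fam, weights = w)
  if (!fit$converged)
    stop("logistic model did not converge; check for separation")
  est <- summary(fit)$coefficients["signature", ]
  if (abs(est[1]) > 15)
    stop("apparent separation on the signature term; inspect the data")
  or <- exp(est[1])
  ci <- exp(est[1] + c(-1, 1) * stats::qnorm(0.975) * est[2])

  mm <- stats::model.matrix(fit)[, -1, drop = FALSE]
  cooks_max <- max(stats::cooks.distance(fit))
  vif <- vif_from_design(mm)

  # linearity of the continuous exposure: quartile indicators vs linear term;
  # skipped (NA) when the exposure has too few distinct levels to bin
  q <- unique(stats::quantile(df$signature, probs = c(0.25, 0.5, 0.75)))
  lin_p <- NA_real_
  if (length(q) == 3) {
    df$sig_q <- cut(df$signature, breaks = c(-Inf, q, Inf), labels = FALSE)
    fit_q <- stats::glm(y ~ . - signature - sig_q + factor(sig_q),
                        family = fam, weights = w, data = df)
    lr <- 2 * (linpred_loglik(fit_q) - linpred_loglik(fit))
    lin_p <- stats::pchisq(max(lr, 0), df = 2, lower.tail = FALSE)
  }

  structure(list(
    outcome = outcome, or = unname(or), ci95 = unname(ci),
    p_value = unname(est[4]), log_or = unname(est[1]), se = unname(est[2]),
    n_used = nrow(df), n_dropped = n_dropped,
    covariates = covariates,
    weighting = if (is.null(weights)) "none" else "IPW",
    diagnostics = list(cooks_max = cooks_max, vif = vif,
                       linearity_p = lin_p,
                       linearity_ok = lin_p > 0.05)),
    class = "association_result")
}

# binomial log-likelihood of a (possibly quasi) logistic fit at its
# fitted values, under the working weights
linpred_loglik <- function(fit) {
  mu <- fit$fitted.values
  y <- fit$y
  w <- fit$prior.weights
  sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s ~ signature [%s]: OR per 1 SD = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d\n",
              x$outcome, x$weighting, x$or, x$ci95[1], x$ci95[2],
              x$p_value, x$n_used))
  invisible(x)
}

#' Inverse-probability weights for epigenetic-data availability
#'
#' Fits a logistic availability model and returns, for the available
#' samples, weights `1 / P(available)`. Weighted analyses of the available
#' subset then estimate the full-cohort association, correcting selection on
#' the modelled predictors (Horvitz-Thompson: the weights sum to roughly the
#' cohort size).
#'
#' @param cohort cohort data.frame with an `available` column
#'   (`"yes"`/`"no"`).
#' @param predictors covariate columns of the availability model.
#' @param truncate_pct optional upper percentile (e.g. 0.99) at which
#'   weights are capped.
#' @return list with `weights` (named by sample id, available samples only),
#'   `fit` summary, `max`, `mean`.
#' @export
ipw_weights <- function(cohort,
                        predictors = c("age", "sex", "smoking_status"),
                        truncate_pct = NULL) {
  av <- as.integer(cohort$available == "yes")
  df <- data.frame(av = av)
  for (p in predictors) df[[p]] <- cohort[[p]]
  fit <- stats::glm(av ~ ., data = df, family = stats::binomial())
  if (!fit$converged) stop("availability model did not converge")
  pi_hat <- stats::fitted(fit)[av == 1]
  if (any(pi_hat < 1e-6) && is.null(truncate_pct))
    stop("near-zero availability probabilities; enable weight truncation")
  w <- 1 / pi_hat
  if (!is.null(truncate_pct))
    w <- pmin(w, stats::quantile(w, truncate_pct))
  list(weights = stats::setNames(w, cohort$id[av == 1]),
       max = max(w), mean = mean(w),
       availability_rate = mean(av))
}

#' Group fixed-effect sensitivity analysis
#'
#' Repeats [cvd_association()] with indicator terms for a grouping factor
#' (recruitment centre or family), so group-level confounding can be
#' compared against the base model. Groups in which the outcome is constant
#' across more than one member are dropped with a message (their indicators
#' would be separated).
#'
#' @inheritParams cvd_association
#' @param group name of the grouping column (e.g. `"center"`).
#' @return an `association_result` with attribute `group`.
#' @export
fixed_effect_sensitivity <- function(cohort, signature, group = "center",
                                     outcome = "cvd_history",
                                     covariates = c("age", "sex", "bmi",
                                                    "education")) {
  g <- as.character(cohort[[group]])
  if (length(unique(g)) < 2) {
    res <- cvd_association(cohort, signature, outcome, covariates)
    attr(res, "group") <- group
    return(res)
  }
  y <- cohort[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "yes")
  keep <- rep(TRUE, nrow(cohort))
  for (lev in unique(g)) {
    in_g <- g == lev
    if (sum(in_g) > 1 && length(unique(y[in_g])) == 1) {
      message("group '", lev, "' has a constant outcome; dropped")
      keep[in_g] <- FALSE
    }
  }
  cohort2 <- cohort[keep, , drop = FALSE]
  cohort2$.group <- factor(g[keep])
  res <- cvd_association(cohort2, signature[keep], outcome,
                         covariates = c(covariates, ".group"))
  attr(res, "group") <- group
  res
}

#' Assemble a validation report for a fitted signature
#'
#' Computes, on a scored cohort, the standard agreement measures between a
#' signature and its self-reported exposure: McFadden pseudo-R-squared and
#' AUC (age- and sex-adjusted model for the pseudo-R-squared), plus for
#' alcohol the heavy-vs-non-drinker contrast and the adjusted R-squared
#' against weekly units.
#'
#' @param cohort cohort data.frame.
#' @param scores data.frame from [score_samples()] aligned to `cohort$id`.
#' @param trait `"smoking"` or `"alcohol"`.
#' @return a `validation_report` list, serializable with
#'   [write_validation_report()].
#' @export
validate_signature <- function(cohort, scores, trait = c("smoking", "alcohol")) {
  trait <- match.arg(trait)
  z <- scores$standardized[match(cohort$id, scores$sample_id)]
  out <- list(trait = trait, comparisons = list())
  oc <- code_outcome(cohort, trait)
  idx <- match(oc$ids, cohort$id)
  covs <- data.frame(age = cohort$age[idx], sex = cohort$sex[idx])
  a <- signature_auc(z[idx], unname(oc$labels))
  out$comparisons[[if (trait == "smoking") "smoker_vs_never"
                   else "drinker_vs_non"]] <-
    list(mcfadden_r2 = mcfadden_r2(unname(oc$labels), z[idx], covs),
         auc = a$auc, auc_ci95 = a$ci95, n = length(idx))
  if (trait == "alcohol") {
    hv <- cohort$alcohol_status %in% c("heavy", "non-drinker")
    lab <- as.integer(cohort$alcohol_status[hv] == "heavy")
    if (length(unique(lab)) == 2) {
      a2 <- signature_auc(z[hv], lab)
      r2h <- tryCatch(
        suppressWarnings(mcfadden_r2(lab, z[hv],
                                     data.frame(age = cohort$age[hv],
                                                sex = cohort$sex[hv]))),
        error = function(e) NA_real_)   # separated contrast: R2 undefined
      out$comparisons$heavy_vs_non <-
        list(mcfadden_r2 = r2h, auc = a2$auc, auc_ci95 = a2$ci95,
             n = sum(hv))
    }
    out$comparisons$units_per_week <-
      list(linear_r2_adjusted = linear_r2_adjusted(
        cohort$alcohol_units_week, z,
        data.frame(age = cohort$age, sex = cohort$sex)),
        n = nrow(cohort))
  }
  structure(out, class = "validation_report")
}

#' Serialize a validation report
#'
#' @param report a `validation_report`.
#' @param path JSON path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
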