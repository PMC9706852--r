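#' Categorize weekly alcohol consumption
#'
#' Sex-specific guideline categories: consuming less than 1 unit per week is
#' a non-drinker; men above 21 units (women above 14) are heavy drinkers;
#' everything between, boundaries included, is moderate.
#'
#' @param units_week weekly alcohol units (>= 0), vectorized.
#' @param sex `"male"`/`"female"`, recycled against `units_week`.
#' @return character vector in `{"non-drinker","moderate","heavy"}`.
#' @export
categorize_alcohol <- function(units_week, sex) {
  if (any(units_week < 0, na.rm = TRUE))
    stop("negative alcohol units")
  sex <- rep_len(as.character(sex), length(units_week))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  cut_heavy <- ifelse(sex == "male", 21, 14)
  ifelse(units_week < 1, "non-drinker",
         ifelse(units_week > cut_heavy, "heavy", "moderate"))
}

#' Binary outcome coding for signature training
#'
#' Smoking models contrast current smokers (1) against never smokers (0),
#' excluding past smokers from training; alcohol models contrast drinkers
#' (at least 1 unit per week, 1) against non-drinkers (0).
#'
#' @param cohort cohort data.frame with `id`, `smoking_status`,
#'   `alcohol_units_week`.
#' @param trait `"smoking"` or `"alcohol"`.
#' @return list with `labels` (named 0/1 vector) and `ids` of retained
#'   samples.
#' @export
code_outcome <- function(cohort, trait = c("smoking", "alcohol")) {
  trait <- match.arg(trait)
  if (trait == "smoking") {
    keep <- cohort$smoking_status %in% c("current smoker", "non-smoker")
    labels <- as.integer(cohort$smoking_status[keep] == "current smoker")
    ids <- cohort$id[keep]
  } else {
    labels <- as.integer(cohort$alcohol_units_week >= 1)
    ids <- cohort$id
  }
  if (length(unique(labels)) < 2)
    stop(sprintf("outcome '%s' has a single class; model unidentifiable",
                 trait))
  list(labels = stats::setNames(labels, ids), ids = ids)
}

#' Draw random candidate model specifications
#'
#' Each specification is a uniform random subset of exactly `max_cpgs` pool
#' CpGs (drawn without replacement within a spec); a CpG with a partner in
#' the mQTL map brings its SNP along as an extra predictor. Duplicate subsets
#' are discarded and redrawn, up to a 10-fold oversampling cap, so the
#' returned list can be shorter than `n_models` when the pool is small.
#'
#' @param pool_cpgs character vector of candidate CpG ids.
#' @param mqtl an `mqtl_map` (may have zero rows).
#' @param n_models number of specifications wanted.
#' @param max_cpgs CpGs per specification (default 7).
#' @param seed integer seed.
#' @return list of specs, each `list(cpg_ids, snp_ids)` with sorted ids.
#' @export
enumerate_random_specs <- function(pool_cpgs, mqtl, n_models,
                                   max_cpgs = 7, seed = 1L) {
  pool_cpgs <- unique(pool_cpgs)
  if (length(pool_cpgs) < max_cpgs)
    stop(sprintf("pool has %d CpGs; need at least %d",
                 length(pool_cpgs), max_cpgs))
  snp_of <- if (!is.null(mqtl) && nrow(mqtl) > 0)
    stats::setNames(mqtl$snp_id, mqtl$cpg_id) else character(0)
  set.seed(seed)
  seen <- character(0)
  specs <- vector("list", n_models)
  found <- 0L; draws <- 0L
  while (found < n_models && draws < 10L * n_models) {
    draws <- draws + 1L
    cpgs <- sort(sample(pool_cpgs, max_cpgs))
    key <- paste(cpgs, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    found <- found + 1L
    snps <- unname(snp_of[intersect(cpgs, names(snp_of))])
    specs[[found]] <- list(cpg_ids = cpgs, snp_ids = sort(snps))
  }
  specs[seq_len(found)]
}

# internal IRLS wrapper around glm.fit: X without intercept column.
# returns coefficients (incl. intercept), SEs, Wald p, log-likelihood and
# convergence/separation flags; aliased (collinear) columns are dropped
# with a warning and recorded.
logistic_ml <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  dropped <- character(0)
  if (anyNA(fit$coefficients)) {
    dropped <- setdiff(names(fit$coefficients)[is.na(fit$coefficients)],
                       "(Intercept)")
    warning("collinear predictor(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep <- setdiff(colnames(X), dropped)
    return(utils::modifyList(logistic_ml(X[, keep, drop = FALSE], y),
                             list(dropped = dropped)))
  }
  k <- fit$rank
  loglik <- k - fit$aic / 2
  p1 <- seq_len(k)
  cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- sqrt(diag(cov_unscaled))
  coefs <- fit$coefficients
  z <- coefs / se
  pvals <- 2 * stats::pnorm(-abs(z))
  if (any(abs(coefs[-1]) > 15)) separated <- TRUE
  list(coefficients = coefs, se = se, p_values = pvals, loglik = loglik,
       n = length(y), k = k, vcov = cov_unscaled,
       converged = isTRUE(fit$converged) && !separated,
       separated = separated, dropped = dropped,
       fitted = fit$fitted.values)
}

# internal: design matrix for a spec (samples x predictors)
spec_design <- function(spec, m, genotypes, ids) {
  miss <- setdiff(spec$cpg_ids, rownames(m))
  if (length(miss))
    stop("CpG probe(s) absent from matrix: ", paste(miss, collapse = ", "))
  X <- t(unclass(m)[spec$cpg_ids, ids, drop = FALSE])
  if (length(spec$snp_ids)) {
    miss <- setdiff(spec$snp_ids, rownames(genotypes))
    if (length(miss))
      stop("SNP(s) absent from genotype matrix: ",
           paste(miss, collapse = ", "))
    X <- cbind(X, t(genotypes[spec$snp_ids, ids, drop = FALSE]))
  }
  X
}

#' Fit one candidate logistic model
#'
#' Maximum-likelihood logistic regression of the binary trait on the spec's
#' CpG M-values and SNP dosages. Non-converged or (quasi-)separated fits are
#' flagged `converged = FALSE` rather than raising, so the surrounding model
#' search can skip them; collinear predictors are dropped with a warning.
#'
#' @param spec `list(cpg_ids, snp_ids)` as produced by
#'   [enumerate_random_specs()].
#' @param m an mvalue-scale [meth_matrix()].
#' @param genotypes dosage matrix (may be `NULL` when the spec has no SNPs).
#' @param labels named 0/1 vector from [code_outcome()].
#' @param min_events minimum samples per class (default 10).
#' @return a `fitted_model` list: spec, coefficients, per-coefficient Wald
#'   p-values, log-likelihood, `n`, `k`, `bic`, `converged`.
#' @export
fit_logistic <- function(spec, m, genotypes = NULL, labels,
                         min_events = 10) {
  ids <- intersect(names(labels), colnames(m))
  if (length(spec$snp_ids)) ids <- intersect(ids, colnames(genotypes))
  y <- labels[ids]
  if (min(table(factor(y, levels = 0:1))) < min_events)
    stop(sprintf("fewer than %d samples in a class", min_events))
  X <- spec_design(spec, m, genotypes, ids)
  fit <- logistic_ml(X, y)
  structure(list(spec = spec, coefficients = fit$coefficients,
                 se = fit$se, p_values = fit$p_values,
                 loglik = fit$loglik, n = fit$n, k = fit$k,
                 bic = bic(fit$loglik, fit$k, fit$n),
                 converged = fit$converged, separated = fit$separated,
                 dropped = fit$dropped),
            class = "fitted_model")
}

#' Bayesian Information Criterion
#'
#' `BIC = k * log(n) - 2 * lnL`; lower values indicate a better fit after
#' the parsimony penalty.
#'
#' @param lnL maximized log-likelihood (<= 0 for discrete outcomes).
#' @param k number of free parameters.
#' @param n sample size (>= 1).
#' @export
bic <- function(lnL, k, n) {
  if (length(n) != 1 || n < 1) stop("'n' must be a positive sample count")
  k * log(n) - 2 * lnL
}

#' Select the best candidate fit and prune to significant predictors
#'
#' Picks the converged fit with minimal BIC (ties broken by fewer
#' predictors, then lexicographic CpG ids), then backward-eliminates: while
#' any predictor's Wald p-value exceeds `prune_alpha`, the worst one is
#' dropped and the model refitted. The surviving model is packaged as a
#' deployable signature with the training-set mean and SD of its raw linear
#' score, so downstream reporting can be per standard deviation.
#'
#' @param fits list of `fitted_model` objects from [fit_logistic()].
#' @param m,genotypes,labels the training data the fits were computed on.
#' @param prune_alpha significance level for backward elimination.
#' @param trait label stored on the signature.
#' @param provenance optional list (seed, n_models, ...) recorded verbatim.
#' @return a `signature_model`: trait, CpG/SNP coefficients, intercept,
#'   standardization constants `mu` and `sigma`, provenance.
#' @export
select_and_prune <- function(fits, m, genotypes = NULL, labels,
                             prune_alpha = 0.05, trait = "smoking",
                             provenance = list()) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) stop("no converged candidate fit")
  bics <- vapply(conv, `[[`, numeric(1), "bic")
  npred <- vapply(conv, function(f) length(f$coefficients) - 1L, integer(1))
  keys <- vapply(conv, function(f) paste(f$spec$cpg_ids, collapse = "|"),
                 character(1))
  best <- conv[[order(bics, npred, keys)[1]]]

  fit <- best
  spec <- best$spec
  repeat {
    p <- fit$p_values[-1]                       # never prune the intercept
    if (length(p) == 0) stop("no significant predictors")
    if (max(p) <= prune_alpha) break
    worst <- names(p)[which.max(p)]
    spec <- list(cpg_ids = setdiff(spec$cpg_ids, worst),
                 snp_ids = setdiff(spec$snp_ids, worst))
    if (length(spec$cpg_ids) + length(spec$snp_ids) == 0)
      stop("no significant predictors")
    fit <- fit_logistic(spec, m, genotypes, labels)
  }

  coefs <- fit$coefficients
  ids <- intersect(names(labels), colnames(m))
  if (length(spec$snp_ids)) ids <- intersect(ids, colnames(genotypes))
  X <- spec_design(spec, m, genotypes, ids)
  raw <- drop(coefs[1] + X %*% coefs[-1])
  mu <- mean(raw); sigma <- stats::sd(raw)
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate signature: raw training scores have zero variance")

  cpg_coef <- coefs[intersect(names(coefs), spec$cpg_ids)]
  snp_coef <- coefs[intersect(names(coefs), spec$snp_ids)]
  structure(list(
    trait = trait,
    cpgs = data.frame(id = names(cpg_coef), coef = unname(cpg_coef),
                      stringsAsFactors = FALSE),
    snps = data.frame(id = names(snp_coef), coef = unname(snp_coef),
                      stringsAsFactors = FALSE),
    intercept = unname(coefs[1]),
    mu = mu, sigma = sigma,
    selection_bic = best$bic,
    provenance = utils::modifyList(list(prune_alpha = prune_alpha,
                                        n_candidates = length(fits),
                                        n_converged = length(conv)),
                                   provenance)),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("polyepigenetic signature [%s]: %d CpG(s), %d SNP(s)\n",
              x$trait, nrow(x$cpgs), nrow(x$snps)))
  cat(sprintf("  intercept %.4f, score mu %.4f sigma %.4f\n",
              x$intercept, x$mu, x$sigma))
  for (i in seq_len(nrow(x$cpgs)))
    cat(sprintf("  %s  %+.4f\n", x$cpgs$id[i], x$cpgs$coef[i]))
  for (i in seq_len(nrow(x$snps)))
    cat(sprintf("  %s  %+.4f\n", x$snps$id[i], x$snps$coef[i]))
  invisible(x)
}

#' Run the full randomized signature search
#'
#' Convenience wrapper chaining [code_outcome()], [enumerate_random_specs()],
#' [fit_logistic()] on every spec and [select_and_prune()].
#'
#' @param m mvalue-scale training [meth_matrix()].
#' @param genotypes dosage matrix (or `NULL`).
#' @param cohort cohort phenotype data.frame.
#' @param trait `"smoking"` or `"alcohol"`.
#' @param pool_cpgs candidate pool CpG ids.
#' @param mqtl `mqtl_map` pairing CpGs to SNPs (or `NULL`).
#' @param n_models number of random specifications (default 10000).
#' @param max_cpgs CpGs per specification.
#' @param prune_alpha backward-elimination level.
#' @param seed integer seed for the spec draw.
#' @return a `signature_model`.
#' @export
build_signature <- function(m, genotypes = NULL, cohort,
                            trait = c("smoking", "alcohol"),
                            pool_cpgs, mqtl = NULL,
                            n_models = 10000, max_cpgs = 7,
                            prune_alpha = 0.05, seed = 1L) {
  trait <- match.arg(trait)
  outcome <- code_outcome(cohort, trait)
  specs <- enumerate_random_specs(pool_cpgs, mqtl, n_models,
                                  max_cpgs = max_cpgs, seed = seed)
  fits <- lapply(specs, function(sp)
    suppressWarnings(fit_logistic(sp, m, genotypes, outcome$labels)))
  select_and_prune(fits, m, genotypes, outcome$labels,
                   prune_alpha = prune_alpha, trait = trait,
                   provenance = list(seed = seed, n_models = n_models,
                                     max_cpgs = max_cpgs))
}

#' Score samples with a fitted signature
#'
#' Raw score `S = b0 + sum_j b_j * M_j` (plus any SNP terms), and the
#' standardized score `z = (S - mu) / sigma` using the training-set
#' constants stored on the model, so a one-unit increase in `z` is one
#' training-set standard deviation.
#'
#' @param model a `signature_model`.
#' @param m mvalue-scale [meth_matrix()] holding every model CpG.
#' @param genotypes dosage matrix, required when the model contains SNPs.
#' @return data.frame with `sample_id`, `raw`, `standardized`.
#' @export
score_samples <- function(model, m, genotypes = NULL) {
  stopifnot(inherits(model, "signature_model"), inherits(m, "meth_matrix"))
  if (meth_scale(m) != "mvalue")
    stop("scoring expects M-values; run beta_to_mvalue() first")
  miss <- setdiff(model$cpgs$id, rownames(m))
  if (length(miss))
    stop("model CpG(s) absent from matrix: ", paste(miss, collapse = ", "))
  if (anyNA(unclass(m)[model$cpgs$id, , drop = FALSE]))
    stop("missing values at model CpGs; impute upstream")
  raw <- model$intercept +
    drop(crossprod(unclass(m)[model$cpgs$id, , drop = FALSE],
                   model$cpgs$coef))
  if (nrow(model$snps) > 0) {
    if (is.null(genotypes)) stop("model contains SNPs; supply genotypes")
    miss <- setdiff(model$snps$id, rownames(genotypes))
    if (length(miss))
      stop("model SNP(s) absent: ", paste(miss, collapse = ", "))
    raw <- raw + drop(crossprod(genotypes[model$snps$id, colnames(m),
                                          drop = FALSE], model$snps$coef))
  }
  data.frame(sample_id = colnames(m), raw = unname(raw),
             standardized = unname((raw - model$mu) / model$sigma),
             stringsAsFactors = FALSE)
}

#' Serialize and restore a signature model as JSON
#'
#' Schema: `{trait, cpgs:[{id, coef}], snps:[{id, coef}], intercept, mu,
#' sigma, provenance}`.
#'
#' @param model a `signature_model`.
#' @param path JSON path.
#' @export
write_signature <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$cpgs <- as.data.frame(obj$cpgs, stringsAsFactors = FALSE)
  if (is.null(obj$snps) || length(obj$snps) == 0)
    obj$snps <- data.frame(id = character(0), coef = numeric(0))
  else obj$snps <- as.data.frame(obj$snps, stringsAsFactors = FALSE)
  structure(obj, class = "signature_model")
}
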