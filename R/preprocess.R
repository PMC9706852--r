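#' Sample-level call-rate quality control
#'
#' Excludes samples whose call rate — the fraction of non-missing probes —
#' falls below `threshold`. The conventional array QC cut-off of 95% is the
#' default; samples at exactly the threshold are retained.
#'
#' @param m a beta-scale [meth_matrix()].
#' @param threshold call-rate cut-off in (0, 1].
#' @return list with `matrix` (failing samples dropped) and `report`, a
#'   `qc_report` holding per-sample call rates, the excluded sample ids and
#'   the threshold applied.
#' @export
qc_call_rate <- function(m, threshold = 0.95) {
  stopifnot(inherits(m, "meth_matrix"))
  if (meth_scale(m) != "beta") stop("call-rate QC expects a beta-scale matrix")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  call_rate <- colMeans(!is.na(m))
  excluded <- colnames(m)[call_rate < threshold]
  kept <- m[, setdiff(colnames(m), excluded), drop = FALSE]
  report <- structure(
    list(call_rate = call_rate, excluded = excluded, threshold = threshold),
    class = "qc_report")
  list(matrix = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("call-rate QC: %d/%d samples excluded (threshold %.3f)\n",
              length(x$excluded), length(x$call_rate), x$threshold))
  invisible(x)
}

#' Restrict two matrices to their common probe set
#'
#' Mirrors the harmonization step for cohorts typed on different array
#' generations: both matrices are restricted to the sorted intersection of
#' their CpG identifiers, in identical row order, and tagged `intersected`.
#'
#' @param a,b beta-scale [meth_matrix()] objects.
#' @return list of the two restricted matrices, names `a` and `b`.
#' @export
intersect_arrays <- function(a, b) {
  stopifnot(inherits(a, "meth_matrix"), inherits(b, "meth_matrix"))
  if (meth_scale(a) != "beta" || meth_scale(b) != "beta")
    stop("array intersection expects beta-scale matrices")
  common <- sort(intersect(rownames(a), rownames(b)))
  if (length(common) == 0) stop("no CpGs shared between the two arrays")
  list(a = set_meth_attrs(a[common, , drop = FALSE], dialect = "intersected"),
       b = set_meth_attrs(b[common, , drop = FALSE], dialect = "intersected"))
}

#' Nearest-average imputation of missing probe values
#'
#' Each missing entry is replaced by the mean of that sample's values over
#' the `k` nearest neighbour CpG rows. Proximity between two rows is the
#' root-mean-square difference over the samples where both are observed
#' (a per-column-normalized Euclidean distance, so rows with different
#' missingness patterns are comparable); for a given missing entry only
#' neighbour rows observed at that sample are eligible. Observed entries are
#' never altered; this is a single deterministic completion.
#'
#' @param m a [meth_matrix()] with possible `NA` entries.
#' @param k number of neighbour rows to average (default 10).
#' @return completed `meth_matrix` with no missing entries.
#' @export
impute_nearest_average <- function(m, k = 10) {
  stopifnot(inherits(m, "meth_matrix"), k >= 1)
  vals <- unclass(m)
  has_na <- rowSums(is.na(vals)) > 0
  if (!any(has_na)) return(m)
  all_na <- rowSums(!is.na(vals)) == 0
  if (any(all_na))
    stop("probe(s) missing in all samples: ",
         paste(rownames(vals)[all_na], collapse = ", "))
  orig <- vals                       # neighbours come from the input only
  obs_mat <- !is.na(orig)
  for (i in which(has_na)) {
    row <- orig[i, ]
    obs <- obs_mat[i, ]
    diffs <- sweep(orig[, obs, drop = FALSE], 2, row[obs])
    overlap <- rowSums(obs_mat[, obs, drop = FALSE])
    d <- sqrt(rowSums(diffs^2, na.rm = TRUE) / pmax(overlap, 1))
    d[i] <- Inf
    d[overlap == 0] <- Inf
    for (s in which(!obs)) {
      elig <- which(is.finite(d) & obs_mat[, s])
      if (length(elig) == 0)
        stop(sprintf("no neighbour observed at sample %s for probe %s",
                     colnames(vals)[s], rownames(vals)[i]))
      nn <- elig[order(d[elig])][seq_len(min(k, length(elig)))]
      vals[i, s] <- mean(orig[nn, s])
    }
  }
  set_meth_attrs(structure(vals, class = class(m)))
}

#' Logit transform beta values to M-values
#'
#' M = log(beta / (1 - beta)), in natural log by default or base 2 (the usual
#' "M-value" convention). Beta values at or beyond machine 0/1 are clipped to
#' `[eps, 1 - eps]` first when `clip = TRUE`; with clipping disabled, exact 0
#' or 1 is an error since the transform diverges there.
#'
#' @param m beta-scale [meth_matrix()], no missing entries.
#' @param log_base `"e"` or `"2"`.
#' @param clip clip degenerate values before transforming?
#' @param eps clipping bound.
#' @return an mvalue-scale `meth_matrix`.
#' @export
beta_to_mvalue <- function(m, log_base = c("e", "2"), clip = TRUE,
                           eps = 1e-6) {
  log_base <- match.arg(log_base)
  stopifnot(inherits(m, "meth_matrix"))
  if (meth_scale(m) != "beta") stop("input is not on the beta scale")
  vals <- unclass(m)
  if (anyNA(vals)) stop("impute missing values before the logit transform")
  if (clip) {
    vals <- pmin(pmax(vals, eps), 1 - eps)
  } else if (any(vals <= 0 | vals >= 1)) {
    stop("beta values at 0 or 1 encountered with clipping disabled")
  }
  mv <- log(vals / (1 - vals))
  if (log_base == "2") mv <- mv / log(2)
  set_meth_attrs(structure(mv, class = class(m)), scale = "mvalue")
}

#' Inverse-logit back-transform of M-values
#'
#' @param m mvalue-scale [meth_matrix()].
#' @inheritParams beta_to_mvalue
#' @export
mvalue_to_beta <- function(m, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  stopifnot(inherits(m, "meth_matrix"))
  if (meth_scale(m) != "mvalue") stop("input is not on the mvalue scale")
  vals <- unclass(m)
  if (log_base == "2") vals <- vals * log(2)
  set_meth_attrs(structure(stats::plogis(vals), class = class(m)),
                 scale = "beta")
}

#' Normalization hook
#'
#' Placeholder for an external intensity-level normalization pipeline, which
#' operates upstream of this package on raw array data. Called on an
#' already-normalized beta matrix it passes the data through unchanged and
#' warns so the provenance is visible in logs.
#'
#' @param m a [meth_matrix()].
#' @export
normalize_hook <- function(m) {
  warning("normalization hook is a pass-through; supply normalized beta values",
          call. = FALSE)
  m
}
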