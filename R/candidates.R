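#' Read a candidate CpG table
#'
#' Candidate CpGs come from published epigenome-wide association results, one
#' row per CpG-trait pair with the source study's p-value and the number of
#' tests behind it. Columns: `cpg_id`, `trait` (`smoking`/`alcohol`),
#' `source_pvalue`, `source_n_tests`, optional `gene`, optional `snp_id`.
#'
#' @param path CSV path.
#' @return data.frame of candidate records.
#' @export
read_candidates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cpg_id", "trait", "source_pvalue", "source_n_tests")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("candidate table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Bonferroni retention of candidate CpGs
#'
#' Keeps records whose source p-value clears the Bonferroni level of the
#' study it came from: `source_pvalue < alpha / source_n_tests`. Input order
#' is preserved.
#'
#' @param records candidate data.frame (see [read_candidates()]).
#' @param alpha family-wise error level.
#' @return the retained subset of `records`.
#' @export
filter_bonferroni <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(records)
  bad <- is.na(records$source_n_tests) | is.null(records$source_n_tests)
  if (any(bad))
    stop("source_n_tests missing for record(s): ",
         paste(records$cpg_id[bad], collapse = ", "))
  keep <- records$source_pvalue < alpha / records$source_n_tests
  records[keep, , drop = FALSE]
}

#' Screen CpG-SNP pairs for methylation QTLs
#'
#' For each candidate pair, regresses the CpG's M-values on additive SNP
#' dosage (0/1/2) by ordinary least squares over the samples shared between
#' the two matrices. A pair enters the map when the slope's p-value clears
#' the screening threshold — `alpha / n_pairs` under the default Bonferroni
#' correction. When several SNPs pass for one CpG, the strongest (smallest
#' p-value, ties broken by lexicographic SNP id) is kept. Monomorphic SNPs
#' are skipped with a warning.
#'
#' @param m an mvalue-scale [meth_matrix()].
#' @param genotypes dosage matrix, SNPs as rows, samples as columns.
#' @param pairs data.frame with columns `cpg_id`, `snp_id`.
#' @param alpha screening level.
#' @param bonferroni divide `alpha` by the number of tested pairs?
#' @return an `mqtl_map` data.frame: `cpg_id`, `snp_id`, `effect` (per-allele
#'   slope on the M-value scale), `p_value`.
#' @export
screen_mqtl <- function(m, genotypes, pairs, alpha = 0.05, bonferroni = TRUE) {
  stopifnot(inherits(m, "meth_matrix"), is.matrix(genotypes),
            is.data.frame(pairs), all(c("cpg_id", "snp_id") %in% names(pairs)))
  if (meth_scale(m) != "mvalue")
    stop("mQTL screening expects M-values; run beta_to_mvalue() first")
  shared <- intersect(colnames(m), colnames(genotypes))
  if (length(shared) == 0) stop("no shared samples between matrices")
  if (length(shared) < 10)
    stop("need at least 10 shared samples for the mQTL screen")
  dvals <- genotypes[, shared, drop = FALSE]
  if (!all(dvals %in% 0:2)) stop("genotype dosages must be 0, 1 or 2")
  mvals <- unclass(m)[, shared, drop = FALSE]

  threshold <- if (bonferroni) alpha / nrow(pairs) else alpha
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cpg <- pairs$cpg_id[i]; snp <- pairs$snp_id[i]
    if (!cpg %in% rownames(mvals) || !snp %in% rownames(dvals)) next
    x <- dvals[snp, ]; y <- mvals[cpg, ]
    if (stats::sd(x) == 0) {
      warning(sprintf("SNP %s is monomorphic in shared samples; pair skipped",
                      snp), call. = FALSE)
      next
    }
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    p <- 2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
    if (p < threshold)
      res[[i]] <- data.frame(cpg_id = cpg, snp_id = snp, effect = slope,
                             p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cpg_id = character(0), snp_id = character(0),
                      effect = numeric(0), p_value = numeric(0))
  # strongest SNP per CpG: smallest p, then lexicographic snp_id
  out <- out[order(out$cpg_id, out$p_value, out$snp_id), , drop = FALSE]
  out <- out[!duplicated(out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mqtl_map", "data.frame")
  out
}

#' Serialize and restore an mQTL map
#'
#' @param map an `mqtl_map` from [screen_mqtl()].
#' @param path JSON path.
#' @export
write_mqtl_map <- function(map, path) {
  jsonlite::write_json(as.data.frame(map), path, digits = NA)
  invisible(path)
}

#' @rdname write_mqtl_map
#' @export
read_mqtl_map <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  class(out) <- c("mqtl_map", "data.frame")
  out
}
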