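#' Methylation matrix container
#'
#' A numeric matrix of methylation values with CpGs as rows and samples as
#' columns, tagged with the measurement scale (`"beta"` for proportions in
#' \[0,1\], `"mvalue"` for logit-transformed values) and the array dialect the
#' probe set comes from (`"HM450K"`, `"EPIC"`, or `"intersected"` after probe
#' harmonization). Missing calls are `NA`.
#'
#' @param values numeric matrix with unique CpG rownames (`cgXXXXXXXX`) and
#'   unique sample colnames.
#' @param scale `"beta"` or `"mvalue"`.
#' @param dialect probe-set dialect label.
#' @return an object of class `meth_matrix`.
#' @export
meth_matrix <- function(values, scale = c("beta", "mvalue"),
                        dialect = c("HM450K", "EPIC", "intersected")) {
  scale <- match.arg(scale)
  dialect <- match.arg(dialect)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry CpG rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate CpG identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (scale == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("beta-scale values must lie in [0, 1]")
  }
  structure(values, class = c("meth_matrix", "matrix", "array"),
            scale = scale, dialect = dialect)
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpGs x %d samples [%s scale, %s dialect, %.1f%% missing]\n",
              nrow(x), ncol(x), attr(x, "scale"), attr(x, "dialect"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.meth_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, class = class(x),
                     scale = attr(x, "scale"), dialect = attr(x, "dialect"))
  out
}

#' @rdname meth_matrix
#' @param x a `meth_matrix`.
#' @export
meth_scale <- function(x) attr(x, "scale")

#' @rdname meth_matrix
#' @export
meth_dialect <- function(x) attr(x, "dialect")

# internal: swap scale/dialect tags without re-validating values
set_meth_attrs <- function(x, scale = attr(x, "scale"),
                           dialect = attr(x, "dialect")) {
  structure(unclass(x), class = c("meth_matrix", "matrix", "array"),
            scale = scale, dialect = dialect)
}

#' Read and write methylation matrices as CSV
#'
#' Plain-text interchange format: one header row of sample identifiers, one
#' row per CpG with the CpG identifier in the first column. Empty cells are
#' missing calls.
#'
#' @param path file path.
#' @param scale,dialect tags for the matrix read (see [meth_matrix()]).
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return [read_meth_matrix()] returns a `meth_matrix`;
#'   [write_meth_matrix()] returns `path` invisibly.
#' @export
read_meth_matrix <- function(path, scale = "beta", dialect = "HM450K",
                             sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, na.strings = c("", "NA"))
  meth_matrix(as.matrix(df), scale = scale, dialect = dialect)
}

#' @rdname read_meth_matrix
#' @param x a `meth_matrix` to write.
#' @export
write_meth_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "meth_matrix"))
  df <- data.frame(cpg_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a GEO series-matrix-style methylation table
#'
#' Tab-delimited export where metadata lines begin with `"!"`; the remaining
#' block is a probe-by-sample table with a header row.
#'
#' @inheritParams read_meth_matrix
#' @export
read_geo_series_matrix <- function(path, scale = "beta", dialect = "HM450K") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE,
                          na.strings = c("", "NA", "null"))
  meth_matrix(as.matrix(df), scale = scale, dialect = dialect)
}
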