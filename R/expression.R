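#' Two-condition expression matrix
#'
#' Container for probe- or gene-level intensities measured in two labeled
#' sample groups (hypoxia vs. normoxia). All normalization, clustering and
#' differential-expression stages operate on this object.
#'
#' @param values numeric matrix, features in rows (rownames = probe or gene
#'   identifiers), samples in columns (colnames = sample identifiers).
#' @param condition character or factor vector naming the condition of each
#'   column; must contain exactly two levels and cover every sample. If the
#'   vector is named, names are matched against `colnames(values)`.
#' @param scale `"log2"` if `values` are already log2-transformed,
#'   `"raw"` for non-negative raw-scale intensities.
#'
#' @return An object of class `expr_mat`: a list with elements `values`,
#'   `condition` (named factor) and `scale`.
#' @export
expression_matrix <- function(values, condition, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite (no NA/NaN/Inf)")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale intensities must be non-negative")
  if (length(condition) != ncol(values))
    stop("`condition` must label every sample: expected ",
         ncol(values), " labels, got ", length(condition))
  if (!is.null(names(condition))) {
    if (!setequal(names(condition), colnames(values)))
      stop("names of `condition` do not match sample ids")
    condition <- condition[colnames(values)]
  }
  condition <- factor(as.character(condition))
  if (nlevels(condition) != 2L)
    stop("`condition` must have exactly two levels; got ",
         nlevels(condition), " (", paste(levels(condition), collapse = ", "), ")")
  names(condition) <- colnames(values)
  structure(list(values = values, condition = condition, scale = scale),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("expr_mat: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Log2-transform a raw-scale expression matrix
#'
#' Applied before clustering and differential expression when the input is
#' flagged as raw intensities. Log2-scale input is returned unchanged.
#'
#' @param m an [expression_matrix()].
#' @param offset constant added before taking logs, to guard against zeros.
#' @return an `expr_mat` on the log2 scale.
#' @export
log2_transform <- function(m, offset = 0) {
  stopifnot(inherits(m, "expr_mat"))
  if (m$scale == "log2") return(m)
  v <- m$values + offset
  if (any(v <= 0))
    stop("raw intensities must be positive after adding `offset`")
  expression_matrix(log2(v), m$condition, scale = "log2")
}

# group sizes / indices, used across the DE stage
.group_split <- function(m) {
  lev <- levels(m$condition)
  list(a = which(m$condition == lev[1L]),
       b = which(m$condition == lev[2L]),
       levels = lev)
}

#' Read / write the tab-separated expression exchange format
#'
#' The on-disk format is plain text: an intensity table whose first column
#' holds feature identifiers and whose header row holds sample identifiers,
#' plus a two-column sidecar file mapping sample id to condition label.
#'
#' @param m an [expression_matrix()].
#' @param values_file path of the intensity table.
#' @param condition_file path of the sample-to-condition sidecar.
#' @param scale scale flag recorded when reading (`"log2"` or `"raw"`).
#' @return `read_expression` returns an `expr_mat`; `write_expression`
#'   returns the input invisibly.
#' @export
write_expression <- function(m, values_file, condition_file) {
  stopifnot(inherits(m, "expr_mat"))
  df <- data.frame(feature = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, values_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(m$condition),
               condition = as.character(m$condition)),
    condition_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @rdname write_expression
#' @export
read_expression <- function(values_file, condition_file,
                            scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(values_file, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1L]]
  cond <- utils::read.delim(condition_file)
  condition <- stats::setNames(as.character(cond$condition), cond$sample)
  expression_matrix(v, condition, scale = scale)
}
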