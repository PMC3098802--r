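#' Quantile normalization of an expression matrix
#'
#' Forces every sample column to share one empirical distribution: after
#' normalization, the sorted values of each column equal the across-column
#' mean of order statistics. Tied raw values receive the mean of their
#' target quantiles. Row and column labels, the condition map and the scale
#' flag are preserved; within-column rank order is preserved by
#' construction.
#'
#' @param m an [expression_matrix()] with at least two samples.
#' @return The normalized `expr_mat`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  if (ncol(m$values) < 2L)
    stop("quantile normalization needs >= 2 samples")
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  expression_matrix(v, m$condition, scale = m$scale)
}

#' Collapse probe-level rows to gene level
#'
#' Multiple probes mapping to the same gene are combined per sample by a
#' summary rule (default: median). Probes without a gene annotation are
#' dropped and counted.
#'
#' @param m a probe-level [expression_matrix()].
#' @param annot data frame with columns `probe` and `gene`; every retained
#'   probe must map to exactly one gene.
#' @param method collapsing rule, `"median"` or `"mean"`, applied per
#'   sample across a gene's probes.
#' @return A gene-level `expr_mat` (rows ordered by gene identifier) with
#'   attribute `n_dropped`, the count of probes lacking an annotation.
#' @export
collapse_probes <- function(m, annot, method = c("median", "mean")) {
  stopifnot(inherits(m, "expr_mat"))
  method <- match.arg(method)
  if (!all(c("probe", "gene") %in% names(annot)))
    stop("`annot` must have columns `probe` and `gene`")
  if (anyDuplicated(annot$probe))
    stop("`annot` maps some probe to more than one gene")

  map <- stats::setNames(as.character(annot$gene), as.character(annot$probe))
  probes <- rownames(m$values)
  mapped <- probes %in% names(map)
  n_dropped <- sum(!mapped)
  if (!any(mapped))
    stop("no probe in the matrix is covered by the annotation")
  if (n_dropped > 0)
    message(n_dropped, " probe(s) without gene annotation dropped")

  v <- m$values[mapped, , drop = FALSE]
  gene <- map[rownames(v)]
  idx <- split(seq_len(nrow(v)), gene)   # alphabetical gene order
  fun <- if (method == "median") stats::median else mean
  out <- matrix(NA_real_, length(idx), ncol(v),
                dimnames = list(names(idx), colnames(v)))
  single <- lengths(idx) == 1L
  if (any(single))
    out[single, ] <- v[unlist(idx[single], use.names = FALSE), , drop = FALSE]
  for (g in which(!single))
    out[g, ] <- apply(v[idx[[g]], , drop = FALSE], 2L, fun)

  res <- expression_matrix(out, m$condition, scale = m$scale)
  attr(res, "n_dropped") <- n_dropped
  res
}

# Pearson correlation distance matrix between rows of `x`
.cor_dist <- function(x) stats::as.dist(1 - stats::cor(t(x)))

#' Two-dimensional hierarchical clustering on Pearson correlation distance
#'
#' Agglomerative clustering with distance d = 1 - Pearson r, applied
#' independently to rows (features) and columns (samples) of the
#' normalized matrix. Rows with zero variance are excluded (correlation
#' distance is undefined for them) and reported; they remain eligible for
#' the differential-expression stage, which does not use correlations.
#'
#' @param m an [expression_matrix()] with at least 2 rows and 2 columns.
#' @param linkage agglomeration rule passed to [stats::hclust()];
#'   average linkage by default, the standard choice for expression
#'   heatmaps.
#' @return A `cluster_result`: list with `row_tree` and `col_tree`
#'   ([stats::hclust] objects), `row_order` / `col_order` (leaf
#'   permutations, indices into the retained rows / columns), `row_labels`
#'   (retained row names) and `dropped_rows` (zero-variance row names).
#' @export
hierarchical_cluster <- function(m, linkage = "average") {
  stopifnot(inherits(m, "expr_mat"))
  v <- m$values
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("clustering needs >= 2 rows and >= 2 columns")
  rv <- apply(v, 1L, stats::var)
  dropped <- rownames(v)[rv == 0]
  v <- v[rv > 0, , drop = FALSE]
  if (nrow(v) < 2L)
    stop("fewer than 2 rows with non-zero variance: ",
         "correlation distance is undefined")
  if (length(dropped) > 0)
    message(length(dropped), " zero-variance row(s) excluded from clustering")

  row_tree <- stats::hclust(.cor_dist(v), method = linkage)
  col_tree <- stats::hclust(.cor_dist(t(v)), method = linkage)
  structure(list(row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order, col_order = col_tree$order,
                 row_labels = rownames(v), col_labels = colnames(v),
                 dropped_rows = dropped),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d rows x %d columns clustered (%s linkage)\n",
              length(x$row_order), length(x$col_order), x$row_tree$method))
  if (length(x$dropped_rows) > 0)
    cat(sprintf("  %d zero-variance row(s) excluded\n", length(x$dropped_rows)))
  invisible(x)
}

#' Write a clustering result as leaf orders plus Newick trees
#'
#' @param cr a `cluster_result`.
#' @param prefix path prefix; writes `<prefix>_row_order.txt`,
#'   `<prefix>_col_order.txt`, `<prefix>_row_tree.nwk`,
#'   `<prefix>_col_tree.nwk`.
#' @return the file paths, invisibly.
#' @export
write_cluster_result <- function(cr, prefix) {
  stopifnot(inherits(cr, "cluster_result"))
  paths <- c(row_order = paste0(prefix, "_row_order.txt"),
             col_order = paste0(prefix, "_col_order.txt"),
             row_tree = paste0(prefix, "_row_tree.nwk"),
             col_tree = paste0(prefix, "_col_tree.nwk"))
  writeLines(cr$row_labels[cr$row_order], paths["row_order"])
  writeLines(cr$col_labels[cr$col_order], paths["col_order"])
  ape::write.tree(ape::as.phylo(cr$row_tree), paths["row_tree"])
  ape::write.tree(ape::as.phylo(cr$col_tree), paths["col_tree"])
  invisible(paths)
}
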