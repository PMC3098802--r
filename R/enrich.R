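#' Gene-set collection
#'
#' A named list of gene sets together with the gene universe they are
#' evaluated against (by default, all genes present on the array after
#' probe collapsing). Members outside the universe are filtered out;
#' terms left empty by filtering are dropped.
#'
#' @param terms named list of character vectors (member genes per term).
#' @param description named character vector of term descriptions
#'   (optional; defaults to empty strings).
#' @param universe character vector of gene identifiers.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, description = NULL, universe) {
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop("`terms` must be a uniquely named list")
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(as.character(universe))
  terms <- lapply(terms, function(g) intersect(unique(g), universe))
  keep <- lengths(terms) > 0
  if (!all(keep)) {
    message(sum(!keep), " term(s) empty after universe filtering dropped")
    terms <- terms[keep]
  }
  if (is.null(description))
    description <- stats::setNames(rep("", length(terms)), names(terms))
  structure(list(terms = terms,
                 description = description[names(terms)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms over %d genes (sizes %d-%d)\n",
              length(x$terms), length(x$universe),
              min(lengths(x$terms)), max(lengths(x$terms))))
  invisible(x)
}

#' Read and write gene sets in GMT format
#'
#' GMT is tab-separated text, one gene set per line: term id, description,
#' then member genes.
#'
#' @param path file path.
#' @param universe gene universe for [gene_set_collection()]; default: the
#'   union of all members in the file.
#' @return `read_gmt` returns a `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT: line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[`, "", 1L)
  desc <- stats::setNames(vapply(parts, `[`, "", 2L), ids)
  terms <- stats::setNames(lapply(parts, function(x) x[-(1:2)]), ids)
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  gene_set_collection(terms, desc, universe)
}

#' @rdname read_gmt
#' @param gsc a `gene_set_collection`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$terms), function(id) {
    paste(c(id, gsc$description[[id]], gsc$terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(gsc)
}

# upper-tail hypergeometric probability P(X >= x), vectorized over x;
# K = term size, n = DE-list size, N = universe size
.hyper_upper <- function(x, K, n, N) {
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided gene-set enrichment test
#'
#' Probability of observing at least the attained overlap between a
#' differentially expressed gene list and a term, under hypergeometric
#' sampling from the universe. The `"ease"` variant (the conservative
#' score used by the DAVID annotation tool) removes one overlapping gene
#' before computing the tail, penalizing single-gene overlaps.
#'
#' @param de character vector of differentially expressed genes.
#' @param term character vector of term member genes.
#' @param universe gene universe; `de` and `term` are intersected with it.
#' @param variant `"hypergeometric"` or `"ease"`.
#' @return One-sided enrichment p-value in (0, 1].
#' @export
enrichment_test <- function(de, term, universe,
                            variant = c("ease", "hypergeometric")) {
  variant <- match.arg(variant)
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  de <- intersect(de, universe)
  term <- intersect(term, universe)
  x <- length(intersect(de, term))
  if (variant == "ease") x <- max(x - 1L, 0L)
  .hyper_upper(x, length(term), length(de), length(universe))
}

#' Test every term of a collection against a DE gene list
#'
#' @param de character vector of differentially expressed genes.
#' @param gsc a [gene_set_collection()].
#' @param variant enrichment statistic, as in [enrichment_test()].
#' @return A data frame of class `enrichment_result` with columns
#'   `term_id`, `n_overlap`, `n_term`, `n_de`, `n_universe` and `p`,
#'   one row per term, in collection order.
#' @export
enrich_collection <- function(de, gsc, variant = c("ease", "hypergeometric")) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  variant <- match.arg(variant)
  de <- intersect(unique(de), gsc$universe)
  ov <- vapply(gsc$terms, function(g) length(intersect(de, g)), 0L)
  x <- if (variant == "ease") pmax(ov - 1L, 0L) else ov
  p <- .hyper_upper(x, lengths(gsc$terms), length(de), length(gsc$universe))
  structure(data.frame(term_id = names(gsc$terms), n_overlap = ov,
                       n_term = unname(lengths(gsc$terms)),
                       n_de = length(de), n_universe = length(gsc$universe),
                       p = unname(p), row.names = NULL),
            class = c("enrichment_result", "data.frame"), variant = variant)
}

#' Permutation-based false discovery rate for enrichment results
#'
#' For each of `n_perm` permutations a random gene list of the observed
#' size is drawn from the universe and all term p-values are recomputed
#' with the same statistic. The FDR at a threshold t is the mean
#' permutation count of p-values at or below t divided by the observed
#' count (floored at 1); each term receives the FDR at its own p-value,
#' capped at 1 and made monotone non-decreasing in p.
#'
#' @param de_size size of the differentially expressed list.
#' @param gsc the [gene_set_collection()] the observed p-values came from.
#' @param observed_p per-term p-values, in collection order (e.g. the `p`
#'   column of [enrich_collection()]).
#' @param n_perm number of permutations (>= 100; resolution is 1/n_perm).
#' @param seed integer RNG seed (required: permutation analyses must be
#'   reproducible).
#' @param variant enrichment statistic; use the one that produced
#'   `observed_p`.
#' @return Numeric vector of per-term FDR estimates, in input order.
#' @export
permutation_fdr <- function(de_size, gsc, observed_p, n_perm = 1000, seed,
                            variant = c("ease", "hypergeometric")) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  variant <- match.arg(variant)
  if (n_perm < 100)
    stop("n_perm must be >= 100 (FDR resolution is 1/n_perm)")
  if (missing(seed)) stop("`seed` is required")
  if (length(observed_p) != length(gsc$terms))
    stop("observed_p must have one value per term")
  set.seed(as.integer(seed))

  N <- length(gsc$universe)
  K <- lengths(gsc$terms)
  n_terms <- length(K)
  # membership matrix: genes x terms
  M <- matrix(0, N, n_terms,
              dimnames = list(gsc$universe, names(gsc$terms)))
  for (j in seq_len(n_terms)) M[gsc$terms[[j]], j] <- 1

  # permutation p-values in blocks, via one matrix product per block
  block <- max(1L, min(n_perm, floor(5e6 / N)))
  perm_p <- numeric(0)
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    Z <- matrix(0, N, b)
    for (j in seq_len(b)) Z[sample.int(N, de_size), j] <- 1
    ov <- crossprod(M, Z)                        # n_terms x b overlaps
    x <- if (variant == "ease") pmax(ov - 1, 0) else ov
    perm_p <- c(perm_p, .hyper_upper(x, K, de_size, N))  # K recycles by row
    done <- done + b
  }

  # FDR at each observed p: E[#perm p <= t] / max(1, #obs p <= t)
  sp <- sort(perm_p)
  so <- sort(observed_p)
  v <- findInterval(so, sp) / n_perm            # mean null count at each t
  r <- pmax(1, findInterval(so, so))            # observed count at each t
  fdr_sorted <- pmin(v / r, 1)
  fdr_sorted <- rev(cummin(rev(fdr_sorted)))    # monotone in p
  fdr <- fdr_sorted[match(observed_p, so)]
  fdr
}

#' Filter enrichment results at a permutation-FDR cutoff
#'
#' @param res an `enrichment_result` data frame carrying a `fdr_perm`
#'   column (attach the output of [permutation_fdr()]).
#' @param fdr_cutoff retain terms with `fdr_perm` strictly below this.
#' @return The retained rows, sorted by p-value.
#' @export
filter_enriched <- function(res, fdr_cutoff = 0.05) {
  stopifnot(inherits(res, "data.frame"))
  if (is.null(res$fdr_perm))
    stop("`res` has no fdr_perm column; run permutation_fdr() first")
  out <- res[res$fdr_perm < fdr_cutoff, , drop = FALSE]
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write enrichment results as tab-separated text
#'
#' @param res an `enrichment_result`.
#' @param path output file.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
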