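# Independent oracles used across the suite. These are deliberately naive
# implementations (enumeration, adjacency matrices, step-by-step formulas)
# kept separate from the package code paths they check.

# toy expression matrix from a plain numeric matrix
toy_expr <- function(values, n_h = NULL, scale = "log2") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(n_h)) n_h <- ncol(values) %/% 2
  cond <- rep(c("hypoxia", "normoxia"),
              c(n_h, ncol(values) - n_h))
  expression_matrix(values, cond, scale = scale)
}

# exact upper-tail hypergeometric by enumeration of all DE-sized subsets
# of the universe; feasible for |universe| <= 30
enum_hyper_p <- function(n_universe, n_term, n_de, n_overlap) {
  subsets <- utils::combn(n_universe, n_de)
  term <- seq_len(n_term)               # wlog the first n_term genes
  hits <- apply(subsets, 2L, function(s) sum(s %in% term))
  mean(hits >= n_overlap)
}

# brute-force average-linkage agglomeration on a distance matrix,
# returning the merge heights in order; lowest-index pair wins ties
brute_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# adjacency-matrix reference for induced subgraphs, degrees and hubs
adj_oracle <- function(seeds, edges_from, edges_to, degree_threshold = 10) {
  seeds <- toupper(seeds)
  nodes_all <- sort(unique(c(toupper(edges_from), toupper(edges_to))))
  A <- matrix(0L, length(nodes_all), length(nodes_all),
              dimnames = list(nodes_all, nodes_all))
  for (i in seq_along(edges_from)) {
    a <- toupper(edges_from[i]); b <- toupper(edges_to[i])
    if (a != b) { A[a, b] <- 1L; A[b, a] <- 1L }
  }
  keep <- intersect(nodes_all, seeds)
  A <- A[keep, keep, drop = FALSE]
  deg <- rowSums(A)
  nodes <- names(deg)[deg > 0]
  A <- A[nodes, nodes, drop = FALSE]
  list(nodes = nodes,
       degree = rowSums(A),
       n_edges = sum(A) / 2,
       hubs = sort(names(which(rowSums(A) >= degree_threshold))))
}

# step-by-step regularized-t evaluation for one group layout, following
# the shrinkage formula directly with explicit loops
direct_regularized_t <- function(x_h, x_n, nu0, window) {
  st <- function(x) {
    n <- ncol(x)
    mu <- apply(x, 1, mean)
    s2 <- apply(x, 1, var)
    ord <- order(mu)
    m <- nrow(x); w <- min(window, m); h <- (w - 1) %/% 2
    bg <- numeric(m)
    for (i in seq_len(m)) {
      lo <- min(max(1, i - h), m - w + 1)
      bg[ord[i]] <- mean(s2[ord][lo:(lo + w - 1)])
    }
    vreg <- if (nu0 == 0) s2 else (nu0 * bg + (n - 1) * s2) / (nu0 + n - 2)
    list(n = n, mu = mu, vreg = vreg)
  }
  a <- st(x_h); b <- st(x_n)
  (a$mu - b$mu) / sqrt(a$vreg / a$n + b$vreg / b$n)
}
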