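# canonical undirected edge form: uppercase ids, lexicographic endpoint
# order, self-loops and duplicates removed
.canonical_edges <- function(from, to) {
  from <- toupper(trimws(as.character(from)))
  to <- toupper(trimws(as.character(to)))
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- a != b
  el <- unique(data.frame(from = a[keep], to = b[keep]))
  el <- el[order(el$from, el$to), , drop = FALSE]
  rownames(el) <- NULL
  el
}

#' Read and write undirected edge lists
#'
#' Two-column tab-separated text, one edge per line. On reading,
#' identifiers are uppercased, endpoints put in lexicographic order,
#' self-loops dropped and duplicate edges merged, so any directionality in
#' the source database is collapsed.
#'
#' @param path file path.
#' @param header does the file carry a header line?
#' @return `read_edge_list` returns an `edge_list` data frame with columns
#'   `from` and `to`.
#' @export
read_edge_list <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header,
                          col.names = c("from", "to"))
  el <- .canonical_edges(df$from, df$to)
  structure(el, class = c("edge_list", "data.frame"))
}

#' @rdname read_edge_list
#' @param el an `edge_list` data frame.
#' @export
write_edge_list <- function(el, path) {
  utils::write.table(el[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(el)
}

#' Build the direct-interaction network induced by DE genes
#'
#' Seeds the network with differentially expressed genes and connects any
#' two of them that share a documented direct interaction in the database.
#' By default the result is the strict induced subgraph on the seed set;
#' seeds that end up with no connection are excluded (and counted), so
#' every retained node has degree >= 1. With `expand_neighbors = TRUE`,
#' database edges with exactly one seed endpoint are also admitted,
#' bringing in first-neighbor connector nodes.
#'
#' Identifiers are matched case-insensitively after uppercasing.
#'
#' @param seeds character vector of differentially expressed genes, or a
#'   `de_result` with a `gene` column.
#' @param db an `edge_list` (see [read_edge_list()] /
#'   [generate_interaction_db()]).
#' @param de_table optional `de_result` used to attach per-node direction
#'   (`up` / `down`); nodes absent from it are labeled `"ns"`.
#' @param expand_neighbors admit first-neighbor non-seed nodes.
#' @return An `interactome`: list with `graph` (igraph object), `nodes`,
#'   `edges` (canonical `edge_list`), `degree` (named integer) and
#'   `de_status` (named character), plus attribute `n_isolated_seeds`.
#' @export
build_interactome <- function(seeds, db, de_table = NULL,
                              expand_neighbors = FALSE) {
  if (is.data.frame(seeds)) {
    if (is.null(de_table)) de_table <- seeds
    seeds <- seeds$gene
  }
  if (length(seeds) == 0) stop("empty seed set")
  seeds <- unique(toupper(trimws(as.character(seeds))))
  el <- .canonical_edges(db$from, db$to)

  in_seed_from <- el$from %in% seeds
  in_seed_to <- el$to %in% seeds
  keep <- if (expand_neighbors) in_seed_from | in_seed_to
          else in_seed_from & in_seed_to
  el <- el[keep, , drop = FALSE]
  rownames(el) <- NULL

  nodes <- sort(unique(c(el$from, el$to)))
  n_isolated <- sum(!(seeds %in% nodes))
  if (nrow(el) == 0)
    warning("no database edge connects two seed genes: empty interactome")
  if (n_isolated > 0)
    message(n_isolated, " seed gene(s) without a direct interaction excluded")

  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = if (length(nodes)) nodes)
  deg <- if (length(nodes)) igraph::degree(g) else
    stats::setNames(integer(0), character(0))

  de_status <- stats::setNames(rep("ns", length(nodes)), nodes)
  if (!is.null(de_table)) {
    dir <- if (!is.null(de_table$direction)) de_table$direction
           else ifelse(de_table$log2_ratio > 0, "up", "down")
    names(dir) <- toupper(de_table$gene)
    hit <- intersect(nodes, names(dir))
    de_status[hit] <- dir[hit]
  } else {
    de_status[intersect(nodes, seeds)] <- "de"
  }

  structure(list(graph = g, nodes = nodes,
                 edges = structure(el, class = c("edge_list", "data.frame")),
                 degree = deg, de_status = de_status),
            class = "interactome", n_isolated_seeds = n_isolated)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Degree distribution of an interactome
#'
#' Exact histogram of node degrees: the count N_k of nodes with each
#' observed connectivity k.
#'
#' @param g an [build_interactome()] result, or a named degree vector.
#' @return A data frame of class `degree_distribution` with columns `k`
#'   and `N_k`, ascending in k; the counts sum to the node count.
#' @export
degree_distribution <- function(g) {
  deg <- if (inherits(g, "interactome")) g$degree else g
  if (length(deg) == 0) stop("empty network: degree distribution undefined")
  tab <- table(deg)
  structure(data.frame(k = as.integer(names(tab)),
                       N_k = as.integer(tab)),
            class = c("degree_distribution", "data.frame"))
}

#' Fit a power law to a degree distribution
#'
#' Tests the scale-free property N_k ~ k^-gamma by ordinary least squares
#' of log10(N_k) on log10(k) over the observed degrees (those with
#' N_k >= 1; no binning). The exponent is reported with the sign
#' convention gamma > 0 for a decaying distribution.
#'
#' @param d a [degree_distribution()] (or data frame with `k` and `N_k`).
#' @return A `power_law_fit`: list with `gamma` (= minus the fitted
#'   slope), `intercept` (log10 scale) and `r_squared`.
#' @export
fit_power_law <- function(d) {
  stopifnot(is.data.frame(d), all(c("k", "N_k") %in% names(d)))
  d <- d[d$N_k >= 1, , drop = FALSE]
  if (nrow(d) < 3)
    stop("power-law fit needs >= 3 distinct observed degrees")
  fit <- stats::lm(log10(N_k) ~ log10(k), data = d)
  y <- log10(d$N_k)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  structure(list(gamma = -unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_support = nrow(d)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: N_k ~ k^-%.3f (R^2 = %.3f, %d support points)\n",
              x$gamma, x$r_squared, x$n_support))
  invisible(x)
}

# coverage statistics over a hub set: total connectivity, unique edges
# touching at least one hub, and hub-hub edges (counted twice in the
# connectivity sum, hence degree_sum = incident + hub_hub)
.hub_coverage <- function(hub_genes, degree, edges) {
  degree_sum <- sum(degree)
  if (is.null(edges))
    return(list(degree_sum = degree_sum, incident_edges = NA_integer_,
                hub_hub_edges = NA_integer_))
  f <- edges$from %in% hub_genes
  t <- edges$to %in% hub_genes
  list(degree_sum = degree_sum,
       incident_edges = sum(f | t),
       hub_hub_edges = sum(f & t))
}

#' Construct a hub table from genes, connectivities and q-values
#'
#' Applies the hub criterion -- differentially expressed (q below the
#' cutoff) and at least `degree_threshold` connections (inclusive) -- to a
#' pre-tabulated set of nodes, e.g. a published hub-connectivity table,
#' and computes coverage statistics. Edge-based statistics require the
#' edge list and are `NA` otherwise.
#'
#' @param gene character vector of node identifiers.
#' @param degree integer connectivity of each node.
#' @param q q-value of each node (NA passes the filter, for tables
#'   without significance columns).
#' @param direction optional `up`/`down` labels.
#' @param name optional long node names.
#' @param degree_threshold minimum connectivity, inclusive.
#' @param q_cutoff strict q-value cutoff.
#' @param edges optional `edge_list` for coverage statistics.
#' @return A data frame of class `hub_table`, sorted by degree descending
#'   then gene, with attributes `degree_threshold`, `degree_sum`,
#'   `incident_edges` and `hub_hub_edges`.
#' @export
hub_table <- function(gene, degree, q = NA_real_, direction = NA_character_,
                      name = NA_character_, degree_threshold = 10,
                      q_cutoff = 0.05, edges = NULL) {
  df <- data.frame(gene = as.character(gene), degree = as.integer(degree),
                   q = as.numeric(q), direction = as.character(direction),
                   name = as.character(name))
  keep <- df$degree >= degree_threshold & (is.na(df$q) | df$q < q_cutoff)
  df <- df[keep, , drop = FALSE]
  df <- df[order(-df$degree, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  cov <- .hub_coverage(df$gene, df$degree, edges)
  structure(df, class = c("hub_table", "data.frame"),
            degree_threshold = degree_threshold, q_cutoff = q_cutoff,
            degree_sum = cov$degree_sum,
            incident_edges = cov$incident_edges,
            hub_hub_edges = cov$hub_hub_edges)
}

#' Identify differentially expressed network hubs
#'
#' Hubs are differentially expressed nodes with at least
#' `degree_threshold` connections (inclusive) and q-value strictly below
#' `q_cutoff`. Alongside the hub rows, three coverage statistics are
#' computed: the summed hub connectivity (`degree_sum`, which counts each
#' hub-hub edge twice), the number of unique edges incident to at least
#' one hub (`incident_edges`), and the number of hub-hub edges; by
#' construction `degree_sum = incident_edges + hub_hub_edges`.
#'
#' @param g an [build_interactome()] result.
#' @param de_table a `de_result` covering the network nodes (supplies q
#'   and direction). `NULL` skips the q filter (all nodes assumed DE).
#' @param degree_threshold minimum connectivity, inclusive ("at least 10
#'   connections").
#' @param q_cutoff strict q-value cutoff.
#' @return A `hub_table` (see [hub_table()]); empty when nothing passes.
#' @export
identify_hubs <- function(g, de_table = NULL, degree_threshold = 10,
                          q_cutoff = 0.05) {
  stopifnot(inherits(g, "interactome"))
  q <- rep(NA_real_, length(g$nodes))
  dir <- unname(g$de_status)
  if (!is.null(de_table)) {
    idx <- match(g$nodes, toupper(de_table$gene))
    q <- de_table$q[idx]
    if (!is.null(de_table$direction)) {
      dir <- de_table$direction[idx]
    } else if (!is.null(de_table$log2_ratio)) {
      dir <- ifelse(de_table$log2_ratio[idx] > 0, "up", "down")
    }
    q[is.na(idx)] <- Inf   # nodes not covered by the DE table never pass
  }
  hub_table(g$nodes, unname(g$degree[g$nodes]), q, dir,
            degree_threshold = degree_threshold, q_cutoff = q_cutoff,
            edges = g$edges)
}

#' @export
print.hub_table <- function(x, ...) {
  cat(sprintf("hub_table: %d hub(s) at degree >= %s\n",
              nrow(x), attr(x, "degree_threshold")))
  if (nrow(x) > 0)
    cat(sprintf("  degree_sum = %d, incident_edges = %s, hub_hub_edges = %s\n",
                attr(x, "degree_sum"), attr(x, "incident_edges"),
                attr(x, "hub_hub_edges")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Induced subgraph on the hub nodes
#'
#' The hubs-only wiring diagram: the subgraph induced on the hub set.
#' Hubs without hub-hub connections are retained as isolated vertices
#' (they remain hubs of the full network).
#'
#' @param g an [build_interactome()] result.
#' @param hubs a `hub_table` whose genes are nodes of `g`.
#' @return An `interactome` restricted to the hub nodes; its edge count
#'   equals the `hub_hub_edges` statistic of `hubs`.
#' @export
hub_subnetwork <- function(g, hubs) {
  stopifnot(inherits(g, "interactome"), inherits(hubs, "hub_table"))
  if (!all(hubs$gene %in% g$nodes))
    stop("hub genes must be nodes of the network")
  sub <- igraph::induced_subgraph(g$graph, hubs$gene)
  el <- igraph::as_edgelist(sub)
  el <- if (nrow(el)) .canonical_edges(el[, 1L], el[, 2L])
        else data.frame(from = character(0), to = character(0))
  nodes <- sort(hubs$gene)
  structure(list(graph = sub, nodes = nodes,
                 edges = structure(el, class = c("edge_list", "data.frame")),
                 degree = igraph::degree(sub)[nodes],
                 de_status = g$de_status[nodes]),
            class = "interactome", n_isolated_seeds = 0L)
}

#' Export an interactome to GraphML
#'
#' Node attribute `de_status` carries the direction of change (`up` /
#' `down`), mirroring the red/green coloring of published network
#' figures.
#'
#' @param g an `interactome`.
#' @param path output file.
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "interactome"))
  gr <- g$graph
  igraph::V(gr)$de_status <- unname(g$de_status[igraph::V(gr)$name])
  igraph::write_graph(gr, path, format = "graphml")
  invisible(g)
}

#' Published VSEL hypoxia hub-connectivity table
#'
#' The 18 differentially expressed hubs (degree >= 10, q < 0.05) reported
#' for the interactome of murine very small embryonic-like stem cells
#' after in vivo hypoxic exposure, with their connectivities and
#' q-values; shipped as a plain-text fixture and used as a worked example
#' for the hub-coverage statistics.
#'
#' @return A data frame with columns `name`, `gene` (symbol), `degree`
#'   and `q`.
#' @export
vsel_hub_fixture <- function() {
  path <- system.file("extdata", "vsel_hypoxia_hubs.tsv",
                      package = "hypoxNet", mustWork = TRUE)
  utils::read.delim(path)
}
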