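#' Specification of a synthetic two-condition microarray experiment
#'
#' Describes the design emulated by [generate_expression()]: a whole-genome
#' oligo array of ~45,000 probes hybridized against pooled samples from
#' hypoxia-exposed and normoxic animals, three independent hybridizations
#' per condition. Effect sizes are planted on the log2 scale for a chosen
#' number of genes so that downstream stages can be checked against known
#' ground truth.
#'
#' @param n_probes number of array probes (rows of the raw matrix).
#' @param n_genes number of distinct genes probed. Default `NULL`: the
#'   number of genes is derived by assigning each gene a small random
#'   probe multiplicity (1-3) until the array is full.
#' @param n_per_group independent hybridizations per condition (>= 2).
#' @param n_de number of genes carrying a planted condition effect.
#' @param effect_size absolute log2 mean shift planted in the hypoxia
#'   group for each differentially expressed gene.
#' @param noise_sd per-measurement residual standard deviation (log2 units).
#' @param baseline_mean,baseline_sd normal distribution of per-gene baseline
#'   intensities on the log2 scale (log-normal on the raw scale).
#' @param prob_up probability that a planted effect is an up-regulation;
#'   the remainder are down-regulated.
#' @param seed integer RNG seed; a fixed seed makes the fixture
#'   byte-reproducible.
#' @return A validated list of class `synth_expr_spec`.
#' @export
synthetic_expression_spec <- function(n_probes = 45000, n_genes = NULL,
                                      n_per_group = 3, n_de = 1388,
                                      effect_size = 2, noise_sd = 0.5,
                                      baseline_mean = 8, baseline_sd = 2,
                                      prob_up = 0.5, seed = 1L) {
  spec <- list(n_probes = as.integer(n_probes), n_genes = n_genes,
               n_per_group = as.integer(n_per_group), n_de = as.integer(n_de),
               effect_size = effect_size, noise_sd = noise_sd,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               prob_up = prob_up, seed = as.integer(seed))
  if (spec$n_per_group < 2)
    stop("invalid spec: n_per_group must be >= 2 (variance undefined below)")
  if (spec$noise_sd <= 0)
    stop("invalid spec: noise_sd must be > 0")
  if (spec$prob_up < 0 || spec$prob_up > 1)
    stop("invalid spec: prob_up must lie in [0, 1]")
  if (spec$n_probes < 1) stop("invalid spec: n_probes must be >= 1")
  if (!is.null(n_genes)) {
    spec$n_genes <- as.integer(n_genes)
    if (spec$n_genes > spec$n_probes)
      stop("invalid spec: n_genes must be <= n_probes (probes map many-to-one)")
    if (spec$n_de > spec$n_genes)
      stop("invalid spec: n_de must be <= n_genes")
  }
  if (spec$n_de > spec$n_probes)
    stop("invalid spec: n_de must be <= the number of genes")
  if (spec$n_de < 0) stop("invalid spec: n_de must be >= 0")
  structure(spec, class = "synth_expr_spec")
}

#' Generate a synthetic probe-level expression matrix with planted effects
#'
#' Draws per-gene baseline intensities from a normal distribution on the
#' log2 scale, assigns each gene 1-3 probes, plants a signed log2 mean
#' shift in the hypoxia group for a chosen set of genes, and adds i.i.d.
#' Gaussian measurement noise. Pool-level variance only is modeled: each
#' array column is treated as one independent measurement of a pooled
#' sample, so no animal-level variance component is drawn.
#'
#' @param spec a [synthetic_expression_spec()].
#' @param scale emit the matrix on the `"log2"` scale (default) or
#'   exponentiated to the `"raw"` intensity scale, to exercise the
#'   log-transform hook.
#' @return A list with elements:
#'   \describe{
#'     \item{expr}{probe-level [expression_matrix()], `n_probes` rows by
#'       `2 * n_per_group` columns, condition labels `hypoxia`/`normoxia`.}
#'     \item{annot}{data frame mapping `probe` to `gene`.}
#'     \item{truth}{ground truth: named numeric `de_genes` (signed log2
#'       effects), the gene universe, and the spec echo.}
#'   }
#' @examples
#' fx <- generate_expression(synthetic_expression_spec(
#'   n_probes = 200, n_genes = 100, n_de = 10, seed = 42))
#' dim(fx$expr)
#' @export
generate_expression <- function(spec, scale = c("log2", "raw")) {
  stopifnot(inherits(spec, "synth_expr_spec"))
  scale <- match.arg(scale)
  set.seed(spec$seed)

  # probe multiplicities: 1-3 probes per gene
  if (is.null(spec$n_genes)) {
    mult <- integer(0)
    while (sum(mult) < spec$n_probes)
      mult <- c(mult, sample(1:3, max(64, spec$n_probes %/% 2), replace = TRUE))
    n_genes <- which(cumsum(mult) >= spec$n_probes)[1L]
    mult <- mult[seq_len(n_genes)]
    mult[n_genes] <- mult[n_genes] - (sum(mult) - spec$n_probes)
  } else {
    n_genes <- spec$n_genes
    extra <- spec$n_probes - n_genes
    mult <- rep(1L, n_genes)
    if (extra > 0)
      mult <- mult + tabulate(sample.int(n_genes, extra, replace = TRUE),
                              nbins = n_genes)
  }
  if (spec$n_de > n_genes)
    stop("invalid spec: n_de must be <= n_genes (", n_genes, " genes derived)")

  genes <- sprintf("G%05d", seq_len(n_genes))
  probes <- sprintf("P%06d", seq_len(spec$n_probes))
  gene_of_probe <- rep(genes, times = mult)

  de_genes <- if (spec$n_de > 0) sample(genes, spec$n_de) else character(0)
  sign_up <- sample(c(1, -1), spec$n_de, replace = TRUE,
                    prob = c(spec$prob_up, 1 - spec$prob_up))
  effects <- stats::setNames(rep(0, n_genes), genes)
  effects[de_genes] <- sign_up * spec$effect_size

  n <- spec$n_per_group
  samples <- c(sprintf("H%d", seq_len(n)), sprintf("N%d", seq_len(n)))
  condition <- stats::setNames(rep(c("hypoxia", "normoxia"), each = n), samples)

  baseline <- stats::rnorm(n_genes, spec$baseline_mean, spec$baseline_sd)
  names(baseline) <- genes
  mu <- outer(baseline[gene_of_probe], rep(1, 2 * n)) +
    outer(effects[gene_of_probe], as.numeric(condition == "hypoxia"))
  v <- mu + matrix(stats::rnorm(length(mu), 0, spec$noise_sd), nrow(mu))
  dimnames(v) <- list(probes, samples)
  if (scale == "raw") v <- 2^v

  truth <- structure(
    list(de_genes = effects[de_genes][order(names(effects[de_genes]))],
         universe = genes, spec = spec),
    class = "synthetic_truth")
  list(expr = expression_matrix(v, condition, scale = scale),
       annot = data.frame(probe = probes, gene = gene_of_probe),
       truth = truth)
}

# largest degree whose expected histogram count is >= 1 under a truncated
# discrete power law; keeps the observed log-log histogram dense so the
# unbinned OLS fit of the exponent is unbiased at finite n
.power_law_kmax <- function(n_nodes, gamma, min_degree) {
  km <- min_degree + 2L
  while (km + 1L < n_nodes - 1L) {
    ks <- min_degree:(km + 1L)
    if (n_nodes * (km + 1L)^(-gamma) / sum(ks^(-gamma)) < 1) break
    km <- km + 1L
  }
  km
}

#' Generate a scale-free interaction database
#'
#' Emulates a direct-interaction database (e.g. curated protein-protein
#' interactions) whose degree sequence follows a discrete power law
#' P(k) proportional to k^-gamma. Degrees are drawn on the support
#' `min_degree..kmax`, where `kmax` is the finite-size cutoff at which the
#' expected count of nodes with that degree falls below one; the sequence
#' is wired by the configuration model and self-loops and duplicate edges
#' are discarded.
#'
#' @param n_nodes number of genes in the database (>= 10).
#' @param gamma power-law exponent (> 1; the default matches a scale-free
#'   interactome with a heavy hub tail).
#' @param min_degree smallest degree on the support.
#' @param seed integer RNG seed.
#' @param universe optional character vector of gene identifiers to label
#'   the nodes with; defaults to `G00001`-style identifiers so labels match
#'   the synthetic expression universe.
#' @return A data frame of class `edge_list` with columns `from` and `to`,
#'   one undirected edge per row, endpoints in lexicographic order, no
#'   self-loops or duplicates. The realized maximum-degree cutoff is
#'   attached as attribute `kmax`.
#' @export
generate_interaction_db <- function(n_nodes, gamma = 1.64, min_degree = 1,
                                    seed = 1L, universe = NULL) {
  if (gamma <= 1)
    stop("gamma must be > 1 (the power-law tail is non-normalizable otherwise)")
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  set.seed(as.integer(seed))

  km <- .power_law_kmax(n_nodes, gamma, as.integer(min_degree))
  ks <- as.integer(min_degree):km
  deg <- sample(ks, n_nodes, replace = TRUE, prob = ks^(-gamma))
  if (sum(deg) %% 2L == 1L) {
    i <- sample.int(n_nodes, 1L)
    deg[i] <- deg[i] + 1L
  }
  g <- igraph::sample_degseq(deg, method = "configuration")
  g <- igraph::simplify(g)   # drop self-loops and multi-edges

  labels <- if (is.null(universe)) {
    sprintf("G%05d", seq_len(n_nodes))
  } else {
    if (length(universe) < n_nodes)
      stop("`universe` smaller than n_nodes")
    sort(sample(universe, n_nodes))
  }
  e <- igraph::as_edgelist(g, names = FALSE)
  from <- labels[pmin(e[, 1L], e[, 2L])]
  to <- labels[pmax(e[, 1L], e[, 2L])]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  el <- data.frame(from = from, to = to)
  el <- el[order(el$from, el$to), , drop = FALSE]
  rownames(el) <- NULL
  structure(el, class = c("edge_list", "data.frame"), kmax = km)
}

#' Generate a gene-set collection with optionally planted enrichment
#'
#' Non-planted terms are uniform draws from the universe. A planted term is
#' over-populated with differentially expressed genes at a stated fraction
#' of its size, so that the enrichment stage can be checked against ground
#' truth.
#'
#' @param n_terms number of gene sets.
#' @param size_range integer vector of length 2: inclusive range of term
#'   sizes, each size drawn uniformly.
#' @param universe character vector of gene identifiers.
#' @param planted named numeric vector: fraction (in \[0, 1\]) of each named
#'   term's members to draw from `de_genes`; unnamed terms are uniform.
#' @param de_genes differentially expressed genes used to populate planted
#'   terms; required when `planted` is non-empty.
#' @param seed integer RNG seed.
#' @return A `gene_set_collection`: list with `terms` (named list of member
#'   vectors), `description` (named character) and `universe`.
#' @export
generate_gene_sets <- function(n_terms, size_range, universe,
                               planted = numeric(0), de_genes = NULL,
                               seed = 1L) {
  if (length(size_range) != 2L || size_range[1] > size_range[2])
    stop("size_range must be c(min, max) with min <= max")
  if (size_range[2] > length(universe))
    stop("size_range exceeds the universe size")
  if (length(planted) > 0) {
    if (any(planted < 0 | planted > 1))
      stop("planted fractions must lie in [0, 1]")
    if (is.null(de_genes))
      stop("`de_genes` is required when terms are planted")
  }
  set.seed(as.integer(seed))

  ids <- sprintf("TERM%04d", seq_len(n_terms))
  planted_ids <- names(planted)
  if (length(planted) > 0 && is.null(planted_ids)) {
    planted_ids <- ids[seq_along(planted)]   # plant into the first terms
    names(planted) <- planted_ids
  }
  sizes <- sample(size_range[1]:size_range[2], n_terms, replace = TRUE)
  terms <- vector("list", n_terms)
  names(terms) <- ids
  for (i in seq_len(n_terms)) {
    s <- sizes[i]
    if (ids[i] %in% planted_ids) {
      n_from_de <- min(round(planted[[ids[i]]] * s), length(de_genes), s)
      hit <- sample(de_genes, n_from_de)
      rest <- sample(setdiff(universe, hit), s - n_from_de)
      terms[[i]] <- sample(c(hit, rest))
    } else {
      terms[[i]] <- sample(universe, s)
    }
  }
  gene_set_collection(terms,
                      description = stats::setNames(
                        ifelse(ids %in% planted_ids, "planted", "random"), ids),
                      universe = universe)
}

#' Generate two labeled groups of measurements
#'
#' Emulates plasma chemokine or stem-cell count data: two independent
#' normal samples with chosen group means and standard deviations, e.g.
#' 20 hypoxia and 30 normoxia measurements.
#'
#' @param n_a,n_b group sizes (>= 2 each).
#' @param mean_a,mean_b group means.
#' @param sd_a,sd_b group standard deviations (> 0).
#' @param seed integer RNG seed.
#' @param label_a,label_b condition names.
#' @return A `group_measurements` object (see [group_measurements()]).
#' @export
generate_group_measurements <- function(n_a = 20, n_b = 30,
                                        mean_a = 0, mean_b = 0,
                                        sd_a = 1, sd_b = 1, seed = 1L,
                                        label_a = "hypoxia",
                                        label_b = "normoxia") {
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2")
  if (sd_a <= 0 || sd_b <= 0) stop("standard deviations must be > 0")
  set.seed(as.integer(seed))
  group_measurements(stats::rnorm(n_a, mean_a, sd_a),
                     stats::rnorm(n_b, mean_b, sd_b),
                     label_a = label_a, label_b = label_b)
}

#' Write / read the plain-text ground-truth manifest
#'
#' Key-value serialization of the synthetic truth (planted genes and their
#' signed effects, generative parameters) consumed by the test harness.
#'
#' @param truth a `synthetic_truth` object from [generate_expression()].
#' @param path file path.
#' @return `read_truth_manifest` returns a list with `de_genes` (named,
#'   signed effects) and any scalar fields written.
#' @export
write_truth_manifest <- function(truth, path) {
  lines <- c(
    sprintf("n_genes=%d", length(truth$universe)),
    sprintf("n_de=%d", length(truth$de_genes)),
    sprintf("seed=%d", truth$spec$seed),
    sprintf("effect_size=%g", truth$spec$effect_size),
    sprintf("noise_sd=%g", truth$spec$noise_sd),
    sprintf("de_genes=%s", paste(names(truth$de_genes), collapse = ",")),
    sprintf("de_effects=%s", paste(truth$de_genes, collapse = ",")))
  writeLines(lines, path)
  invisible(truth)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  names(vals) <- keys
  genes <- strsplit(vals[["de_genes"]], ",", fixed = TRUE)[[1L]]
  eff <- as.numeric(strsplit(vals[["de_effects"]], ",", fixed = TRUE)[[1L]])
  list(de_genes = stats::setNames(eff, genes),
       n_genes = as.integer(vals[["n_genes"]]),
       n_de = as.integer(vals[["n_de"]]),
       effect_size = as.numeric(vals[["effect_size"]]),
       noise_sd = as.numeric(vals[["noise_sd"]]),
       seed = as.integer(vals[["seed"]]))
}
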