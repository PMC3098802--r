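#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. Inputs come either from files (expression table + condition
#' sidecar, probe annotation, GMT gene sets, interaction edge list) or
#' from the synthetic-data module when `sim` is supplied; exactly one of
#' the two must be given per input slot.
#'
#' @param expression_file,condition_file,annotation_file tab-separated
#'   inputs (see [read_expression()]); `annotation_file` has columns
#'   `probe` and `gene`.
#' @param gmt_file gene sets in GMT format.
#' @param edge_list_file interaction database as a two-column edge list.
#' @param measurements_files optional named character vector of
#'   (condition, value) tables for the group-comparison stage.
#' @param sim a [synthetic_expression_spec()]; when given, expression,
#'   annotation, gene sets and interaction database are all simulated and
#'   the file slots must stay `NULL`.
#' @param sim_gene_sets,sim_db lists of extra arguments for
#'   [generate_gene_sets()] and [generate_interaction_db()] in simulation
#'   mode (term count, size range, planted terms; node count, gamma).
#' @param q_cutoff q-value threshold for calling differential expression.
#' @param enrich_fdr_cutoff permutation-FDR threshold for enriched terms.
#' @param degree_threshold minimum hub connectivity, inclusive.
#' @param nu0,window regularized-t hyperparameters (see
#'   [regularized_t()]).
#' @param n_perm permutations for the enrichment FDR.
#' @param enrich_variant enrichment statistic (see [enrichment_test()]).
#' @param cluster_max_genes the clustering stage uses at most this many
#'   top-variance genes (full-transcriptome correlation matrices are
#'   quadratic in memory).
#' @param seed master RNG seed; every stochastic stage derives from it.
#' @param outdir output directory; `NULL` disables file output.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(expression_file = NULL, condition_file = NULL,
                       annotation_file = NULL, gmt_file = NULL,
                       edge_list_file = NULL, measurements_files = NULL,
                       sim = NULL,
                       sim_gene_sets = list(n_terms = 200,
                                            size_range = c(10, 200)),
                       sim_db = list(n_nodes = 2000, gamma = 1.64),
                       q_cutoff = 0.05, enrich_fdr_cutoff = 0.05,
                       degree_threshold = 10, nu0 = 10, window = 101,
                       n_perm = 1000,
                       enrich_variant = c("ease", "hypergeometric"),
                       cluster_max_genes = 2000, seed = 1L, outdir = NULL) {
  enrich_variant <- match.arg(enrich_variant)
  have_files <- !is.null(expression_file)
  if (is.null(sim) && !have_files)
    stop("provide either input files or a simulation spec `sim`")
  if (!is.null(sim) && have_files)
    stop("provide input files or `sim`, not both")
  if (!is.null(sim)) stopifnot(inherits(sim, "synth_expr_spec"))
  for (v in c(q_cutoff, enrich_fdr_cutoff))
    if (v <= 0 || v >= 1) stop("cutoffs must lie in (0, 1)")
  if (degree_threshold < 1) stop("degree_threshold must be >= 1")
  structure(list(expression_file = expression_file,
                 condition_file = condition_file,
                 annotation_file = annotation_file,
                 gmt_file = gmt_file, edge_list_file = edge_list_file,
                 measurements_files = measurements_files,
                 sim = sim, sim_gene_sets = sim_gene_sets, sim_db = sim_db,
                 q_cutoff = q_cutoff, enrich_fdr_cutoff = enrich_fdr_cutoff,
                 degree_threshold = degree_threshold, nu0 = nu0,
                 window = window, n_perm = n_perm,
                 enrich_variant = enrich_variant,
                 cluster_max_genes = cluster_max_genes,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

# stage timing helper
.timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- expr
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full analysis pipeline
#'
#' Executes normalization (log2 transform if needed, quantile
#' normalization, probe-to-gene collapsing), hierarchical clustering,
#' regularized-t differential expression with q-value control, gene-set
#' enrichment with permutation FDR, and interactome construction with
#' power-law fitting and hub identification; a group-comparison stage
#' runs when measurement tables are supplied. All stage outputs are
#' written under `cfg$outdir` when set. Identical configuration and seed
#' give identical outputs.
#'
#' @param cfg a [run_config()].
#' @return A `run_report`: list with per-stage record counts (probes in,
#'   genes after collapse, DE genes, enriched terms, network nodes and
#'   edges, hubs, hub coverage, fitted exponent and R-squared), the
#'   configuration echo, per-stage wall-clock seconds, and the stage
#'   objects themselves in `$objects`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$outdir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  path <- function(f) file.path(out, f)
  timings <- list()
  report <- list(config = cfg[setdiff(names(cfg), "sim")],
                 seed = cfg$seed)
  objects <- list()

  ## ingest -----------------------------------------------------------
  st <- .timed({
    if (!is.null(cfg$sim)) {
      fx <- generate_expression(cfg$sim)
      truth <- fx$truth
      gsc <- do.call(generate_gene_sets,
                     c(cfg$sim_gene_sets,
                       list(universe = truth$universe,
                            de_genes = names(truth$de_genes),
                            seed = cfg$seed + 1L)))
      db <- do.call(generate_interaction_db,
                    c(cfg$sim_db, list(seed = cfg$seed + 2L,
                                       universe = truth$universe)))
      list(expr = fx$expr, annot = fx$annot, gsc = gsc, db = db,
           truth = truth)
    } else {
      list(expr = read_expression(cfg$expression_file, cfg$condition_file),
           annot = utils::read.delim(cfg$annotation_file),
           gsc = if (!is.null(cfg$gmt_file)) read_gmt(cfg$gmt_file),
           db = if (!is.null(cfg$edge_list_file))
             read_edge_list(cfg$edge_list_file),
           truth = NULL)
    }
  })
  timings$ingest <- st$seconds
  inp <- st$value
  report$n_probes_in <- nrow(inp$expr$values)

  ## normalize --------------------------------------------------------
  st <- .timed({
    m <- log2_transform(inp$expr)
    m <- quantile_normalize(m)
    collapse_probes(m, inp$annot)
  })
  timings$normalize <- st$seconds
  genes <- st$value
  report$n_genes_collapsed <- nrow(genes$values)
  report$n_probes_dropped <- attr(genes, "n_dropped")
  if (!is.null(out)) write_expression(genes, path("expression_genes.tsv"),
                                      path("conditions.tsv"))

  ## cluster ----------------------------------------------------------
  st <- .timed({
    v <- apply(genes$values, 1L, stats::var)
    top <- utils::head(order(v, decreasing = TRUE),
                       min(cfg$cluster_max_genes, sum(v > 0)))
    sub <- expression_matrix(genes$values[sort(top), , drop = FALSE],
                             genes$condition, scale = genes$scale)
    hierarchical_cluster(sub)
  })
  timings$cluster <- st$seconds
  cl <- st$value
  report$n_genes_clustered <- length(cl$row_order)
  if (!is.null(out)) write_cluster_result(cl, path("cluster"))

  ## differential expression ------------------------------------------
  st <- .timed({
    de_all <- regularized_t(genes, nu0 = cfg$nu0, window = cfg$window)
    de_all$q <- as.numeric(qvalues(de_all$p))
    list(all = de_all, hits = call_de(de_all, q_cutoff = cfg$q_cutoff))
  })
  timings$diffexpr <- st$seconds
  de_all <- st$value$all
  de_hits <- st$value$hits
  report$n_de_genes <- nrow(de_hits)
  if (!is.null(out)) {
    write_de_table(de_all, path("de_table_full.tsv"))
    write_de_table(de_hits, path("de_table_significant.tsv"))
  }

  ## enrichment -------------------------------------------------------
  if (!is.null(inp$gsc)) {
    st <- .timed({
      if (nrow(de_hits) == 0) {
        warning("no differentially expressed genes: enrichment skipped")
        NULL
      } else {
        res <- enrich_collection(de_hits$gene, inp$gsc,
                                 variant = cfg$enrich_variant)
        res$fdr_perm <- permutation_fdr(
          de_size = res$n_de[1], gsc = inp$gsc, observed_p = res$p,
          n_perm = cfg$n_perm, seed = cfg$seed + 3L,
          variant = cfg$enrich_variant)
        list(all = res,
             enriched = filter_enriched(res, cfg$enrich_fdr_cutoff))
      }
    })
    timings$enrich <- st$seconds
    enr <- st$value
    report$n_enriched_terms <- if (is.null(enr)) 0L else nrow(enr$enriched)
    if (!is.null(out) && !is.null(enr)) {
      write_enrichment(enr$all, path("enrichment_full.tsv"))
      write_enrichment(enr$enriched, path("enrichment_significant.tsv"))
    }
    objects$enrichment <- enr
  }

  ## interactome ------------------------------------------------------
  if (!is.null(inp$db)) {
    st <- .timed({
      if (nrow(de_hits) == 0) {
        warning("no differentially expressed genes: network stage skipped")
        NULL
      } else {
        net <- build_interactome(de_hits, inp$db)
        if (length(net$nodes) == 0) {
          list(net = net, fit = NULL, hubs = NULL, sub = NULL)
        } else {
          dd <- degree_distribution(net)
          fit <- if (nrow(dd) >= 3) fit_power_law(dd)
          hubs <- identify_hubs(net, de_all,
                                degree_threshold = cfg$degree_threshold,
                                q_cutoff = cfg$q_cutoff)
          sub <- hub_subnetwork(net, hubs)
          list(net = net, dd = dd, fit = fit, hubs = hubs, sub = sub)
        }
      }
    })
    timings$interactome <- st$seconds
    nw <- st$value
    if (!is.null(nw)) {
      report$n_network_nodes <- length(nw$net$nodes)
      report$n_network_edges <- nrow(nw$net$edges)
      report$n_hubs <- if (is.null(nw$hubs)) 0L else nrow(nw$hubs)
      report$hub_degree_sum <- if (is.null(nw$hubs)) 0L
        else attr(nw$hubs, "degree_sum")
      report$hub_incident_edges <- if (is.null(nw$hubs)) 0L
        else attr(nw$hubs, "incident_edges")
      report$hub_hub_edges <- if (is.null(nw$hubs)) 0L
        else attr(nw$hubs, "hub_hub_edges")
      if (!is.null(nw$fit)) {
        report$gamma <- nw$fit$gamma
        report$r_squared <- nw$fit$r_squared
      }
      if (!is.null(out) && length(nw$net$nodes) > 0) {
        write_edge_list(nw$net$edges, path("network_edges.tsv"))
        writeLines(nw$net$nodes, path("network_nodes.txt"))
        write_graphml(nw$net, path("network.graphml"))
        if (!is.null(nw$hubs))
          utils::write.table(nw$hubs, path("hub_table.tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE)
      }
    } else {
      report$n_network_nodes <- 0L
      report$n_network_edges <- 0L
      report$n_hubs <- 0L
    }
    objects$network <- nw
  }

  ## group comparisons ------------------------------------------------
  if (!is.null(cfg$measurements_files)) {
    st <- .timed({
      lapply(cfg$measurements_files, function(f) {
        gm <- read_group_measurements(f)
        list(test = two_sample_test(gm), summary = summarize_groups(gm))
      })
    })
    timings$cohortstats <- st$seconds
    objects$cohortstats <- st$value
    report$n_measurement_tables <- length(st$value)
  }

  report$timings <- timings
  report$version <- as.character(utils::packageVersion("hypoxNet"))
  report$objects <- c(list(genes = genes, cluster = cl, de_all = de_all,
                           de_hits = de_hits, truth = inp$truth), objects)
  if (!is.null(out)) {
    if (!is.null(inp$truth)) write_truth_manifest(inp$truth, path("truth.txt"))
    write_run_report(report, path("run_report.txt"))
  }
  structure(report, class = "run_report")
}

#' Write the scalar fields of a run report as key-value text
#'
#' Timestamps and in-memory objects are excluded, so reports from
#' identical configurations and seeds are byte-identical.
#'
#' @param report a `run_report`.
#' @param path output file.
#' @export
write_run_report <- function(report, path) {
  keep <- vapply(report, function(x)
    is.atomic(x) && length(x) == 1 && !is.null(x), TRUE)
  fields <- report[keep]
  lines <- sprintf("%s=%s", names(fields),
                   vapply(fields, function(x) format(x, digits = 10), ""))
  writeLines(lines, path)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  for (f in c("n_probes_in", "n_genes_collapsed", "n_de_genes",
              "n_enriched_terms", "n_network_nodes", "n_network_edges",
              "n_hubs", "hub_degree_sum", "gamma", "r_squared"))
    if (!is.null(x[[f]]))
      cat(sprintf("  %-20s %s\n", f, format(x[[f]], digits = 4)))
  invisible(x)
}
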