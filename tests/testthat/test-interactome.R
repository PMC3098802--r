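test_that("induced-subgraph construction matches the worked example", {
  db <- data.frame(from = c("A", "B"), to = c("B", "D"))
  net <- suppressMessages(build_interactome(c("A", "B", "C"), db))
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")
  expect_equal(attr(net, "n_isolated_seeds"), 1L)   # C dropped
  expect_false("D" %in% net$nodes)                  # non-seed excluded
})

test_that("seeds disjoint from the database give an empty network with a
           warning, and identifiers match case-insensitively", {
  db <- data.frame(from = "X", to = "Y")
  expect_warning(net <- suppressMessages(build_interactome(c("A", "B"), db)),
                 "empty")
  expect_length(net$nodes, 0)
  net2 <- build_interactome(c("a", "b"), data.frame(from = "A", to = "b"))
  expect_setequal(net2$nodes, c("A", "B"))
})

test_that("neighbor expansion admits first-neighbor connector nodes", {
  db <- data.frame(from = c("A", "B"), to = c("B", "D"))
  net <- build_interactome(c("A", "B"), db, expand_neighbors = TRUE)
  expect_setequal(net$nodes, c("A", "B", "D"))
  expect_equal(net$de_status[["D"]], "ns")
  expect_equal(nrow(net$edges), 2)
})

test_that("induced subgraph, degrees and hubs match an adjacency-matrix
           oracle on random graphs", {
  for (rep in 1:25) {
    set.seed(400 + rep)
    n <- sample(10:50, 1)
    labels <- sprintf("N%02d", 1:n)
    n_edge <- sample(5:80, 1)
    ef <- sample(labels, n_edge, replace = TRUE)
    et <- sample(labels, n_edge, replace = TRUE)
    seeds <- sample(labels, sample(5:n, 1))
    thr <- sample(2:5, 1)

    oracle <- adj_oracle(seeds, ef, et, degree_threshold = thr)
    db <- data.frame(from = ef, to = et)
    net <- tryCatch(
      suppressMessages(suppressWarnings(build_interactome(seeds, db))),
      error = function(e) NULL)
    if (length(oracle$nodes) == 0) {
      expect_true(is.null(net) || length(net$nodes) == 0)
      next
    }
    expect_setequal(net$nodes, oracle$nodes)
    expect_equal(net$degree[oracle$nodes], oracle$degree[oracle$nodes])
    expect_equal(nrow(net$edges), oracle$n_edges)
    hubs <- identify_hubs(net, degree_threshold = thr)
    expect_equal(sort(hubs$gene), oracle$hubs)
    # handshake lemma
    expect_equal(sum(net$degree), 2 * nrow(net$edges))
  }
})

test_that("degree histograms match closed forms and recounts", {
  tri <- build_interactome(c("A", "B", "C"),
                           data.frame(from = c("A", "A", "B"),
                                      to = c("B", "C", "C")))
  dd <- degree_distribution(tri)
  expect_equal(dd$k, 2L)
  expect_equal(dd$N_k, 3L)

  star <- build_interactome(c("H", paste0("L", 1:5)),
                            data.frame(from = "H", to = paste0("L", 1:5)))
  dd2 <- degree_distribution(star)
  expect_equal(dd2$k, c(1L, 5L))
  expect_equal(dd2$N_k, c(5L, 1L))

  el <- generate_interaction_db(100, gamma = 2, seed = 5)
  net <- build_interactome(unique(c(el$from, el$to)), el)
  dd3 <- degree_distribution(net)
  recount <- table(table(c(el$from, el$to)))
  expect_equal(dd3$N_k, as.integer(recount))
  expect_equal(sum(dd3$N_k), length(net$nodes))
  expect_error(degree_distribution(setNames(integer(0), character(0))),
               "empty")
})

test_that("exactly collinear counts give slope -2 with perfect fit", {
  d <- data.frame(k = c(1, 2, 4), N_k = c(16, 4, 1))
  fit <- fit_power_law(d)
  expect_equal(fit$gamma, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, log10(16), tolerance = 1e-12)
  expect_error(fit_power_law(data.frame(k = c(1, 2), N_k = c(3, 1))),
               ">= 3")
})

test_that("generative exponent is recovered across the scale-free range", {
  for (gamma in c(1.5, 2.0)) {
    fits <- vapply(1:15, function(s) {
      el <- generate_interaction_db(424, gamma = gamma, seed = 500 + s)
      net <- build_interactome(unique(c(el$from, el$to)), el)
      fit_power_law(degree_distribution(net))$gamma
    }, 0)
    expect_lt(abs(mean(fits) - gamma), 0.2)
  }
})

test_that("hub identification applies both criteria with an inclusive
           degree threshold", {
  # star hub H (degree 12) plus peripheral nodes
  db <- data.frame(from = "H", to = paste0("P", 1:12))
  de <- structure(data.frame(gene = c("H", paste0("P", 1:12)),
                             log2_ratio = 1,
                             p = 0.001, q = c(0.01, rep(0.01, 12))),
                  class = c("de_result", "data.frame"))
  net <- build_interactome(de$gene, db, de_table = de)
  hubs <- identify_hubs(net, de, degree_threshold = 10)
  expect_equal(hubs$gene, "H")
  expect_equal(hubs$degree, 12L)
  expect_equal(nrow(identify_hubs(net, de, degree_threshold = 13)), 0)
  expect_equal(nrow(identify_hubs(net, de, degree_threshold = 12)), 1)
  # q filter: a high-q node never becomes a hub
  de$q[de$gene == "H"] <- 0.5
  expect_equal(nrow(identify_hubs(net, de, degree_threshold = 10)), 0)
})

test_that("raising the degree threshold never adds hubs", {
  el <- generate_interaction_db(300, gamma = 1.64, seed = 42)
  net <- build_interactome(unique(c(el$from, el$to)), el)
  prev <- Inf
  for (thr in 1:8) {
    n <- nrow(identify_hubs(net, degree_threshold = thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("hub coverage identity holds and the hub subnetwork realizes
           hub_hub_edges", {
  set.seed(401)
  el <- generate_interaction_db(200, gamma = 1.5, seed = 21)
  net <- build_interactome(unique(c(el$from, el$to)), el)
  hubs <- identify_hubs(net, degree_threshold = 4)
  ds <- attr(hubs, "degree_sum")
  ie <- attr(hubs, "incident_edges")
  hh <- attr(hubs, "hub_hub_edges")
  expect_equal(ds, sum(hubs$degree))
  expect_equal(ds, ie + hh)
  expect_lte(ie, nrow(net$edges))
  sub <- hub_subnetwork(net, hubs)
  expect_equal(nrow(sub$edges), hh)
  expect_setequal(sub$nodes, hubs$gene)
  # hubs with no mutual edges stay as isolated vertices
  db <- data.frame(from = c("A", "B"), to = c("X", "Y"))
  net2 <- build_interactome(c("A", "B", "X", "Y"), db)
  h2 <- identify_hubs(net2, degree_threshold = 1)
  s2 <- hub_subnetwork(net2, hub_table(c("A", "B"), c(1L, 1L),
                                       degree_threshold = 1))
  expect_equal(nrow(s2$edges), 0)
  expect_setequal(s2$nodes, c("A", "B"))
})

test_that("edge lists and GraphML round-trip through disk", {
  el <- generate_interaction_db(50, gamma = 2, seed = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(el, f)
  back <- read_edge_list(f)
  expect_equal(back$from, el$from)
  expect_equal(back$to, el$to)

  net <- build_interactome(unique(c(el$from, el$to)), el)
  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, g)
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gorder(gr), length(net$nodes))
  expect_true("de_status" %in% igraph::vertex_attr_names(gr))
})

test_that("the published hub fixture is internally consistent", {
  hubs <- vsel_hub_fixture()
  expect_equal(nrow(hubs), 18)
  expect_true(all(hubs$degree >= 10))
  expect_true(all(hubs$q < 0.05))
})
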