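test_that("with shrinkage off the regularized t reduces to Student's t", {
  set.seed(101)
  m <- toy_expr(matrix(rnorm(20 * 6, 8, 1), 20))
  de <- regularized_t(m, nu0 = 0)
  for (i in c(1, 7, 20)) {
    tt <- t.test(m$values[i, 1:3], m$values[i, 4:6], var.equal = TRUE)
    expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$df[i], 4)
  }
})

test_that("equal group means give t = 0, p = 1", {
  set.seed(100)
  v <- rbind(g = c(5, 6, 7, 5, 6, 7),
             matrix(rnorm(4 * 6, 8), 4, dimnames = list(paste0("x", 1:4),
                                                        NULL)))
  colnames(v) <- paste0("s", 1:6)
  m <- expression_matrix(v, rep(c("hypoxia", "normoxia"), each = 3))
  de <- regularized_t(m, nu0 = 4, window = 3)
  expect_equal(de$t[de$gene == "g"], 0)
  expect_equal(de$p[de$gene == "g"], 1)
})

test_that("regularized t matches a step-by-step direct evaluation", {
  set.seed(102)
  x <- matrix(rnorm(5 * 6, mean = rep(c(2, 4, 6, 8, 10), 6), sd = 0.7), 5)
  m <- toy_expr(x)
  de <- regularized_t(m, nu0 = 4, window = 3)
  oracle <- direct_regularized_t(x[, 1:3], x[, 4:6], nu0 = 4, window = 3)
  expect_equal(de$t, oracle, tolerance = 1e-12)
  # df under both conventions
  expect_equal(de$df, rep(3 + 3 + 2 * 4 - 2, 5))
  de_c <- regularized_t(m, nu0 = 4, window = 3, df_convention = "classic")
  expect_equal(de_c$df, rep(4, 5))
})

test_that("nu0 -> infinity drives every variance to the local background", {
  set.seed(103)
  x <- matrix(rnorm(9 * 6, 8, 2), 9)
  m <- toy_expr(x)
  big <- regularized_t(m, nu0 = 1e8, window = 3)
  # recompute the implied regularized variance from the t statistic and
  # compare with the background of a direct evaluation
  st <- function(xx) list(mu = rowMeans(xx),
                          s2 = apply(xx, 1, var))
  a <- st(x[, 1:3]); b <- st(x[, 4:6])
  # direct background per group (window 3 on the intensity ranking)
  bg <- function(mu, s2) {
    ord <- order(mu); out <- numeric(9)
    for (i in 1:9) {
      lo <- min(max(1, i - 1), 7)
      out[ord[i]] <- mean(s2[ord][lo:(lo + 2)])
    }
    out
  }
  se_limit <- sqrt(bg(a$mu, a$s2) / 3 + bg(b$mu, b$s2) / 3)
  expect_equal(big$t, (a$mu - b$mu) / se_limit, tolerance = 1e-6)
})

test_that("hyperparameters and degenerate designs are validated", {
  m <- toy_expr(matrix(rnorm(30), 5))
  expect_error(regularized_t(m, nu0 = -1), "nu0")
  expect_error(regularized_t(m, window = 4), "odd")
  raw <- toy_expr(matrix(2^rnorm(30, 8), 5), scale = "raw")
  expect_error(regularized_t(raw), "log2")
  m1 <- toy_expr(matrix(rnorm(15), 5, 3), n_h = 1)
  expect_error(regularized_t(m1), ">= 2 samples")
})

test_that("q-values equal Benjamini-Hochberg when pi0 is 1", {
  set.seed(104)
  p <- runif(200)^1.5
  q <- qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-14)
})

test_that("q-values match the hand-evaluated step-down minimum", {
  p <- c(0.01, 0.02, 0.9, 0.95)
  q <- qvalues(p, lambda = 0.5)
  expect_equal(attr(q, "pi0"), 1)   # 2 of 4 p-values exceed 0.5
  expect_equal(as.numeric(q), c(0.04, 0.04, 0.95, 0.95))
})

test_that("q-values are monotone in p, order-invariant, and degenerate
           cases behave", {
  set.seed(105)
  p <- c(runif(150), rep(1, 10), runif(40, 0, 1e-3))
  q <- as.numeric(qvalues(p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  sh <- sample(length(p))
  expect_equal(as.numeric(qvalues(p[sh])), q[sh])
  expect_equal(as.numeric(qvalues(rep(1, 5))), rep(1, 5))
  expect_identical(qvalues(numeric(0)), numeric(0))
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the smoother pi0 tracks a mostly-null p distribution", {
  set.seed(106)
  p <- c(runif(900), rbeta(100, 0.2, 5))
  q <- qvalues(p, lambda = seq(0.05, 0.95, 0.05), pi0_method = "smoother")
  expect_gt(attr(q, "pi0"), 0.7)
  expect_lte(attr(q, "pi0"), 1)
})

test_that("call_de applies a strict cutoff and keeps direction", {
  de <- structure(data.frame(gene = c("a", "b", "c"),
                             log2_ratio = c(1.2, -0.8, 0.3),
                             p = c(0.001, 0.004, 0.2),
                             q = c(0.01, 0.05, 0.2)),
                  class = c("de_result", "data.frame"))
  hits <- call_de(de, q_cutoff = 0.05)
  expect_equal(hits$gene, "a")            # 0.05 itself is excluded
  expect_equal(hits$direction, "up")
  empty <- call_de(de, q_cutoff = 0.001)
  expect_equal(nrow(empty), 0)
})

test_that("planted genes are recovered with high power and the ordinary
           t-test is beaten on the same fixture", {
  sens <- function(effect, seed) {
    fx <- generate_expression(synthetic_expression_spec(
      n_probes = 1000, n_genes = 1000, n_de = 50, effect_size = effect,
      noise_sd = 0.5, seed = seed))
    genes <- collapse_probes(fx$expr, fx$annot)
    truth <- names(fx$truth$de_genes)
    de <- regularized_t(genes, nu0 = 10, window = 101)
    de$q <- as.numeric(qvalues(de$p))
    de0 <- regularized_t(genes, nu0 = 0)
    de0$q <- as.numeric(qvalues(de0$p))
    c(reg = mean(truth %in% call_de(de)$gene),
      plain = mean(truth %in% call_de(de0)$gene))
  }
  # strong planted effect: near-complete recovery
  s2 <- rowMeans(vapply(1:3, function(r) sens(2, 107 + r), c(0, 0)))
  expect_gte(s2[["reg"]], 0.9)
  # marginal effect (2 x noise SD): shrinkage must not lose power vs the
  # ordinary t-test on the same fixtures
  s1 <- rowMeans(vapply(1:3, function(r) sens(1, 117 + r), c(0, 0)))
  expect_gte(s1[["reg"]], s1[["plain"]])
})

test_that("under a complete null the q < 0.05 call rate stays controlled", {
  rates <- vapply(1:10, function(r) {
    fx <- generate_expression(synthetic_expression_spec(
      n_probes = 500, n_genes = 500, n_de = 0, noise_sd = 0.5,
      seed = 200 + r))
    genes <- collapse_probes(fx$expr, fx$annot)
    de <- regularized_t(genes, nu0 = 10, window = 101)
    mean(as.numeric(qvalues(de$p)) < 0.05)
  }, 0)
  mc_err <- sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), 0.05 + 3 * mc_err)
})

test_that("DE tables round-trip the supplementary-file schema", {
  de <- structure(data.frame(gene = c("a", "b"), log2_ratio = c(1, -1),
                             t = c(3, -3), df = c(4, 4),
                             p = c(0.01, 0.02), q = c(0.03, 0.04)),
                  class = c("de_result", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de, f)
  back <- read.delim(f)
  expect_equal(back$gene, de$gene)
  expect_equal(back$q, de$q)
})
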