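# rowwise mean and unbiased variance, avoiding apply() at array scale
.row_stats <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  s2 <- rowSums((x - mu)^2) / (n - 1)
  list(n = n, mean = mu, var = s2)
}

# local background variance: mean of the sample variances of the `window`
# genes nearest in mean intensity; fixed-size window, shifted inward at the
# ends of the intensity ranking so every window holds exactly `window` genes
.background_var <- function(mu, s2, window) {
  m <- length(mu)
  w <- min(window, m)
  ord <- order(mu)
  cs <- cumsum(c(0, s2[ord]))
  h <- (w - 1L) %/% 2L
  pos <- seq_len(m)
  lo <- pmin(pmax(1L, pos - h), m - w + 1L)
  hi <- lo + w - 1L
  bg <- (cs[hi + 1L] - cs[lo]) / w
  out <- numeric(m)
  out[ord] <- bg
  out
}

#' Empirical-Bayes regularized two-sample t-test
#'
#' A Bayesian-regularized unpaired t-test for two-condition expression
#' data at small n. For each gene and each condition, a background
#' variance sigma0^2 is estimated as the mean sample variance of the
#' `window` genes closest in mean intensity within that condition; the
#' gene's variance is then shrunk toward this local background through a
#' scaled-inverse-chi-squared prior worth `nu0` pseudo-observations:
#'
#'   var_reg = (nu0 * sigma0^2 + (n - 1) * s^2) / (nu0 + n - 2)
#'
#' The statistic is the unpaired two-sample t with the regularized
#' per-group variances; with `nu0 = 0` shrinkage is off and the ordinary
#' Student t-test (pooled variance, df = n1 + n2 - 2) is returned.
#'
#' @param m a gene-level, log2-scale [expression_matrix()] with at least
#'   two samples per condition.
#' @param nu0 prior pseudo-observation count (>= 0); larger values pull
#'   each gene's variance harder toward its local background.
#' @param window odd window width (>= 3) for the background-variance
#'   estimate, clipped at the ends of the intensity ranking.
#' @param df_convention `"augmented"` (default) counts the prior
#'   pseudo-observations toward the degrees of freedom,
#'   df = n1 + n2 + 2 nu0 - 2; `"classic"` uses df = n1 + n2 - 2.
#' @return A data frame of class `de_result`, one row per gene, with
#'   columns `gene`, `log2_ratio` (hypoxia minus normoxia mean on the log2
#'   scale), `s2_hypoxia`, `s2_normoxia`, `t`, `df` and `p`. Q-values are
#'   added by [qvalues()] / [call_de()].
#' @references Baldi P, Long AD (2001) A Bayesian framework for the
#'   analysis of microarray expression data. Bioinformatics 17:509-519.
#' @export
regularized_t <- function(m, nu0 = 10, window = 101,
                          df_convention = c("augmented", "classic")) {
  stopifnot(inherits(m, "expr_mat"))
  df_convention <- match.arg(df_convention)
  if (m$scale != "log2")
    stop("regularized_t expects a log2-scale matrix; see log2_transform()")
  if (nu0 < 0) stop("nu0 must be >= 0")
  if (window < 3 || window %% 2 == 0)
    stop("window must be odd and >= 3")

  hyp <- grep("hypox", levels(m$condition), value = TRUE)
  if (length(hyp) != 1L) hyp <- levels(m$condition)[1L]
  ia <- which(m$condition == hyp)
  ib <- which(m$condition != hyp)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each condition needs >= 2 samples (variance undefined)")

  a <- .row_stats(m$values[, ia, drop = FALSE])
  b <- .row_stats(m$values[, ib, drop = FALSE])

  shrink <- function(st) {
    if (nu0 == 0) return(st$var)          # shrinkage off: plain Student
    bg <- .background_var(st$mean, st$var, window)
    (nu0 * bg + (st$n - 1) * st$var) / (nu0 + st$n - 2)
  }
  va <- shrink(a)
  vb <- shrink(b)

  diff <- a$mean - b$mean
  se <- sqrt(va / a$n + vb / b$n)
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- if (df_convention == "augmented" && nu0 > 0)
    a$n + b$n + 2 * nu0 - 2 else a$n + b$n - 2
  p <- 2 * stats::pt(-abs(t), df = df)

  structure(data.frame(gene = rownames(m$values), log2_ratio = diff,
                       s2_hypoxia = a$var, s2_normoxia = b$var,
                       t = t, df = df, p = p, row.names = NULL),
            class = c("de_result", "data.frame"),
            nu0 = nu0, window = window, df_convention = df_convention)
}

#' Storey q-values for false-discovery-rate control
#'
#' Estimates the proportion of true nulls pi0 from the flat right tail of
#' the p-value distribution and converts each p-value to the minimum FDR
#' at which its test would be called significant:
#' q(p_(i)) = min over j >= i of pi0 * m * p_(j) / j. With pi0 fixed at 1,
#' q-values reduce exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda tuning value(s) in \[0, 1). For `pi0_method = "fixed"`,
#'   a single lambda (default 0.5, robust at small m); for `"smoother"`,
#'   an increasing grid on which pi0(lambda) is smoothed and evaluated at
#'   the grid maximum.
#' @param pi0_method how to combine the grid: `"fixed"` or `"smoother"`.
#' @param pi0 optional override forcing the null proportion (e.g. 1 for
#'   plain Benjamini-Hochberg).
#' @return Numeric q-values in the order of `p`, capped at 1, with the
#'   estimate used attached as attribute `pi0`.
#' @references Storey JD, Tibshirani R (2003) Statistical significance for
#'   genomewide studies. PNAS 100:9440-9445.
#' @export
qvalues <- function(p, lambda = 0.5,
                    pi0_method = c("fixed", "smoother"), pi0 = NULL) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)

  if (is.null(pi0)) {
    if (any(lambda < 0 | lambda >= 1) || is.unsorted(lambda, strictly = TRUE))
      stop("lambda must be strictly increasing values in [0, 1)")
    pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
    pi0 <- if (pi0_method == "fixed") {
      if (length(lambda) != 1L)
        stop("pi0_method = \"fixed\" expects a single lambda")
      pi0_l
    } else {
      if (length(lambda) < 4L)
        stop("pi0_method = \"smoother\" needs a grid of >= 4 lambda values")
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) {
      warning("estimated pi0 <= 0; using 1/m")
      pi0 <- 1 / m
    }
  }

  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))   # step-down minimum over j >= i
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Call differentially expressed genes at a q-value cutoff
#'
#' Appends q-values to a [regularized_t()] result if absent and returns
#' the genes with q strictly below the cutoff, with the direction of
#' change retained.
#'
#' @param de a `de_result` data frame; a `q` column is computed from `p`
#'   via [qvalues()] defaults when missing.
#' @param q_cutoff significance threshold on the q-value (strict `<`).
#' @param ... passed to [qvalues()] when q must be computed.
#' @return The subset of rows with `q < q_cutoff`, ordered by q, with a
#'   `direction` column (`"up"` / `"down"` in hypoxia).
#' @export
call_de <- function(de, q_cutoff = 0.05, ...) {
  stopifnot(inherits(de, "data.frame"))
  if (is.null(de$q)) de$q <- as.numeric(qvalues(de$p, ...))
  hits <- de[de$q < q_cutoff, , drop = FALSE]
  hits$direction <- ifelse(hits$log2_ratio > 0, "up", "down")
  hits <- hits[order(hits$q, hits$p, hits$gene), , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, class = c("de_result", "data.frame"), q_cutoff = q_cutoff)
}

#' Write a differential-expression table
#'
#' Tab-separated text with columns gene, log2_ratio, t, p, q (mirroring
#' the usual supplementary-table schema of gene symbol, q-value and log2
#' expression ratio).
#'
#' @param de a `de_result` with q-values.
#' @param path output file.
#' @export
write_de_table <- function(de, path) {
  cols <- intersect(c("gene", "log2_ratio", "t", "df", "p", "q", "direction"),
                    names(de))
  utils::write.table(de[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(de)
}
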