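#' Two labeled groups of measurements
#'
#' Container for analyte-level group data, e.g. plasma chemokine
#' concentrations (pg/ml) or stem-cell counts under hypoxia vs. normoxia.
#'
#' @param values_a,values_b numeric vectors, length >= 2, finite.
#' @param label_a,label_b condition names.
#' @return A `group_measurements` object.
#' @export
group_measurements <- function(values_a, values_b,
                               label_a = "hypoxia", label_b = "normoxia") {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs >= 2 values")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("values must be finite")
  structure(list(values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b),
                 label_a = label_a, label_b = label_b),
            class = "group_measurements")
}

#' Read two-column (condition, value) measurement tables
#'
#' @param path tab-separated file with columns `condition` and `value`;
#'   exactly two condition labels.
#' @return A [group_measurements()] object; group A is the first label in
#'   file order.
#' @export
read_group_measurements <- function(path) {
  df <- utils::read.delim(path)
  lab <- unique(as.character(df$condition))
  if (length(lab) != 2)
    stop("expected exactly two condition labels, got ", length(lab))
  group_measurements(df$value[df$condition == lab[1]],
                     df$value[df$condition == lab[2]],
                     label_a = lab[1], label_b = lab[2])
}

#' Unpaired two-tailed t-test with variance-equality policy
#'
#' Compares two groups by the unpaired, two-tailed Student's t-test, with
#' the p-value adjusted for unequal variances when appropriate: under
#' `policy = "auto"` the Welch-Satterthwaite form is used when an F-test
#' of variance equality rejects at alpha = 0.05, and the pooled-variance
#' form otherwise. If both groups are constant and equal, p = 1 by
#' convention.
#'
#' @param g a [group_measurements()] object.
#' @param policy `"auto"`, `"pooled"` or `"welch"`.
#' @param var_alpha significance level of the F-test used by `"auto"`.
#' @return A list of class `t_test_result`: `t`, `df` (fractional for
#'   Welch), `p`, `method` (the form actually used), and the group labels.
#' @export
two_sample_test <- function(g, policy = c("auto", "pooled", "welch"),
                            var_alpha = 0.05) {
  stopifnot(inherits(g, "group_measurements"))
  policy <- match.arg(policy)
  a <- g$values_a; b <- g$values_b

  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      message("both groups constant and equal: p = 1 by convention")
      return(structure(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                            method = "pooled", labels = c(g$label_a, g$label_b)),
                       class = "t_test_result"))
    }
    stop("both groups constant with different means: t undefined")
  }

  method <- switch(policy,
    pooled = "pooled",
    welch = "welch",
    auto = if (stats::var.test(a, b)$p.value < var_alpha) "welch" else "pooled")
  tt <- stats::t.test(a, b, var.equal = (method == "pooled"),
                      alternative = "two.sided")
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, method = method,
                 labels = c(g$label_a, g$label_b)),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s vs %s: t = %.4f, df = %.4g, p = %.4g (%s)\n",
              x$labels[1], x$labels[2], x$t, x$df, x$p, x$method))
  invisible(x)
}

#' Five-number box-and-whisker summary
#'
#' Minimum, lower quartile, median, upper quartile and maximum, the
#' quantities drawn as whiskers and box in the summary plots. Quartiles
#' use linear interpolation of order statistics ([stats::quantile()]
#' type 7).
#'
#' @param values numeric vector, length >= 1, finite.
#' @return Named numeric vector `(min, q1, median, q3, max)`.
#' @export
box_whisker_summary <- function(values) {
  if (length(values) < 1) stop("empty vector")
  if (!all(is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Summarize a measurement table per group
#'
#' @param g a [group_measurements()] object.
#' @return A data frame with one row per group: label, n, and the five
#'   box-whisker numbers.
#' @export
summarize_groups <- function(g) {
  stopifnot(inherits(g, "group_measurements"))
  rows <- rbind(box_whisker_summary(g$values_a),
                box_whisker_summary(g$values_b))
  data.frame(condition = c(g$label_a, g$label_b),
             n = c(length(g$values_a), length(g$values_b)),
             rows)
}
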