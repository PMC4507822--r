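#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test of association in a 2x2 contingency table
#' (rows = groups, columns = classification outcome). With both margins
#' fixed, the count in cell (1,1) is hypergeometric under the null; the
#' two-sided p-value follows the minimum-likelihood rule: the sum of the
#' probabilities of all tables in the support whose probability does not
#' exceed that of the observed table (with the customary 1e-7 relative
#' tolerance on the comparison). Used for group differences in
#' classification proportions (e.g. the share of cells below a CV cutoff).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list of class `group_result`: `test_name`, `statistic` (the
#'   observed (1,1) count), `p_value`, `odds_ratio` (sample OR, may be
#'   `Inf`), `n_per_group` (row sums).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("fisher_exact needs a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(table) == 0)
    stop("table has no observations", call. = FALSE)
  a <- table[1L, 1L]
  m <- sum(table[1L, ])   # row 1 total
  n2 <- sum(table[2L, ])  # row 2 total
  k <- sum(table[, 1L])   # column 1 total
  lo <- max(0L, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- probs[match(a, support)]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (table[1L, 1L] * table[2L, 2L]) / (table[1L, 2L] * table[2L, 1L])
  structure(
    list(test_name = "fisher_exact_two_sided", statistic = a, p_value = p,
         odds_ratio = or, n_per_group = rowSums(table)),
    class = "group_result")
}

#' One-sided Fisher exact tail probability
#'
#' Upper or lower hypergeometric tail for the (1,1) cell; the two-sided
#' minimum-likelihood p-value is always at least the smaller tail.
#'
#' @param table 2x2 matrix of counts.
#' @param alternative `"greater"` or `"less"` (association direction for
#'   cell (1,1)).
#' @return tail probability.
#' @export
fisher_exact_one_sided <- function(table, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  a <- table[1L, 1L]
  m <- sum(table[1L, ]); n2 <- sum(table[2L, ]); k <- sum(table[, 1L])
  if (alternative == "greater")
    stats::phyper(a - 1, m, n2, k, lower.tail = FALSE)
  else
    stats::phyper(a, m, n2, k, lower.tail = TRUE)
}

#' Two-sample group comparison
#'
#' Welch's unequal-variance t test or the Mann-Whitney (Wilcoxon rank-sum)
#' test, two-sided, with the method recorded in the result. The degenerate
#' Welch case (zero variance in both groups, equal means) returns p = 1.
#'
#' @param a,b numeric samples.
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @return list of class `group_result`: `test_name`, `statistic`,
#'   `p_value`, `n_per_group`, `effect_summary` (difference of means or of
#'   medians, per method).
#' @export
compare_two_samples <- function(a, b, method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (method == "welch_t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("welch_t needs n >= 2 per group", call. = FALSE)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      return(structure(
        list(test_name = "welch_t", statistic = if (same) 0 else Inf,
             p_value = if (same) 1 else 0,
             n_per_group = c(length(a), length(b)),
             effect_summary = sprintf("mean difference %.4g",
                                      mean(a) - mean(b))),
        class = "group_result"))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    eff <- sprintf("mean difference %.4g", mean(a) - mean(b))
  } else {
    if (length(a) < 1L || length(b) < 1L)
      stop("mann_whitney needs n >= 1 per group", call. = FALSE)
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    eff <- sprintf("median difference %.4g",
                   stats::median(a) - stats::median(b))
  }
  structure(
    list(test_name = method, statistic = unname(ht$statistic),
         p_value = ht$p.value, n_per_group = c(length(a), length(b)),
         effect_summary = eff),
    class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: statistic %.4g, p = %.3g (n = %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Format a p-value to 3 significant figures
#' @param p p-value(s).
#' @return character vector.
#' @export
format_pvalue <- function(p) formatC(signif(p, 3), format = "g")
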