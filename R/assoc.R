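# Validation-layer statistics: IHC expression scores, nonparametric group
# comparisons, categorical association, rank correlation.
# The rank/exact tests delegate to the standard base-R implementations
# (wilcox.test, fisher.test); this module fixes their configuration and the
# result contract.

#' Immunohistochemistry expression score
#'
#' Product of epithelial staining intensity (0 = negative, 1 = weak,
#' 2 = moderate, 3 = strong) and percentage of positively stained cells
#' (0-100), giving a score in \[0, 300\]. Vectorised.
#'
#' @param intensity integer vector with values in 0:3.
#' @param percent_positive numeric vector in \[0, 100\].
#' @param sample_id optional sample ids.
#' @return data.frame: `sample_id`, `intensity`, `percent_positive`, `score`.
#' @export
ihc_score <- function(intensity, percent_positive, sample_id = NULL) {
  if (!all(intensity %in% 0:3)) stop("intensity must be in {0, 1, 2, 3}")
  if (any(percent_positive < 0 | percent_positive > 100))
    stop("percent_positive must be in [0, 100]")
  data.frame(
    sample_id = sample_id %||% seq_along(intensity),
    intensity = intensity,
    percent_positive = percent_positive,
    score = intensity * percent_positive,
    stringsAsFactors = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) group comparison
#'
#' Exact p by enumeration when `nA + nB <= 12` and there are no ties;
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction. Identical values throughout both groups give
#' p = 1 by convention.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return `group_comparison` list: `statistic` (U for x), `p`, `n`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    res <- list(statistic = length(x) * length(y) / 2, p = 1,
                method = "mann-whitney (degenerate: all values equal)")
  } else {
    exact <- (length(x) + length(y) <= 12) && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                         correct = TRUE))
    res <- list(statistic = unname(wt$statistic), p = wt$p.value,
                method = if (exact) "mann-whitney exact"
                         else "mann-whitney normal approximation")
  }
  structure(c(res, list(n = c(length(x), length(y)),
                        alternative = alternative)),
            class = "group_comparison")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of all tables (at
#' fixed margins) no more likely than the observed one. An empty margin
#' gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `group_comparison` list: `p`, `odds_ratio`, `n`, `method`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    res <- list(p = 1, odds_ratio = NA_real_,
                method = "fisher exact (empty margin)")
  } else {
    ft <- stats::fisher.test(table)
    res <- list(p = ft$p.value, odds_ratio = unname(ft$estimate),
                method = "fisher exact")
  }
  structure(c(res, list(n = sum(table))), class = "group_comparison")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Midrank-based rank correlation; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list: `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  rho <- stats::cor(x, y, method = "spearman")
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$method, "- p =", format(x$p, digits = 4), "\n")
  invisible(x)
}
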