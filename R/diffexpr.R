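# Differential expression between risk groups: logCPM normalisation,
# empirical-Bayes moderated t (moment-matched variance shrinkage in the
# Smyth tradition), BH adjustment, and construction of the ranked list that
# feeds preranked GSEA.

#' log2 counts-per-million with pseudocount
#'
#' `log2((count + pc) / (libsize + 2 pc) * 1e6)`; the pseudocount keeps
#' zero counts finite.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param pseudocount added to every count (default 0.5).
#' @return numeric matrix of the same shape.
#' @export
logcpm <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("all-zero sample column")
  t(log2(t(counts + pseudocount) / (libsize + 2 * pseudocount) * 1e6))
}

# Newton solve of trigamma(x) = y, vectorised; used for moment matching of
# the prior degrees of freedom.
.trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- (tri - y) / psigamma(x, deriv = 2)
    x <- x - dif
    x[x <= 0] <- 1e-8
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

# Moment-match a scaled inverse-chi-square prior (d0, s0^2) to the observed
# gene-wise variances s2 with residual df. On the log scale,
# log s2 ~ log s0^2 + log F(df, d0); the mean and variance of log F in terms
# of digamma/trigamma give the matching equations. When the spread of log s2
# is no larger than pure sampling noise the variances are treated as
# exchangeable replicates of a single value: d0 = Inf and s0^2 = their
# geometric mean (so equal observed variances are shrunk to themselves).
.squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = stats::median(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  dfok <- df[ok]
  e <- z - digamma(dfok / 2) + log(dfok / 2)
  evar <- stats::var(e) - mean(trigamma(dfok / 2))
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s02 = exp(mean(z)))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s02 = s02)
  }
}

#' Moderated two-group differential expression
#'
#' Gene-wise two-sample comparison on a log-scale matrix (RNA logCPM or
#' protein log-intensity with `NA` for missing values). Gene variances are
#' shrunk toward a common prior estimated by moment matching on the
#' distribution of log gene variances, yielding a moderated t with
#' `d0 + df_gene` degrees of freedom. Proteins are only tested when the
#' observed fraction reaches `min_obs_frac` in *each* group (missing values
#' are omitted pairwise, never imputed).
#'
#' @param mat numeric matrix, genes x samples, log scale; `NA` allowed.
#' @param groupA,groupB column names (or indices) of the two groups;
#'   the reported log fold change is `mean(A) - mean(B)`.
#' @param min_obs_frac minimum per-group observed fraction (default 0.6).
#' @param method `"moderated"` (default) or `"welch"` for an ordinary
#'   Welch t-test without variance shrinkage.
#' @return `de_result` data.frame: `gene`, `logFC`, `t`, `p`, `q`, `n_A`,
#'   `n_B`, `usable`; attribute `prior` holds `d0` and `s02` for the
#'   moderated method.
#' @export
moderated_de <- function(mat, groupA, groupB, min_obs_frac = 0.6,
                         method = c("moderated", "welch")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  A <- mat[, groupA, drop = FALSE]
  B <- mat[, groupB, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) stop("need >= 2 samples per group")
  nA <- rowSums(!is.na(A))
  nB <- rowSums(!is.na(B))
  usable <- nA >= 2 & nB >= 2 &
    nA / ncol(A) >= min_obs_frac & nB / ncol(B) >= min_obs_frac
  mA <- rowMeans(A, na.rm = TRUE)
  mB <- rowMeans(B, na.rm = TRUE)
  vA <- apply(A, 1, stats::var, na.rm = TRUE)
  vB <- apply(B, 1, stats::var, na.rm = TRUE)
  logFC <- mA - mB
  if (method == "welch") {
    se <- sqrt(vA / nA + vB / nB)
    tstat <- logFC / se
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    prior <- NULL
  } else {
    df <- nA + nB - 2
    s2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
    prior <- .squeeze_var(s2[usable], df[usable])
    d0 <- prior$d0
    s2tilde <- if (is.infinite(d0)) rep(prior$s02, length(s2)) else
      (d0 * prior$s02 + df * s2) / (d0 + df)
    s2tilde <- pmax(s2tilde, 1e-12)          # floor against all-constant genes
    se <- sqrt(s2tilde * (1 / nA + 1 / nB))
    tstat <- logFC / se
    df <- df + d0
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat) & logFC == 0] <- 1
  tstat[!is.finite(tstat) & logFC == 0] <- 0
  p[!usable] <- NA
  tstat[!usable] <- NA
  logFC[!usable] <- NA
  out <- data.frame(
    gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    logFC = logFC, t = tstat, p = p, q = bh_adjust(p),
    n_A = nA, n_B = nB, usable = usable,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) p_(j) m / j`, capped at 1.
#' `NA` p-values are excluded from the adjustment (they do not count toward
#' `m`) and propagate as `NA`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Rank genes for preranked GSEA
#'
#' Score = `sign(logFC) * -log10(p)` (p floored at 1e-300), descending, so
#' genes significantly overexpressed in group A sit at the top of the list.
#' Ties are broken by `|logFC|` descending, then lexicographic gene id, so
#' the output is a deterministic strict order regardless of input order.
#'
#' @param de `de_result` from [moderated_de()] (rows with `NA` p are dropped).
#' @return `ranked_list` data.frame: `gene`, `score`, in rank order.
#' @export
rank_genes <- function(de) {
  de <- de[!is.na(de$p), , drop = FALSE]
  score <- sign(de$logFC) * -log10(pmax(de$p, 1e-300))
  score[de$logFC == 0] <- 0
  ord <- order(-score, -abs(de$logFC), de$gene)
  out <- data.frame(gene = de$gene[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}
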