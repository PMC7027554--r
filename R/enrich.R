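# Gene set enrichment: weighted Kolmogorov-Smirnov-like preranked GSEA with
# a gene-tag permutation null, single-sample GSEA, and ESTIMATE-style
# stromal/immune scoring built on the ssGSEA statistic.

# Core running-sum walk. hit_pos: sorted 1-based positions of set members in
# the ranked list; w: their weights |score|^p; N: list length. The running
# sum increases by w_i / sum(w) at each hit and decreases by 1/(N - k) per
# miss; the ES is the extreme (signed) deviation, which is attained just
# before or just after a hit.
.es_walk <- function(hit_pos, w, N) {
  k <- length(hit_pos)
  if (k == 0 || k >= N) return(NA_real_)
  sw <- sum(w)
  if (sw <= 0) w <- rep(1, k) else w <- w / sum(w)
  cw <- cumsum(w)
  miss <- 1 / (N - k)
  i <- seq_len(k)
  after <- cw - (hit_pos - i) * miss
  before <- c(0, cw[-k]) - (hit_pos - i) * miss
  # extremes of the walk occur just before or just after a hit; interleave in
  # walk order so an exact +/- tie (up to rounding) resolves to the earlier
  # deviation
  cand <- as.vector(rbind(before, after))
  cand[which(abs(cand) >= max(abs(cand)) - 1e-12)[1]]
}

#' Preranked GSEA enrichment score for one gene set
#'
#' Weighted running-sum statistic over a ranked gene list: every set member
#' ("hit") advances the sum by its weight `|score|^p` (normalised over set
#' members), every non-member retreats it by `1/(N - k)`. The enrichment
#' score is the signed maximal deviation from zero; `p = 0` reduces to the
#' classic unweighted Kolmogorov-Smirnov statistic.
#'
#' @param ranked `ranked_list` data.frame (`gene`, `score`), already ordered.
#' @param members character vector of set member gene ids.
#' @param weight_p weight exponent (default 1).
#' @return single numeric ES in \[-1, 1\].
#' @examples
#' rl <- data.frame(gene = paste0("g", 1:5), score = 5:1)
#' es_preranked(rl, c("g1", "g2"))   # +1
#' es_preranked(rl, "g5")            # -1
#' @export
es_preranked <- function(ranked, members, weight_p = 1) {
  N <- nrow(ranked)
  if (N == 0) stop("empty ranked list")
  pos <- which(ranked$gene %in% members)
  if (length(pos) == 0) stop("gene set has no overlap with the ranked list")
  if (length(pos) >= N) stop("gene set covers the entire ranked list")
  .es_walk(pos, abs(ranked$score[pos])^weight_p, N)
}

#' Preranked GSEA with gene-tag permutation significance
#'
#' For each set, the observed ES is compared to a null of random gene sets
#' of equal size drawn from the ranked universe. The nominal p uses the
#' plus-one estimator over same-sign nulls, NES is ES divided by the mean
#' magnitude of same-sign nulls, and FDR q follows the GSEA ratio estimator
#' on the pooled normalised null distribution.
#'
#' @param ranked `ranked_list`.
#' @param sets named list of character vectors (gene sets).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param weight_p running-sum weight exponent (default 1).
#' @param fdr_threshold q-value below which a set is flagged `enriched`
#'   (default 0.15).
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p`, `q`, `enriched`.
#'   Sets with no overlap get `NA` statistics.
#' @export
gsea_significance <- function(ranked, sets, n_perm = 1000, seed = 1,
                              weight_p = 1, fdr_threshold = 0.15) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  N <- nrow(ranked)
  absw <- abs(ranked$score)^weight_p
  set.seed(seed)
  nm <- names(sets) %||% as.character(seq_along(sets))

  sizes <- integer(length(sets))
  es_obs <- rep(NA_real_, length(sets))
  hitlist <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    pos <- which(ranked$gene %in% sets[[i]])
    sizes[i] <- length(pos)
    if (length(pos) > 0 && length(pos) < N) {
      hitlist[[i]] <- pos
      es_obs[i] <- .es_walk(pos, absw[pos], N)
    }
  }

  # permutation nulls shared across sets of equal size
  null_by_size <- list()
  for (k in unique(sizes[sizes > 0 & sizes < N])) {
    nulls <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pos <- sort.int(sample.int(N, k))
      nulls[b] <- .es_walk(pos, absw[pos], N)
    }
    null_by_size[[as.character(k)]] <- nulls
  }

  p <- nes <- rep(NA_real_, length(sets))
  null_nes_pool <- list()
  for (i in seq_along(sets)) {
    if (is.na(es_obs[i])) next
    nulls <- null_by_size[[as.character(sizes[i])]]
    same <- if (es_obs[i] >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    if (length(same) == 0) {          # degenerate one-signed null
      p[i] <- 1 / (n_perm + 1)
      nes[i] <- sign(es_obs[i]) * abs(es_obs[i]) / mean(abs(nulls))
    } else {
      p[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
      nes[i] <- es_obs[i] / abs(mean(same))
    }
    pos_m <- mean(nulls[nulls >= 0])
    neg_m <- abs(mean(nulls[nulls < 0]))
    nn <- ifelse(nulls >= 0,
                 nulls / ifelse(pos_m > 0, pos_m, NA),
                 nulls / ifelse(neg_m > 0, neg_m, NA))
    null_nes_pool[[i]] <- nn[is.finite(nn)]
  }
  pool <- unlist(null_nes_pool)
  obs <- nes[!is.na(nes)]
  q <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num <- sum(pool >= nes[i]) / max(sum(pool >= 0), 1)
      den <- sum(obs >= nes[i]) / max(sum(obs >= 0), 1)
    } else {
      num <- sum(pool <= nes[i]) / max(sum(pool < 0), 1)
      den <- sum(obs <= nes[i]) / max(sum(obs < 0), 1)
    }
    q[i] <- if (den > 0) min(num / den, 1) else 1
  }
  data.frame(set = nm, size = sizes, ES = es_obs, NES = nes, p = p, q = q,
             enriched = !is.na(q) & q <= fdr_threshold,
             stringsAsFactors = FALSE)
}

# ssGSEA statistic for one sample given the descending order of genes.
# ord: permutation ordering expression descending; inset: logical over genes
# (original order); alpha: rank weight exponent.
.ssgsea_one <- function(ord, inset, alpha) {
  N <- length(ord)
  ins <- inset[ord]
  k <- sum(ins)
  if (k == 0 || k == N) return(NA_real_)
  rankw <- (N - seq_len(N) + 1)^alpha
  win <- ifelse(ins, rankw, 0)
  ecdf_in <- cumsum(win) / sum(win)
  ecdf_out <- cumsum(!ins) / (N - k)
  sum(ecdf_in - ecdf_out)
}

#' Single-sample GSEA scores
#'
#' Per sample, genes are ranked by expression (descending, ties broken by
#' stable gene order) and the score is the sum over all ranks of the
#' difference between the weighted in-set ECDF (weights
#' `|rank-normalised value|^alpha`) and the unweighted out-of-set ECDF.
#' Raw scores are normalised by the (max - min) of raw scores across the
#' whole run, so normalised scores are comparable across samples.
#'
#' @param expr numeric matrix, genes x samples (log expression).
#' @param sets named list of gene sets (or a single character vector).
#' @param alpha rank weight exponent (default 0.25).
#' @return list with `score` and `normalized`, each a sets x samples matrix,
#'   and `ties` (logical per sample: constant/tied expression flagged).
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need >= 2 genes")
  if (!is.list(sets)) sets <- list(set = sets)
  nm <- names(sets) %||% as.character(seq_along(sets))
  genes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  insets <- lapply(sets, function(s) genes %in% s)
  raw <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(nm, colnames(expr)))
  ties <- logical(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    ord <- order(-x, seq_along(x))        # stable tie-break by gene order
    ties[j] <- anyDuplicated(x) > 0
    for (i in seq_along(insets))
      raw[i, j] <- .ssgsea_one(ord, insets[[i]], alpha)
  }
  rng <- range(raw, na.rm = TRUE)
  denom <- rng[2] - rng[1]
  normalized <- if (is.finite(denom) && denom > 0) raw / denom else raw
  list(score = raw, normalized = normalized, ties = ties)
}

#' ESTIMATE-style stromal and immune scores
#'
#' Signature-based ssGSEA (alpha = 0.25) of a stromal and an immune gene
#' signature per sample; `combined = stromal + immune` tracks overall
#' non-tumor cell content. Signatures are user-supplied (e.g. read from GMT
#' with [read_gmt()]); the package bundles small synthetic ones for its
#' simulated cohorts.
#'
#' @param expr genes x samples log-expression matrix.
#' @param stromal_sig,immune_sig character vectors of signature genes.
#' @return data.frame: `sample`, `stromal`, `immune`, `combined` (raw ssGSEA
#'   scores).
#' @export
estimate_scores <- function(expr, stromal_sig, immune_sig) {
  genes <- rownames(expr) %||% character(0)
  for (sig in list(stromal = stromal_sig, immune = immune_sig)) {
    if (sum(genes %in% sig) < 10)
      warning("fewer than 10 signature genes found in expression matrix")
  }
  sc <- ssgsea_score(expr, list(stromal = stromal_sig, immune = immune_sig),
                     alpha = 0.25)
  data.frame(sample = colnames(expr) %||% as.character(seq_len(ncol(expr))),
             stromal = sc$score["stromal", ],
             immune = sc$score["immune", ],
             combined = sc$score["stromal", ] + sc$score["immune", ],
             row.names = NULL, stringsAsFactors = FALSE)
}
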