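# Gene-dosage effect analysis: gene-level copy number from segments,
# three-way DNA/RNA/protein correlation per gene, arm direction audit, and
# candidate-driver nomination (adenoma/CRC overlap restricted to CAE arms
# with gain-only dosage in the high-risk group).

#' Gene-level copy number from segment sets
#'
#' Per gene and sample, the overlap-length-weighted mean of the log2 means
#' of all segments overlapping the gene interval; `NA` where no segment
#' overlaps.
#'
#' @param segments_by_sample named list of `segment_set` objects (names are
#'   sample ids).
#' @param annotation data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open, same convention as the segments).
#' @return numeric matrix genes x samples.
#' @export
gene_copy_number <- function(segments_by_sample, annotation) {
  stopifnot(is.list(segments_by_sample),
            all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  ids <- names(segments_by_sample) %||%
    as.character(seq_along(segments_by_sample))
  cn <- matrix(NA_real_, nrow(annotation), length(segments_by_sample),
               dimnames = list(annotation$gene, ids))
  for (j in seq_along(segments_by_sample)) {
    seg <- segments_by_sample[[j]]
    for (ch in unique(annotation$chrom)) {
      gi <- which(annotation$chrom == ch)
      s <- seg[seg$chrom == ch, , drop = FALSE]
      if (nrow(s) == 0) next
      wsum <- num <- numeric(length(gi))
      for (k in seq_len(nrow(s))) {
        ov <- pmin(annotation$end[gi], s$end[k]) -
          pmax(annotation$start[gi], s$start[k])
        pos <- ov > 0
        wsum[pos] <- wsum[pos] + ov[pos]
        num[pos] <- num[pos] + ov[pos] * s$seg_mean[k]
      }
      cn[gi[wsum > 0], j] <- num[wsum > 0] / wsum[wsum > 0]
    }
  }
  cn
}

# correlation + t-approximation p for one pair of vectors
.cor_test <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(c(r = NA, p = NA, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA, p = NA, n = n))
  r <- stats::cor(x, y, method = method)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Three-way DNA/RNA/protein dosage correlations per gene
#'
#' For every gene, pairwise correlations between gene-level copy number, RNA
#' log-expression and protein log-intensity across the shared non-missing
#' samples of the analysis group. Pearson on log2 values is the default:
#' copy number is near-constant (plus sub-threshold segment jitter) in
#' unaltered samples, and rank methods treat that jitter as real variation,
#' diluting genuine dosage relations. Spearman is selectable. P-values use
#' the t approximation; BH adjustment runs over genes separately within each
#' pair type. A gene *passes* when all three correlations are positive with
#' `q <= alpha`.
#'
#' @param cn genes x samples copy-number matrix ([gene_copy_number()]).
#' @param rna genes x samples RNA log-expression matrix.
#' @param prot genes x samples protein log-intensity matrix (NA = missing).
#' @param samples sample ids of the analysis group (e.g. all adenomas).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha per-pair BH FDR threshold for the pass flag (default 0.05).
#' @param min_n minimum complete pairs per correlation (default 8).
#' @return `dosage_records` data.frame, one row per gene shared by all three
#'   layers: correlations/p/q/n per pair, `pass`, `reason`
#'   (`"ok"`, `"low_n"`, `"zero_variance"`).
#' @export
dosage_correlations <- function(cn, rna, prot, samples,
                                method = c("pearson", "spearman"),
                                alpha = 0.05, min_n = 8) {
  method <- match.arg(method)
  genes <- Reduce(intersect, list(rownames(cn), rownames(rna), rownames(prot)))
  if (length(genes) == 0) stop("no genes shared across the three layers")
  samples_cn <- intersect(samples, colnames(cn))
  samples_rna <- intersect(samples, colnames(rna))
  samples_prot <- intersect(samples, colnames(prot))
  pairs <- list(
    cn_rna = list(a = cn, b = rna, sa = samples_cn, sb = samples_rna),
    cn_prot = list(a = cn, b = prot, sa = samples_cn, sb = samples_prot),
    rna_prot = list(a = rna, b = prot, sa = samples_rna, sb = samples_prot))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  low_n <- zero_var <- rep(FALSE, length(genes))
  for (pn in names(pairs)) {
    pr <- pairs[[pn]]
    shared <- intersect(pr$sa, pr$sb)
    res <- t(vapply(genes, function(g)
      .cor_test(pr$a[g, shared], pr$b[g, shared], method),
      c(r = 0, p = 0, n = 0)))
    n_ok <- res[, "n"] >= min_n
    r <- ifelse(n_ok, res[, "r"], NA)
    p <- ifelse(n_ok, res[, "p"], NA)
    low_n[!n_ok] <- TRUE
    zero_var[n_ok & is.na(res[, "r"])] <- TRUE
    out[[paste0("r_", pn)]] <- r
    out[[paste0("p_", pn)]] <- p
    out[[paste0("q_", pn)]] <- bh_adjust(p)
    out[[paste0("n_", pn)]] <- as.integer(res[, "n"])
  }
  out$pass <- with(out,
    !is.na(r_cn_rna) & !is.na(r_cn_prot) & !is.na(r_rna_prot) &
    r_cn_rna > 0 & r_cn_prot > 0 & r_rna_prot > 0 &
    q_cn_rna <= alpha & q_cn_prot <= alpha & q_rna_prot <= alpha)
  out$reason <- ifelse(low_n, "low_n",
                ifelse(zero_var, "zero_variance", "ok"))
  class(out) <- c("dosage_records", "data.frame")
  out
}

#' Direction of copy-number events on an arm within a sample group
#'
#' `gain_only` when every non-neutral, conclusive call of the arm within the
#' group is a gain; `loss_only` symmetrically; `mixed` when both occur;
#' `none` when the arm is neutral throughout.
#'
#' @param arm_calls_long data.frame with columns `sample_id`, `arm_id`,
#'   `call` (stack of per-sample [call_arms()] outputs).
#' @param arm arm id, e.g. `"20q"`.
#' @param samples optional subset of sample ids (default: all).
#' @return one of `"gain_only"`, `"loss_only"`, `"mixed"`, `"none"`.
#' @export
direction_on_arm <- function(arm_calls_long, arm, samples = NULL) {
  d <- arm_calls_long[arm_calls_long$arm_id == arm, , drop = FALSE]
  if (!is.null(samples)) d <- d[d$sample_id %in% samples, , drop = FALSE]
  if (nrow(d) == 0) stop("no calls for arm ", arm, " in the group")
  has_gain <- any(d$call == "gain")
  has_loss <- any(d$call == "loss")
  if (has_gain && has_loss) "mixed"
  else if (has_gain) "gain_only"
  else if (has_loss) "loss_only"
  else "none"
}

#' Nominate candidate progression drivers
#'
#' A gene is nominated when it shows a significant positive three-way
#' dosage effect in *both* the adenoma and the CRC cohort, lies on one of
#' the seven CAE arms, and its arm shows gain-only dosage direction in the
#' high-risk adenoma group. The full audit table keeps per-filter flags.
#'
#' @param adenoma,crc `dosage_records` for the two cohorts.
#' @param directions named character vector arm_id -> direction in the HRA
#'   group (from [direction_on_arm()]).
#' @param annotation data.frame with columns `gene`, `arm_id`.
#' @param cae_arms arm ids counted as CAE arms (default the 7-arm universe).
#' @return `driver_candidates` data.frame: `gene`, `arm_id`, `in_adenoma`,
#'   `in_crc`, `on_cae_arm`, `gain_only_in_hra`, `nominated`.
#' @export
nominate_drivers <- function(adenoma, crc, directions, annotation,
                             cae_arms = cae_universe()$arm_id) {
  pass_a <- adenoma$gene[adenoma$pass]
  pass_c <- crc$gene[crc$pass]
  genes <- union(pass_a, pass_c)
  arm <- annotation$arm_id[match(genes, annotation$gene)]
  dir <- unname(directions[arm])
  out <- data.frame(
    gene = genes,
    arm_id = arm,
    in_adenoma = genes %in% pass_a,
    in_crc = genes %in% pass_c,
    on_cae_arm = !is.na(arm) & arm %in% cae_arms,
    gain_only_in_hra = !is.na(dir) & dir == "gain_only",
    stringsAsFactors = FALSE)
  out$nominated <- out$in_adenoma & out$in_crc & out$on_cae_arm &
    out$gain_only_in_hra
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("driver_candidates", "data.frame")
  out
}
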