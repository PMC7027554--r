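# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive each statistic from its definition and
# never call the package functions they check.

# Benjamini-Hochberg by the step-up definition: q_(i) = min_{j>=i} p_(j)*m/j
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# GSEA running sum evaluated literally, position by position
es_bruteforce <- function(scores, inset, p = 1) {
  N <- length(scores)
  w <- abs(scores)^p
  sw <- sum(w[inset])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- if (inset[i]) run + w[i] / sw else run - 1 / (N - sum(inset))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_bruteforce <- function(x, y) {
  n <- length(x) + length(y)
  vals <- c(x, y)
  u_of <- function(idx) {
    xx <- vals[idx]; yy <- vals[-idx]
    sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  }
  u_obs <- u_of(seq_along(x))
  mid <- length(x) * length(y) / 2
  combs <- utils::combn(n, length(x))
  us <- apply(combs, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# two-sided Fisher p: sum of hypergeometric probabilities of all tables (at
# the observed margins) no more likely than the observed one
fisher_bruteforce <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# classic Spearman formula for tie-free vectors
spearman_formula <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exhaustive best single split by the pooled-variance two-sample t statistic
best_split_bruteforce <- function(x, min_side = 2) {
  n <- length(x)
  best_t <- -Inf
  best_k <- NA
  for (k in min_side:(n - min_side)) {
    a <- x[1:k]; b <- x[(k + 1):n]
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2)
    tt <- abs(mean(a) - mean(b)) / sqrt(s2 * (1 / k + 1 / (n - k)))
    if (tt > best_t) { best_t <- tt; best_k <- k }
  }
  best_k
}

# fixture: single-chromosome binned profile from a vector of bin values
profile_from_values <- function(x, chrom = "chr1", bw = 1e6, sample_id = NULL) {
  p <- data.frame(chrom = chrom, start = (seq_along(x) - 1) * bw,
                  end = seq_along(x) * bw, log2 = x)
  if (!is.null(sample_id)) attr(p, "sample_id") <- sample_id
  p
}

# fixture: arm-call table for detect_caes from a named call vector
# (e.g. c("8q" = "gain")); every other CAE arm defaults to neutral
calls_from <- function(calls = character(0), genome = hg19_genome()) {
  df <- data.frame(arm_id = genome$arms$arm_id, chrom = genome$arms$chrom,
                   call = "neutral", altered_fraction = 0,
                   mean_log2 = 0, stringsAsFactors = FALSE)
  df$call[match(names(calls), df$arm_id)] <- unname(calls)
  df
}

# fixture: cae_profile built through the public detect_caes surface
cae_from <- function(caes = character(0), inconclusive = FALSE,
                     sample_id = "s") {
  uni <- cae_universe()
  sel <- uni[uni$cae %in% caes, ]
  calls <- stats::setNames(sel$direction, sel$arm_id)
  if (inconclusive) calls <- c(calls, "18q" = "inconclusive")
  detect_caes(calls_from(calls), sample_id = sample_id)
}

# small, fast simulation settings for tests that do not need the full genome;
# explicit arguments override the tiny defaults
tiny_sim <- function(seed = 1, ...) {
  defaults <- list(seed = seed, genome = toy_genome(22, arm_bins = 12),
                   n_genes = 300, n_dosage_genes = 14,
                   n_de_up = 40, n_de_down = 20,
                   n_stromal = 30, n_immune = 30,
                   n_genesets = 10, n_planted_sets = 2, geneset_size = 15)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
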