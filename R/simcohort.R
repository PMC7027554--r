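# Synthetic multi-omic cohort generator with known ground truth.
#
# Emulates the cohort design this package targets: matched copy-number
# (binned log2 ratios), RNA (negative-binomial counts) and protein
# (log-intensity with missing-not-at-random dropout) layers for four sample
# classes -- normal mucosa, low-risk adenoma (LRA), high-risk adenoma (HRA)
# and colorectal cancer (CRC) -- with planted arm-level cancer-associated
# events, dosage-driven genes on CAE arms, differentially expressed genes,
# enriched gene sets and stroma-coupled stromal/immune signatures.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: cohort sizes 18 normal /
#' 15 LRA / 9 HRA / 30 CRC, stroma-percentage medians 40.89 (HRA) and 27.20
#' (LRA), one-copy gain/loss log2 shifts, and an MSI fraction of 0.2 among
#' CRCs (MSI CRCs are planted with markedly fewer copy-number events).
#' Per-arm CAE frequencies have no fixed reference values and are
#' plain configuration.
#'
#' @param n_normal,n_lra,n_hra,n_crc samples per class.
#' @param seed RNG seed; the full output bundle is reproducible bit-for-bit.
#' @param genome `genome_model` (default hg19 arms, 1 Mb bins).
#' @param cae_gain_log2,cae_loss_log2 expected tumor-intrinsic log2 shift of
#'   a one-copy gain / loss (defaults `log2(3/2)`, `log2(1/2)`).
#' @param purity named tumor-cell fraction per class; observed copy-number
#'   signal is diluted as `log2(purity * 2^planted + (1 - purity))`.
#' @param stroma_median,stroma_sd per-class stroma-percentage distribution
#'   (truncated normal, so the median equals the configured value).
#' @param bin_noise_sd Gaussian noise sd on binned log2 ratios.
#' @param n_genes,n_dosage_genes total genes and planted dosage-driver genes
#'   (spread over the 7 CAE arms, at least two per arm).
#' @param dosage_beta RNA log2 change per unit copy-number log2.
#' @param n_de_up,n_de_down,de_log2fc planted HRA-vs-LRA differential genes
#'   (placed on non-CAE arms so they stay independent of copy number).
#' @param n_stromal,n_immune,stroma_beta,immune_beta stroma/immune signature
#'   gene counts and log2 slope per unit cell fraction.
#' @param gain_copy_probs probabilities of 1, 2, ... extra copies for a
#'   planted gain (default `c(0.55, 0.3, 0.15)`: arm gains are a mix of one-
#'   to three-extra-copy events, as in chromosomally unstable tumors).
#' @param lib_size,nb_dispersion RNA library size and NB dispersion
#'   (`var = mu + dispersion * mu^2`).
#' @param protein_fraction fraction of genes quantified on protein level
#'   (higher-abundance genes; planted dosage genes are always quantified).
#' @param protein_attenuation protein log2 response per unit of realized RNA
#'   log2 deviation (protein is synthesised from the same transcript pool the
#'   RNA layer measures, so biological variation is shared between the two
#'   layers and attenuated on protein level).
#' @param protein_noise_sd protein measurement noise sd.
#' @param mnar_mid,mnar_scale logistic missingness: the probability that a
#'   protein value is missing is `plogis((mnar_mid - intensity)/mnar_scale)`.
#' @param n_genesets,geneset_size,n_planted_sets random gene-set collection;
#'   the first planted sets are drawn mostly from the DE genes (half
#'   up-regulated sets, half down).
#' @param msi_fraction_crc fraction of CRCs planted as MSI.
#' @param cae_prob_hra,cae_prob_crc_mss,cae_prob_crc_msi per-CAE planting
#'   probabilities (named by CAE label).
#' @param other_event_prob per-arm probability of a random gain/loss on a
#'   non-CAE arm in tumors.
#' @param opposite_event_prob probability that a CAE arm without its planted
#'   event receives an event in the opposite direction (this is what makes
#'   mixed gain/loss arms, e.g. 8p, possible).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_normal = 18, n_lra = 15, n_hra = 9, n_crc = 30,
                       seed = 1,
                       genome = hg19_genome(1e6),
                       cae_gain_log2 = log2(3 / 2),
                       cae_loss_log2 = log2(1 / 2),
                       purity = c(normal = 1, LRA = 0.75, HRA = 0.75,
                                  CRC = 0.65),
                       stroma_median = c(normal = 35, LRA = 27.20,
                                         HRA = 40.89, CRC = 45),
                       stroma_sd = 8,
                       bin_noise_sd = 0.1,
                       n_genes = 1000, n_dosage_genes = 20, dosage_beta = 1,
                       gain_copy_probs = c(0.55, 0.3, 0.15),
                       n_de_up = 100, n_de_down = 50, de_log2fc = 1.2,
                       n_stromal = 60, n_immune = 60,
                       stroma_beta = 3, immune_beta = 3,
                       lib_size = 1e6, nb_dispersion = 0.01,
                       protein_fraction = 0.6, protein_attenuation = 0.9,
                       protein_noise_sd = 0.08,
                       mnar_mid = 9, mnar_scale = 1,
                       n_genesets = 20, geneset_size = 30, n_planted_sets = 4,
                       msi_fraction_crc = 0.2,
                       cae_prob_hra = c("8q+" = 0.5, "13q+" = 0.55,
                                        "20q+" = 0.8, "8p-" = 0.35,
                                        "15q-" = 0.35, "17p-" = 0.45,
                                        "18q-" = 0.55),
                       cae_prob_crc_mss = c("8q+" = 0.6, "13q+" = 0.7,
                                            "20q+" = 0.8, "8p-" = 0.55,
                                            "15q-" = 0.45, "17p-" = 0.7,
                                            "18q-" = 0.7),
                       cae_prob_crc_msi = c("8q+" = 0.15, "13q+" = 0.15,
                                            "20q+" = 0.15, "8p-" = 0.15,
                                            "15q-" = 0.15, "17p-" = 0.15,
                                            "18q-" = 0.15),
                       other_event_prob = 0.03,
                       opposite_event_prob = 0.02) {
  cfg <- as.list(environment())
  fracs <- c(purity, msi_fraction_crc, protein_fraction,
             cae_prob_hra, cae_prob_crc_mss, cae_prob_crc_msi,
             other_event_prob, opposite_event_prob)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  if (dosage_beta < 0) stop("dosage_beta must be >= 0")
  ns <- c(n_normal, n_lra, n_hra, n_crc, n_genes, n_dosage_genes)
  if (any(ns < 0)) stop("counts must be >= 0")
  stopifnot(inherits(genome, "genome_model"))
  class(cfg) <- "sim_config"
  cfg
}

#' Draw planted stroma percentages for a class
#'
#' Truncated normal centred on the class median (symmetric truncation keeps
#' the median at the configured value for interior medians).
#'
#' @param n number of draws.
#' @param class `"normal"`, `"LRA"`, `"HRA"` or `"CRC"`.
#' @param config `sim_config`.
#' @return numeric vector of stroma percentages in (2, 95).
#' @export
sample_stroma <- function(n, class, config) {
  m <- config$stroma_median[[class]]
  x <- stats::rnorm(n, m, config$stroma_sd)
  pmin(pmax(x, 2), 95)
}

#' Draw negative-binomial counts
#'
#' Mean `mu`, variance `mu + dispersion * mu^2` (dispersion 0 degenerates to
#' Poisson).
#'
#' @param mu vector of means.
#' @param dispersion NB dispersion.
#' @param n number of draws (default `length(mu)`).
#' @return integer-valued numeric vector.
#' @export
nb_counts <- function(mu, dispersion, n = length(mu)) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# tumor-intrinsic log2 of a gain with k extra copies, anchored so that one
# extra copy gives exactly cae_gain_log2
.gain_log2 <- function(config, k) {
  log2(1 + k * (2^config$cae_gain_log2 - 1))
}

# draw per-event gain amplitudes (number of extra copies)
.draw_gain <- function(config, n) {
  k <- sample.int(length(config$gain_copy_probs), n, replace = TRUE,
                  prob = config$gain_copy_probs)
  .gain_log2(config, k)
}

# plant arm-level events for one tumor sample; returns named log2 vector
# over all arms of the genome (0 = neutral)
.plant_arm_events <- function(config, cae_prob, force_min2 = FALSE) {
  uni <- cae_universe()
  arms <- config$genome$arms$arm_id
  ev <- stats::setNames(rep(0, length(arms)), arms)
  hit <- stats::runif(nrow(uni)) < cae_prob[uni$cae]
  if (force_min2 && sum(hit) < 2) {
    need <- 2 - sum(hit)
    pool <- which(!hit)
    add <- pool[sample.int(length(pool), need,
                           prob = cae_prob[uni$cae][pool])]
    hit[add] <- TRUE
  }
  gains <- hit & uni$direction == "gain"
  losses <- hit & uni$direction == "loss"
  ev[uni$arm_id[gains]] <- .draw_gain(config, sum(gains))
  ev[uni$arm_id[losses]] <- config$cae_loss_log2
  # opposite-direction event on unhit loss-CAE arms only (e.g. an 8p gain
  # riding a whole-chromosome-8 gain); gain-CAE arms are essentially never
  # lost in chromosomally unstable colorectal tumors
  opp <- !hit & uni$direction == "loss" &
    stats::runif(nrow(uni)) < config$opposite_event_prob
  if (any(opp)) ev[uni$arm_id[opp]] <- .draw_gain(config, sum(opp))
  other <- setdiff(arms, uni$arm_id)
  oh <- which(stats::runif(length(other)) < config$other_event_prob)
  if (length(oh)) {
    dir_gain <- stats::runif(length(oh)) < 0.5
    ev[other[oh]] <- ifelse(dir_gain, .draw_gain(config, length(oh)),
                            config$cae_loss_log2)
  }
  ev
}

# deterministic allocation of dosage genes over CAE arms: at least two per
# arm, remainder by largest-remainder proportional to gene counts
.allocate_dosage <- function(counts, total, min_per_arm = 2) {
  if (sum(counts) < total)
    stop("n_dosage_genes exceeds the number of genes on CAE arms")
  base <- pmin(counts, min_per_arm)
  if (sum(base) > total) {                      # tiny totals: proportional only
    base <- rep(0, length(counts))
  }
  rest <- total - sum(base)
  room <- counts - base
  if (rest > 0) {
    share <- rest * room / sum(room)
    add <- floor(share)
    frac_order <- order(share - add, decreasing = TRUE)
    short <- rest - sum(add)
    i <- 1
    while (short > 0) {
      k <- frac_order[(i - 1) %% length(counts) + 1]
      if (add[k] < room[k]) { add[k] <- add[k] + 1; short <- short - 1 }
      i <- i + 1
    }
    base <- base + add
  }
  base
}

#' Simulate a matched multi-omic cohort with known ground truth
#'
#' Generates, from a single seed, the complete input bundle of the pipeline:
#' binned copy-number profiles, RNA counts, protein log-intensities with
#' MNAR missingness, sample metadata, gene annotation, gene-set collection
#' and a truth manifest recording every planted feature.
#'
#' Structure of the planted model (all parameters from [sim_config()]):
#' * Arm events: HRA samples always carry >= 2 CAEs; LRA and normal samples
#'   carry none; CRCs follow per-CAE frequencies (much lower when MSI).
#' * Bins: `log2 = log2(purity * 2^planted + 1 - purity) + N(0, sd)`.
#' * RNA: NB counts; dosage genes multiply their mean by
#'   `2^(beta * CN_log2)`; stromal/immune signature genes scale with the
#'   sample's planted stroma/immune fraction; DE genes shift in HRA (and,
#'   stronger, CRC).
#' * Protein: `offset + attenuation * RNA_log2_effect + noise`, then
#'   logistic MNAR dropout increasing as intensity decreases.
#'
#' @param config `sim_config`.
#' @return object of class `sim_cohort`: list with `metadata`, `bins`
#'   (named list of binned profiles), `arm_truth` (long data.frame of
#'   planted and observed arm log2), `rna_counts`, `protein`, `annotation`,
#'   `genesets`, `signatures` (stromal/immune), and `truth` (per-sample and
#'   per-gene manifests plus planted set names).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- config$genome
  uni <- cae_universe()

  ## --- samples -----------------------------------------------------------
  classes <- rep(c("normal", "LRA", "HRA", "CRC"),
                 c(config$n_normal, config$n_lra, config$n_hra, config$n_crc))
  ids <- unlist(mapply(function(cl, n) sprintf("%s%02d", toupper(cl), seq_len(n)),
                       c("normal", "LRA", "HRA", "CRC"),
                       c(config$n_normal, config$n_lra, config$n_hra,
                         config$n_crc),
                       SIMPLIFY = FALSE))
  ids <- unname(sub("^NORMAL", "N", ids))
  n_samples <- length(ids)
  msi <- rep("MSS", n_samples)
  crc_idx <- which(classes == "CRC")
  n_msi <- round(config$msi_fraction_crc * length(crc_idx))
  if (n_msi > 0) msi[sample(crc_idx, n_msi)] <- "MSI"
  purity <- config$purity[classes]
  tumor <- classes %in% c("LRA", "HRA", "CRC")
  purity[tumor] <- pmin(pmax(
    purity[tumor] + stats::runif(sum(tumor), -0.05, 0.05), 0.05), 1)
  stroma <- numeric(n_samples)
  immune <- numeric(n_samples)
  for (cl in c("normal", "LRA", "HRA", "CRC")) {
    idx <- which(classes == cl)
    stroma[idx] <- sample_stroma(length(idx), cl, config)
  }
  immune <- pmin(pmax(0.55 * stroma + stats::rnorm(n_samples, 0, 5), 1), 70)

  ## --- arm events and bins -----------------------------------------------
  arms <- genome$arms$arm_id
  planted <- matrix(0, length(arms), n_samples, dimnames = list(arms, ids))
  for (j in seq_len(n_samples)) {
    planted[, j] <- switch(
      classes[j],
      HRA = .plant_arm_events(config, config$cae_prob_hra, force_min2 = TRUE),
      CRC = .plant_arm_events(config,
                              if (msi[j] == "MSI") config$cae_prob_crc_msi
                              else config$cae_prob_crc_mss),
      stats::setNames(rep(0, length(arms)), arms))
  }
  observed <- log2(sweep(2^planted, 2, purity, `*`) +
                   matrix(1 - purity, length(arms), n_samples, byrow = TRUE))
  bins0 <- genome_bins(genome)
  bin_arm <- match(bins0$arm_id, arms)
  bins <- vector("list", n_samples)
  names(bins) <- ids
  for (j in seq_len(n_samples)) {
    b <- bins0[, c("chrom", "start", "end")]
    b$log2 <- observed[bin_arm, j] +
      stats::rnorm(nrow(bins0), 0, config$bin_noise_sd)
    attr(b, "sample_id") <- ids[j]
    bins[[j]] <- b
  }

  ## --- gene annotation ----------------------------------------------------
  arm_len <- genome$arms$end - genome$arms$start
  gene_arm <- sample.int(nrow(genome$arms), config$n_genes, replace = TRUE,
                         prob = arm_len)
  gstart <- floor(genome$arms$start[gene_arm] +
                  stats::runif(config$n_genes) *
                  (arm_len[gene_arm] - 3e4))
  annotation <- data.frame(
    gene = sprintf("g%04d", seq_len(config$n_genes)),
    chrom = genome$arms$chrom[gene_arm],
    start = gstart, end = gstart + 3e4,
    arm_id = genome$arms$arm_id[gene_arm],
    stringsAsFactors = FALSE)

  on_cae <- annotation$arm_id %in% uni$arm_id
  counts_by_arm <- vapply(uni$arm_id,
                          function(a) sum(annotation$arm_id == a), integer(1))
  alloc <- .allocate_dosage(counts_by_arm, config$n_dosage_genes)
  dosage_genes <- unlist(lapply(seq_along(alloc), function(i) {
    pool <- annotation$gene[annotation$arm_id == uni$arm_id[i]]
    if (alloc[i] == 0) character(0) else sample(pool, alloc[i])
  }))
  is_dosage <- annotation$gene %in% dosage_genes

  pool_bg <- which(!on_cae & !is_dosage)
  need_bg <- config$n_de_up + config$n_de_down + config$n_stromal +
    config$n_immune
  if (length(pool_bg) < need_bg)
    stop("not enough non-CAE-arm genes for DE and signature planting")
  picks <- sample(pool_bg, need_bg)
  de_up <- picks[seq_len(config$n_de_up)]
  de_down <- picks[config$n_de_up + seq_len(config$n_de_down)]
  stromal_idx <- picks[config$n_de_up + config$n_de_down +
                       seq_len(config$n_stromal)]
  immune_idx <- picks[config$n_de_up + config$n_de_down + config$n_stromal +
                      seq_len(config$n_immune)]
  de_dir <- integer(config$n_genes)
  de_dir[de_up] <- 1L
  de_dir[de_down] <- -1L

  ## --- RNA layer ----------------------------------------------------------
  baseline <- stats::rnorm(config$n_genes, 5, 1.5)
  baseline[is_dosage] <- stats::rnorm(sum(is_dosage), 6.5, 0.8)
  cn_gene <- observed[match(annotation$arm_id, arms), , drop = FALSE]
  de_mult <- c(normal = 0, LRA = 0, HRA = 1, CRC = 1.2)[classes]
  eff <- matrix(baseline, config$n_genes, n_samples)
  eff <- eff + config$dosage_beta * cn_gene * is_dosage
  eff <- eff + outer(de_dir * config$de_log2fc, de_mult)
  sig_flag <- numeric(config$n_genes)
  sig_flag[stromal_idx] <- 1
  eff <- eff + config$stroma_beta * outer(sig_flag, stroma / 100)
  sig_flag <- numeric(config$n_genes)
  sig_flag[immune_idx] <- 1
  eff <- eff + config$immune_beta * outer(sig_flag, immune / 100)
  rel <- 2^eff
  mu <- sweep(rel, 2, colSums(rel), `/`) * config$lib_size
  rna_counts <- matrix(nb_counts(as.vector(mu), config$nb_dispersion),
                       config$n_genes, n_samples,
                       dimnames = list(annotation$gene, ids))

  ## --- protein layer ------------------------------------------------------
  # protein is synthesised from the realized transcript pool: its log
  # intensity tracks the sample's realized RNA log expression (attenuated),
  # so RNA biological noise is shared between the two layers
  rna_log <- logcpm(rna_counts)
  rna_dev <- rna_log - rowMeans(rna_log)
  n_prot <- round(config$protein_fraction * config$n_genes)
  rank_base <- order(baseline + stats::rnorm(config$n_genes, 0, 0.5),
                     decreasing = TRUE)
  measured <- union(which(is_dosage), rank_base)[seq_len(max(n_prot,
                                                             sum(is_dosage)))]
  measured <- sort(measured)
  offset <- 12 + 0.5 * (baseline[measured] - 5) +
    stats::rnorm(length(measured), 0, 1)
  prot_true <- offset + config$protein_attenuation *
    rna_dev[measured, , drop = FALSE] +
    matrix(stats::rnorm(length(measured) * n_samples, 0,
                        config$protein_noise_sd),
           length(measured), n_samples)
  drop <- matrix(stats::runif(length(prot_true)),
                 nrow(prot_true)) <
    stats::plogis((config$mnar_mid - prot_true) / config$mnar_scale)
  protein <- prot_true
  protein[drop] <- NA
  dimnames(protein) <- list(annotation$gene[measured], ids)

  ## --- gene sets ----------------------------------------------------------
  genesets <- list()
  n_up_sets <- ceiling(config$n_planted_sets / 2)
  for (i in seq_len(config$n_genesets)) {
    if (i <= n_up_sets) {
      core <- sample(de_up, round(0.8 * config$geneset_size))
      rest <- sample(setdiff(seq_len(config$n_genes), core),
                     config$geneset_size - length(core))
      members <- c(core, rest)
      nm <- sprintf("PLANTED_UP_%02d", i)
    } else if (i <= config$n_planted_sets) {
      core <- sample(de_down, round(0.8 * config$geneset_size))
      rest <- sample(setdiff(seq_len(config$n_genes), core),
                     config$geneset_size - length(core))
      members <- c(core, rest)
      nm <- sprintf("PLANTED_DOWN_%02d", i - n_up_sets)
    } else {
      members <- sample.int(config$n_genes, config$geneset_size)
      nm <- sprintf("RANDOM_%02d", i - config$n_planted_sets)
    }
    genesets[[nm]] <- annotation$gene[members]
  }
  signatures <- list(stromal = annotation$gene[stromal_idx],
                     immune = annotation$gene[immune_idx])

  ## --- truth manifest -----------------------------------------------------
  planted_caes <- vapply(seq_len(n_samples), function(j) {
    shift <- planted[uni$arm_id, j]
    match_dir <- (uni$direction == "gain" & shift > 0) |
      (uni$direction == "loss" & shift < 0)
    paste(uni$cae[match_dir], collapse = ",")
  }, character(1))
  metadata <- data.frame(
    sample_id = ids, class = classes, msi_status = msi,
    purity = unname(purity), stroma_fraction = stroma,
    immune_fraction = immune, stringsAsFactors = FALSE)
  truth_samples <- cbind(metadata,
                         planted_caes = planted_caes,
                         n_planted_cae = vapply(
                           strsplit(planted_caes, ","),
                           function(x) sum(nzchar(x)), integer(1)))
  truth_genes <- data.frame(
    gene = annotation$gene, arm_id = annotation$arm_id,
    dosage_driver = is_dosage,
    de_direction = de_dir,
    stromal_signature = seq_len(config$n_genes) %in% stromal_idx,
    immune_signature = seq_len(config$n_genes) %in% immune_idx,
    protein_measured = seq_len(config$n_genes) %in% measured,
    stringsAsFactors = FALSE)
  arm_truth <- data.frame(
    sample_id = rep(ids, each = length(arms)),
    arm_id = rep(arms, n_samples),
    planted_log2 = as.vector(planted),
    observed_log2 = as.vector(observed),
    stringsAsFactors = FALSE)

  structure(list(
    metadata = metadata, bins = bins, arm_truth = arm_truth,
    rna_counts = rna_counts, protein = protein, annotation = annotation,
    genesets = genesets, signatures = signatures,
    truth = list(samples = truth_samples, genes = truth_genes,
                 planted_sets = names(genesets)[seq_len(config$n_planted_sets)],
                 seed = config$seed)),
    class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the standard plain-text bundle: per-sample bin BED-like TSVs,
#' metadata and annotation TSVs, RNA/protein matrices, gene sets and
#' signatures as GMT, and the truth manifest as JSON.
#'
#' @param cohort `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(file.path(dir, "bins"), recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = cohort$truth$seed)
  for (id in names(cohort$bins))
    write_bins(cohort$bins[[id]], file.path(dir, "bins", paste0(id, ".tsv")),
               provenance = prov)
  .write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"), prov)
  .write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"), prov)
  write_matrix_tsv(cohort$rna_counts, file.path(dir, "rna_counts.tsv"), prov)
  write_matrix_tsv(cohort$protein, file.path(dir, "protein.tsv"), prov)
  write_gmt(cohort$genesets, file.path(dir, "genesets.gmt"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
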