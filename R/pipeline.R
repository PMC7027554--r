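# End-to-end orchestration: simulate (or load) -> segment -> arm calls ->
# CAE detection -> risk stratification -> differential expression -> GSEA ->
# ESTIMATE-style microenvironment scores -> gene-dosage analysis -> driver
# nomination -> report.

# polynomial rolling hash over the serialized object; cheap provenance
# fingerprint (not cryptographic)
.config_hash <- function(x) {
  b <- as.double(serialize(x, NULL, version = 2))
  h <- 0
  base <- 31
  mod <- 2^31 - 1
  for (chunk in split(b, ceiling(seq_along(b) / 2048))) {
    h <- (h * base + sum(chunk * (base^(seq_along(chunk) %% 13)))) %% mod
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Bundles all stage parameters. Input is either a `sim_config` (the cohort
#' is simulated on the fly) or a directory previously written by
#' [write_cohort()].
#'
#' @param sim `sim_config` for synthetic input (default [sim_config()]).
#' @param input_dir directory with a cohort bundle (overrides `sim`).
#' @param out_dir optional output directory for stage artifacts.
#' @param min_bins,penalty segmentation parameters ([segment_profile()]).
#' @param gain_thr,loss_thr,min_altered_frac,noise_mad_max arm-calling
#'   parameters ([call_arms()]).
#' @param de_q DE significance threshold used for up/down counts.
#' @param n_perm,gsea_fdr GSEA permutations and enrichment FDR threshold.
#' @param dosage_alpha,dosage_min_n,cor_method dosage-analysis parameters.
#' @param seed seed for the pipeline's own randomness (GSEA permutations);
#'   the simulator uses the seed inside `sim`.
#' @return classed list `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = NULL,
                            min_bins = 5, penalty = 15,
                            gain_thr = 0.15, loss_thr = -0.15,
                            min_altered_frac = 0.5, noise_mad_max = 0.25,
                            de_q = 0.05, n_perm = 1000, gsea_fdr = 0.15,
                            dosage_alpha = 0.05, dosage_min_n = 8,
                            cor_method = "pearson", seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir bundle directory.
#' @return `sim_cohort`-shaped list (without the truth manifest unless
#'   `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  binfiles <- list.files(file.path(dir, "bins"), full.names = TRUE)
  bins <- lapply(binfiles, function(f)
    read_bins(f, sample_id = sub("[.]tsv$", "", basename(f))))
  names(bins) <- sub("[.]tsv$", "", basename(binfiles))
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  structure(list(
    metadata = .read_tsv(file.path(dir, "metadata.tsv")),
    bins = bins,
    rna_counts = read_matrix_tsv(file.path(dir, "rna_counts.tsv")),
    protein = read_matrix_tsv(file.path(dir, "protein.tsv")),
    annotation = .read_tsv(file.path(dir, "annotation.tsv")),
    genesets = read_gmt(file.path(dir, "genesets.gmt")),
    signatures = read_gmt(file.path(dir, "signatures.gmt")),
    truth = truth), class = "sim_cohort")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis chain
#'
#' Executes all stages in dependency order on a simulated or loaded cohort
#' and returns a run report; identical config yields an identical report.
#'
#' @param config `pipeline_config`.
#' @return `run_report` list: `stratification` (risk-label table + counts),
#'   `de_rna`/`de_protein`, `gsea_rna`, `estimate` (scores + stroma tests),
#'   `dosage_adenoma`/`dosage_crc`, `drivers`, `arm_calls`, plus a
#'   `provenance` block (seed, config hash, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- .stage("load", {
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else simulate_cohort(config$sim)
  })
  meta <- cohort$metadata

  segments <- .stage("segment", {
    lapply(cohort$bins, segment_profile,
           min_bins = config$min_bins, penalty = config$penalty)
  })

  genome <- if (!is.null(config$sim)) config$sim$genome else hg19_genome()
  arm_calls <- .stage("arm_calls", {
    out <- lapply(names(segments), function(id) {
      ac <- call_arms(segments[[id]], genome,
                      gain_thr = config$gain_thr, loss_thr = config$loss_thr,
                      min_altered_frac = config$min_altered_frac,
                      noise_mad_max = config$noise_mad_max)
      cbind(sample_id = id, ac)
    })
    do.call(rbind, out)
  })

  strat <- .stage("stratify", {
    aden <- meta$sample_id[meta$class %in% c("LRA", "HRA")]
    caes <- lapply(aden, function(id)
      detect_caes(arm_calls[arm_calls$sample_id == id, ], sample_id = id))
    msi <- stats::setNames(meta$msi_status, meta$sample_id)[aden]
    stratify_cohort(caes, msi)
  })

  rna_log <- .stage("normalize", logcpm(cohort$rna_counts))
  hra <- strat$sample_id[strat$label == "HRA"]
  lra <- strat$sample_id[strat$label == "LRA"]

  de_rna <- .stage("de_rna", moderated_de(rna_log, hra, lra))
  de_prot <- .stage("de_protein", {
    ph <- intersect(hra, colnames(cohort$protein))
    pl <- intersect(lra, colnames(cohort$protein))
    moderated_de(cohort$protein, ph, pl)
  })

  gsea_rna <- .stage("gsea", {
    gsea_significance(rank_genes(de_rna), cohort$genesets,
                      n_perm = config$n_perm, seed = config$seed,
                      fdr_threshold = config$gsea_fdr)
  })

  est <- .stage("estimate", {
    sc <- estimate_scores(rna_log, cohort$signatures$stromal,
                          cohort$signatures$immune)
    sc$class <- meta$class[match(sc$sample, meta$sample_id)]
    stromal_hra <- sc$stromal[sc$sample %in% hra]
    stromal_lra <- sc$stromal[sc$sample %in% lra]
    mw <- mann_whitney(stromal_hra, stromal_lra)
    aden <- c(hra, lra)
    rho <- spearman_corr(
      meta$stroma_fraction[match(aden, meta$sample_id)],
      sc$stromal[match(aden, sc$sample)])
    list(scores = sc, stromal_hra_vs_lra = mw, stroma_vs_score = rho)
  })

  dosage <- .stage("dosage", {
    cn <- gene_copy_number(segments, cohort$annotation)
    aden_all <- meta$sample_id[meta$class %in% c("LRA", "HRA")]
    crc_all <- meta$sample_id[meta$class == "CRC"]
    list(cn = cn,
         adenoma = dosage_correlations(cn, rna_log, cohort$protein, aden_all,
                                       method = config$cor_method,
                                       alpha = config$dosage_alpha,
                                       min_n = config$dosage_min_n),
         crc = dosage_correlations(cn, rna_log, cohort$protein, crc_all,
                                   method = config$cor_method,
                                   alpha = config$dosage_alpha,
                                   min_n = config$dosage_min_n))
  })

  drivers <- .stage("drivers", {
    dirs <- vapply(cae_universe()$arm_id, function(a)
      direction_on_arm(arm_calls, a, samples = hra), character(1))
    nominate_drivers(dosage$adenoma, dosage$crc, dirs, cohort$annotation)
  })

  summary <- attr(strat, "summary")
  report <- structure(list(
    stratification = list(labels = strat, counts = summary),
    de_rna = list(table = de_rna,
                  n_up = sum(de_rna$q <= config$de_q & de_rna$logFC > 0,
                             na.rm = TRUE),
                  n_down = sum(de_rna$q <= config$de_q & de_rna$logFC < 0,
                               na.rm = TRUE)),
    de_protein = list(table = de_prot,
                      n_up = sum(de_prot$q <= config$de_q & de_prot$logFC > 0,
                                 na.rm = TRUE),
                      n_down = sum(de_prot$q <= config$de_q &
                                   de_prot$logFC < 0, na.rm = TRUE)),
    gsea_rna = gsea_rna,
    estimate = est,
    arm_calls = arm_calls,
    dosage_adenoma = dosage$adenoma,
    dosage_crc = dosage$crc,
    drivers = drivers,
    truth = cohort$truth,
    provenance = list(seed = config$seed,
                      sim_seed = if (!is.null(config$sim)) config$sim$seed,
                      config_hash = .config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("adenodrive")))),
    class = "run_report")

  if (!is.null(config$out_dir)) .stage("write", write_report(report, config))
  report
}

#' Write the artifacts of a pipeline run
#'
#' TSV tables per stage plus a JSON summary; every file carries the run seed
#' and config hash in `# key=value` header lines (TSV) or the provenance
#' block (JSON).
#'
#' @param report `run_report`.
#' @param config the `pipeline_config` that produced it.
#' @return output directory, invisibly.
#' @export
write_report <- function(report, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = report$provenance$seed,
               config_hash = report$provenance$config_hash)
  .write_tsv(report$stratification$labels,
             file.path(dir, "risk_labels.tsv"), prov)
  .write_tsv(report$de_rna$table, file.path(dir, "de_rna.tsv"), prov)
  .write_tsv(report$de_protein$table, file.path(dir, "de_protein.tsv"), prov)
  .write_tsv(report$gsea_rna, file.path(dir, "gsea_rna.tsv"), prov)
  .write_tsv(report$estimate$scores, file.path(dir, "estimate_scores.tsv"),
             prov)
  .write_tsv(report$dosage_adenoma, file.path(dir, "dosage_adenoma.tsv"), prov)
  .write_tsv(report$dosage_crc, file.path(dir, "dosage_crc.tsv"), prov)
  .write_tsv(report$drivers, file.path(dir, "driver_candidates.tsv"), prov)
  summary <- list(
    provenance = report$provenance,
    stratification = as.list(report$stratification$counts),
    de_rna = list(up = report$de_rna$n_up, down = report$de_rna$n_down),
    de_protein = list(up = report$de_protein$n_up,
                      down = report$de_protein$n_down),
    gsea_enriched = sum(report$gsea_rna$enriched, na.rm = TRUE),
    dosage_pass_adenoma = sum(report$dosage_adenoma$pass),
    dosage_pass_crc = sum(report$dosage_crc$pass),
    nominated_drivers = report$drivers$gene[report$drivers$nominated])
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cnt <- x$stratification$counts
  cat("adenodrive run report\n")
  cat(sprintf("  risk stratification: HRA=%d LRA=%d classifiable=%d of %d\n",
              cnt["HRA"], cnt["LRA"], cnt["classifiable"], cnt["total"]))
  cat(sprintf("  DE (RNA): %d up / %d down; (protein): %d up / %d down\n",
              x$de_rna$n_up, x$de_rna$n_down,
              x$de_protein$n_up, x$de_protein$n_down))
  cat(sprintf("  GSEA: %d gene sets enriched (q <= threshold)\n",
              sum(x$gsea_rna$enriched, na.rm = TRUE)))
  cat(sprintf("  dosage pass: %d adenoma / %d CRC; nominated drivers: %s\n",
              sum(x$dosage_adenoma$pass), sum(x$dosage_crc$pass),
              paste(x$drivers$gene[x$drivers$nominated], collapse = ", ")))
  invisible(x)
}
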