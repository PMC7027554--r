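# HRA/LRA risk stratification of adenomas from CAE profiles.
#
# High-risk adenoma (HRA): at least two of the seven CAEs.
# Low-risk adenoma (LRA): microsatellite-stable with none of the CAEs.
# Everything else is excluded with an explicit reason, in the precedence
# order MSI > inconclusive calling > single CAE.

.RISK_LABELS <- c("HRA", "LRA", "excluded_msi", "excluded_single_cae",
                  "excluded_inconclusive")

#' Assign a risk label to one adenoma
#'
#' @param cae `cae_profile` from [detect_caes()].
#' @param msi_status `"MSS"`, `"MSI"` or `"unknown"`.
#' @param unknown_msi how to treat an unknown MSI status: `"MSS"` (default,
#'   treat as stable) or `"exclude"`.
#' @return one-row data.frame: `sample_id`, `label`, `n_cae`, `msi_status`.
#' @export
stratify_sample <- function(cae, msi_status = c("MSS", "MSI", "unknown"),
                            unknown_msi = c("MSS", "exclude")) {
  stopifnot(inherits(cae, "cae_profile"))
  msi_status <- match.arg(msi_status)
  unknown_msi <- match.arg(unknown_msi)
  eff_msi <- msi_status
  if (msi_status == "unknown") {
    if (unknown_msi == "exclude") {
      return(data.frame(sample_id = cae$sample_id %||% NA_character_,
                        label = "excluded_msi", n_cae = cae$n_cae,
                        msi_status = msi_status, stringsAsFactors = FALSE))
    }
    eff_msi <- "MSS"
  }
  label <- if (eff_msi == "MSI") {
    "excluded_msi"
  } else if (cae$inconclusive_flag) {
    "excluded_inconclusive"
  } else if (cae$n_cae >= 2) {
    "HRA"
  } else if (cae$n_cae == 1) {
    "excluded_single_cae"
  } else "LRA"
  data.frame(sample_id = cae$sample_id %||% NA_character_,
             label = label, n_cae = cae$n_cae,
             msi_status = msi_status, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratify a cohort of adenomas into risk classes
#'
#' Applies [stratify_sample()] to every sample and tallies the per-label
#' bookkeeping: HRA and LRA counts and the number of classifiable samples
#' (HRA + LRA).
#'
#' @param caes list of `cae_profile` objects with unique sample ids.
#' @param msi_status character vector parallel to `caes` (`"MSS"`, `"MSI"`,
#'   `"unknown"`), or a named vector matched by sample id.
#' @param unknown_msi see [stratify_sample()].
#' @return data.frame of risk labels, with attribute `summary`: named counts
#'   per label plus `classifiable`.
#' @export
stratify_cohort <- function(caes, msi_status, unknown_msi = c("MSS", "exclude")) {
  unknown_msi <- match.arg(unknown_msi)
  if (length(caes) == 0) stop("empty cohort")
  ids <- vapply(caes, function(x) as.character(x$sample_id %||% NA_character_),
                character(1))
  if (anyDuplicated(stats::na.omit(ids)))
    stop("duplicate sample ids in cohort")
  if (!is.null(names(msi_status))) {
    msi_status <- msi_status[ids]
    msi_status[is.na(msi_status)] <- "unknown"
  } else if (length(msi_status) == 1) {
    msi_status <- rep(msi_status, length(caes))
  }
  stopifnot(length(msi_status) == length(caes))
  rows <- lapply(seq_along(caes), function(i)
    stratify_sample(caes[[i]], msi_status[i], unknown_msi))
  out <- do.call(rbind, rows)
  counts <- vapply(.RISK_LABELS, function(l) sum(out$label == l), integer(1))
  summary <- c(counts, classifiable = unname(counts["HRA"] + counts["LRA"]),
               total = nrow(out))
  attr(out, "summary") <- summary
  out
}
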