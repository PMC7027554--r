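# Arm-level copy-number calls and cancer-associated event (CAE) detection.

#' The seven colorectal cancer-associated events (CAEs)
#'
#' Recurrent arm-level copy-number changes associated with colorectal cancer:
#' gains of 8q, 13q and 20q, and losses of 8p, 15q, 17p and 18q. The presence
#' of at least two of these events defines a high-risk adenoma.
#'
#' @return data.frame with columns `cae` (label, e.g. `"8q+"`), `arm_id` and
#'   `direction` (`"gain"` or `"loss"`); always exactly 7 rows.
#' @export
cae_universe <- function() {
  data.frame(
    cae = c("8q+", "13q+", "20q+", "8p-", "15q-", "17p-", "18q-"),
    arm_id = c("8q", "13q", "20q", "8p", "15q", "17p", "18q"),
    direction = c("gain", "gain", "gain", "loss", "loss", "loss", "loss"),
    stringsAsFactors = FALSE
  )
}

#' Call gain/loss/neutral status per chromosome arm
#'
#' For every arm in the genome model, computes the fraction of the arm's
#' covered territory (overlap-length weighted, a proxy for bin counts with
#' equal-width bins) lying in segments whose mean exceeds the gain threshold
#' or falls below the loss threshold. An arm is called `gain` (`loss`) when
#' the gained (lost) fraction reaches `min_altered_frac`; `inconclusive`
#' when the profile is too noisy (residual bin MAD above `noise_mad_max`),
#' when gained and lost fractions are simultaneously above threshold, or
#' when the arm has no covered territory; otherwise `neutral`.
#'
#' @param segments `segment_set` from [segment_profile()] (or read from SEG;
#'   segments lacking the `residual_mad` attribute are treated as noise-free).
#' @param genome `genome_model`.
#' @param gain_thr,loss_thr segment-mean log2 thresholds
#'   (`loss_thr < 0 < gain_thr`).
#' @param min_altered_frac minimum altered fraction of the arm, in (0, 1].
#' @param noise_mad_max maximum tolerated residual bin MAD per chromosome.
#' @return data.frame (`arm_call` rows): `arm_id`, `chrom`, `call`,
#'   `altered_fraction`, `mean_log2`, plus `sample_id` attribute when present.
#' @export
call_arms <- function(segments, genome, gain_thr = 0.15, loss_thr = -0.15,
                      min_altered_frac = 0.5, noise_mad_max = 0.25) {
  stopifnot(inherits(genome, "genome_model"))
  if (!(loss_thr < 0 && 0 < gain_thr))
    stop("thresholds must satisfy loss_thr < 0 < gain_thr")
  if (!(min_altered_frac > 0 && min_altered_frac <= 1))
    stop("min_altered_frac must be in (0, 1]")
  rmad <- attr(segments, "residual_mad")
  arms <- genome$arms
  out <- data.frame(arm_id = arms$arm_id, chrom = arms$chrom,
                    call = "neutral", altered_fraction = 0,
                    mean_log2 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    s <- segments[segments$chrom == a$chrom, , drop = FALSE]
    ov <- pmin(s$end, a$end) - pmax(s$start, a$start)
    keep <- ov > 0
    if (!any(keep)) {
      out$call[i] <- "inconclusive"
      out$altered_fraction[i] <- NA_real_
      next
    }
    w <- ov[keep]
    m <- s$seg_mean[keep]
    covered <- sum(w)
    fg <- sum(w[m >= gain_thr]) / covered
    fl <- sum(w[m <= loss_thr]) / covered
    out$mean_log2[i] <- sum(w * m) / covered
    noisy <- !is.null(rmad) && !is.na(rmad[a$chrom]) &&
      rmad[a$chrom] > noise_mad_max
    call <- if (noisy || (fg >= min_altered_frac && fl >= min_altered_frac)) {
      "inconclusive"
    } else if (fg >= min_altered_frac) {
      "gain"
    } else if (fl >= min_altered_frac) {
      "loss"
    } else "neutral"
    out$call[i] <- call
    out$altered_fraction[i] <- switch(call, gain = fg, loss = fl, max(fg, fl))
  }
  sid <- attr(segments, "sample_id")
  if (!is.null(sid)) attr(out, "sample_id") <- sid
  out
}

#' Derive the CAE profile of a sample from its arm calls
#'
#' A CAE is present exactly when the corresponding arm's call matches the
#' CAE direction (gain for 8q/13q/20q, loss for 8p/15q/17p/18q). A CAE arm
#' that is missing from the calls or called `inconclusive` raises the
#' profile's `inconclusive_flag`.
#'
#' @param arm_calls data.frame from [call_arms()].
#' @param sample_id optional sample id (defaults to the calls' attribute).
#' @return object of class `cae_profile`: list with `sample_id`, `status`
#'   (named logical over the 7 CAEs), `n_cae` and `inconclusive_flag`.
#' @export
detect_caes <- function(arm_calls, sample_id = NULL) {
  uni <- cae_universe()
  idx <- match(uni$arm_id, arm_calls$arm_id)
  call <- ifelse(is.na(idx), "inconclusive", arm_calls$call[idx])
  status <- call == uni$direction
  names(status) <- uni$cae
  if (is.null(sample_id)) sample_id <- attr(arm_calls, "sample_id")
  structure(list(sample_id = sample_id,
                 status = status,
                 n_cae = sum(status),
                 inconclusive_flag = any(call == "inconclusive")),
            class = "cae_profile")
}

#' @export
print.cae_profile <- function(x, ...) {
  cat("CAE profile", if (!is.null(x$sample_id)) paste0("[", x$sample_id, "]"),
      "- events:", x$n_cae,
      if (x$inconclusive_flag) "(inconclusive arms present)", "\n")
  present <- names(x$status)[x$status]
  if (length(present)) cat("  ", paste(present, collapse = " "), "\n")
  invisible(x)
}
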