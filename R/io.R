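# Readers and writers for the plain-text formats used across the pipeline:
# BED-like bin TSV (0-based half-open), SEG (1-based inclusive on disk),
# expression matrices as TSV with a gene-id index column, GMT gene sets and
# .rnk ranked lists. Lines starting with '#' are treated as comments
# everywhere, so files can carry provenance headers.

.read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

.provenance_header <- function(provenance) {
  if (is.null(provenance)) return(character(0))
  paste0("# ", names(provenance), "=", unlist(provenance))
}

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a BED-like binned log2-ratio profile
#'
#' Expects a TSV with columns `chrom`, `start`, `end`, `log2` (0-based
#' half-open); additional columns are kept.
#'
#' @param path file path.
#' @param sample_id optional sample id to attach.
#' @return validated binned profile data.frame.
#' @export
read_bins <- function(path, sample_id = NULL) {
  b <- .read_tsv(path)
  if (!is.null(sample_id)) attr(b, "sample_id") <- sample_id
  validate_binned_profile(b)
  b
}

#' Write a binned profile as BED-like TSV
#' @param bins binned profile data.frame.
#' @param path file path.
#' @param provenance optional named list written as `# key=value` headers.
#' @export
write_bins <- function(bins, path, provenance = NULL) {
  .write_tsv(bins[, c("chrom", "start", "end", "log2")], path, provenance)
}

#' Write segments in SEG format
#'
#' SEG is 1-based inclusive on disk; internal 0-based half-open coordinates
#' are converted on write (`start + 1`, `end` unchanged).
#'
#' @param segments `segment_set` (internal coordinates).
#' @param path file path.
#' @param sample_id sample id column value (defaults to the set's attribute).
#' @param provenance optional named list of header fields.
#' @export
write_seg <- function(segments, path, sample_id = NULL, provenance = NULL) {
  sid <- sample_id %||% attr(segments, "sample_id") %||% "sample"
  seg <- data.frame(ID = sid, chrom = segments$chrom,
                    loc.start = segments$start + 1, loc.end = segments$end,
                    num.mark = segments$n_bins, seg.mean = segments$seg_mean)
  .write_tsv(seg, path, provenance)
}

#' Read a SEG file into internal coordinates
#'
#' Converts the on-disk 1-based inclusive intervals back to 0-based
#' half-open. Segment sets read from SEG carry no residual-noise attribute,
#' so downstream arm calling treats them as noise-free.
#'
#' @param path file path.
#' @return named list of `segment_set` data.frames, one per sample ID.
#' @export
read_seg <- function(path) {
  seg <- .read_tsv(path)
  names(seg) <- tolower(names(seg))
  split_ids <- unique(seg$id)
  out <- lapply(split_ids, function(s) {
    d <- seg[seg$id == s, ]
    r <- data.frame(chrom = d$chrom, start = d$loc.start - 1, end = d$loc.end,
                    seg_mean = d$seg.mean, n_bins = d$num.mark,
                    stringsAsFactors = FALSE)
    attr(r, "sample_id") <- s
    class(r) <- c("segment_set", "data.frame")
    r
  })
  names(out) <- split_ids
  out
}

#' Read/write a genes x samples matrix as TSV
#'
#' First column `gene` is used as the row index.
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  d <- .read_tsv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param mat matrix to write.
#' @param provenance optional named list of header fields.
#' @export
write_matrix_tsv <- function(mat, path, provenance = NULL) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, provenance)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description optional vector of descriptions (defaults to names).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Read/write a ranked list in .rnk format (gene, score TSV, no header)
#' @param path file path.
#' @return `ranked_list` data.frame ordered by descending score.
#' @export
read_rnk <- function(path) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  names(d) <- c("gene", "score")
  d <- d[order(-d$score, d$gene), ]
  rownames(d) <- NULL
  class(d) <- c("ranked_list", "data.frame")
  d
}

#' @rdname read_rnk
#' @param ranked `ranked_list` to write.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}
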