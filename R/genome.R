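# Chromosome-arm genome models used for arm-level copy-number calling.
# Coordinates are 0-based half-open throughout the package; SEG files are
# converted to 1-based inclusive only on write.

# hg19 autosome lengths and approximate centromere midpoints (bp), derived
# from the UCSC cytoband track. Acrocentric p-arms (13p, 14p, 15p, 21p, 22p)
# carry no reliable low-coverage WGS signal and are dropped from the arm
# universe.
.HG19_CHROMS <- data.frame(
  chrom = paste0("chr", 1:22),
  length = c(
    249250621L, 243199373L, 198022430L, 191154276L, 180915260L, 171115067L,
    159138663L, 146364022L, 141213431L, 135534747L, 135006516L, 133851895L,
    115169878L, 107349540L, 102531392L,  90354753L,  81195210L,  78077248L,
     59128983L,  63025520L,  48129895L,  51304566L),
  centromere = c(
    125000000L,  93300000L,  91000000L,  50400000L,  48400000L,  61000000L,
     59900000L,  45600000L,  49000000L,  40200000L,  53700000L,  35800000L,
     17900000L,  17600000L,  19000000L,  36600000L,  24000000L,  17200000L,
     26500000L,  27500000L,  13200000L,  14700000L),
  stringsAsFactors = FALSE
)

.ACROCENTRIC <- c("chr13", "chr14", "chr15", "chr21", "chr22")

#' Build an hg19-derived chromosome-arm genome model
#'
#' The model covers the 22 autosomes with p/q arm boundaries at the
#' centromere midpoint; acrocentric p-arms are excluded. It defines the arm
#' universe over which cancer-associated events (CAEs) are called.
#'
#' @param bin_width Width in bp of the equal-width bins tiling each arm
#'   (default 1 Mb, the usual granularity of low-coverage WGS read-depth
#'   profiles).
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (data.frame: chrom, length), `arms` (data.frame: chrom, arm_id, start,
#'   end; 0-based half-open) and `bin_width`.
#' @examples
#' g <- hg19_genome()
#' subset(g$arms, arm_id %in% c("8q", "20q"))
#' @export
hg19_genome <- function(bin_width = 1e6) {
  chroms <- .HG19_CHROMS
  arms <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    ch <- chroms$chrom[i]
    cen <- chroms$centromere[i]
    len <- chroms$length[i]
    num <- sub("^chr", "", ch)
    p <- data.frame(chrom = ch, arm_id = paste0(num, "p"),
                    start = 0, end = cen, stringsAsFactors = FALSE)
    q <- data.frame(chrom = ch, arm_id = paste0(num, "q"),
                    start = cen, end = len, stringsAsFactors = FALSE)
    if (ch %in% .ACROCENTRIC) q else rbind(p, q)
  }))
  rownames(arms) <- NULL
  genome_model(chroms[, c("chrom", "length")], arms, bin_width)
}

#' Construct and validate a genome model
#'
#' @param chromosomes data.frame with columns `chrom`, `length`.
#' @param arms data.frame with columns `chrom`, `arm_id`, `start`, `end`
#'   (0-based half-open); arms must lie within their chromosome and must not
#'   overlap.
#' @param bin_width positive bin width in bp.
#' @return `genome_model` object.
#' @export
genome_model <- function(chromosomes, arms, bin_width) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(arms))
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    stop("bin_width must be a single positive number")
  if (anyDuplicated(arms$arm_id)) stop("duplicate arm_id in genome model")
  if (any(arms$start >= arms$end)) stop("arm intervals must be non-empty")
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    a <- a[order(a$start), ]
    len <- chromosomes$length[match(ch, chromosomes$chrom)]
    if (is.na(len)) stop("arm on unknown chromosome: ", ch)
    if (any(a$end > len)) stop("arm exceeds chromosome length on ", ch)
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
      stop("overlapping arms on ", ch)
  }
  structure(list(chromosomes = chromosomes, arms = arms,
                 bin_width = bin_width),
            class = "genome_model")
}

#' Small synthetic genome for tests and examples
#'
#' Equal-sized chromosomes split into equal p/q arms, tiled by equal-width
#' bins. Arm ids follow the same `"<n><p|q>"` convention as [hg19_genome()],
#' so CAE arms ("8q", "20q", ...) exist when `n_chrom >= 20`.
#'
#' @param n_chrom number of chromosomes (default 22).
#' @param arm_bins bins per arm (default 20).
#' @param bin_width bin width in bp (default 1e6).
#' @return `genome_model` object.
#' @export
toy_genome <- function(n_chrom = 22, arm_bins = 20, bin_width = 1e6) {
  len <- 2 * arm_bins * bin_width
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length = rep(len, n_chrom), stringsAsFactors = FALSE)
  arms <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    data.frame(chrom = rep(chroms$chrom[i], 2),
               arm_id = paste0(i, c("p", "q")),
               start = c(0, len / 2), end = c(len / 2, len),
               stringsAsFactors = FALSE)
  }))
  genome_model(chroms, arms, bin_width)
}

#' Bin coordinates tiling a genome model
#'
#' Tiles each arm with `bin_width` bins (the last bin of an arm is truncated
#' at the arm boundary so bins never straddle a centromere).
#'
#' @param genome `genome_model` object.
#' @return data.frame: chrom, start, end, arm_id (0-based half-open).
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  bw <- genome$bin_width
  out <- lapply(seq_len(nrow(genome$arms)), function(i) {
    a <- genome$arms[i, ]
    starts <- seq(a$start, a$end - 1, by = bw)
    data.frame(chrom = a$chrom, start = starts,
               end = pmin(starts + bw, a$end),
               arm_id = a$arm_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# arm_id for an interval midpoint; NA if outside any arm
.assign_arm <- function(genome, chrom, start, end) {
  mid <- (start + end) / 2
  arm <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(genome$arms))) {
    a <- genome$arms[i, ]
    hit <- chrom == a$chrom & mid >= a$start & mid < a$end
    arm[hit] <- a$arm_id
  }
  arm
}
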