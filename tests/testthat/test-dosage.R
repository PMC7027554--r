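# Gene-level copy number, three-way dosage correlations, arm directions and
# driver nomination.

seg_of <- function(chrom, starts, ends, means) {
  s <- data.frame(chrom = chrom, start = starts, end = ends,
                  seg_mean = means, n_bins = 10L)
  class(s) <- c("segment_set", "data.frame")
  s
}

test_that("gene copy number is the overlap-weighted segment mean", {
  segs <- list(
    s1 = seg_of("chr1", c(0, 50), c(50, 100), c(0.585, 0.585)),
    s2 = seg_of("chr1", c(0, 50), c(50, 100), c(0, 1)))
  ann <- data.frame(gene = c("inside", "straddle", "nowhere"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(10, 40, 10), end = c(30, 60, 30))
  cn <- gene_copy_number(segs, ann)
  expect_equal(cn["inside", "s1"], 0.585)
  expect_equal(cn["straddle", "s2"], 0.5)          # half in 0, half in 1
  expect_true(all(is.na(cn["nowhere", ])))
})

test_that("perfect monotone three-way dependence passes; constant CN is excluded", {
  n <- 12
  ids <- paste0("s", 1:n)
  x <- seq_len(n)
  cn <- rbind(good = x, flat = rep(0.3, n))
  rna <- rbind(good = 2 * x + 1, flat = rnorm(n))
  prot <- rbind(good = x^1.5, flat = rnorm(n))
  colnames(cn) <- colnames(rna) <- colnames(prot) <- ids
  d <- dosage_correlations(cn, rna, prot, ids, method = "spearman")
  g <- d[d$gene == "good", ]
  expect_equal(c(g$r_cn_rna, g$r_cn_prot, g$r_rna_prot), c(1, 1, 1))
  expect_true(g$pass)
  f <- d[d$gene == "flat", ]
  expect_equal(f$reason, "zero_variance")
  expect_false(f$pass)
})

test_that("correlations below min_n complete pairs are not reported", {
  ids <- paste0("s", 1:10)
  cn <- rna <- prot <- matrix(rnorm(10), 1, dimnames = list("g", ids))
  prot[1, 1:5] <- NA
  d <- dosage_correlations(cn, rna, prot, ids, min_n = 8)
  expect_true(is.na(d$r_cn_prot))
  expect_equal(d$reason, "low_n")
})

test_that("correlation routine matches a brute-force rank oracle on small vectors", {
  set.seed(23)
  ids <- paste0("s", 1:6)
  for (i in 1:15) {
    x <- sample(1:20, 6); y <- sample(1:20, 6)
    cn <- matrix(x, 1, dimnames = list("g", ids))
    rna <- matrix(y, 1, dimnames = list("g", ids))
    d <- dosage_correlations(cn, rna, rna, ids, method = "spearman", min_n = 3)
    expect_equal(d$r_cn_rna, spearman_formula(x, y))
  }
})

test_that("planted dosage drivers are recovered with low empirical FDR", {
  co <- simulate_cohort(sim_config(seed = 33))
  segs <- lapply(co$bins, segment_profile)
  cn <- gene_copy_number(segs, co$annotation)
  rna <- logcpm(co$rna_counts)
  crc <- co$metadata$sample_id[co$metadata$class == "CRC"]
  d <- dosage_correlations(cn, rna, co$protein, crc)
  truth <- co$truth$genes$gene[co$truth$genes$dosage_driver]
  pass <- d$gene[d$pass]
  expect_gte(mean(truth %in% pass), 0.8)
  expect_lte(mean(!(pass %in% truth)), 0.1)
})

test_that("arm direction summarises non-neutral calls within the group", {
  calls <- data.frame(
    sample_id = rep(paste0("s", 1:5), each = 2),
    arm_id = rep(c("8p", "20q"), 5),
    call = c("loss", "gain", "loss", "gain", "gain", "gain",
             "loss", "neutral", "neutral", "neutral"))
  expect_equal(direction_on_arm(calls, "8p"), "mixed")
  expect_equal(direction_on_arm(calls, "20q"), "gain_only")
  expect_equal(direction_on_arm(calls, "20q", samples = "s5"), "none")
  expect_error(direction_on_arm(calls, "13q"), "no calls")
})

test_that("nomination intersects cohorts on gain-only CAE arms", {
  recs <- function(genes, pass) {
    d <- data.frame(gene = genes, pass = pass)
    class(d) <- c("dosage_records", "data.frame")
    d
  }
  ann <- data.frame(gene = c("A", "B", "C", "X", "Y", "M"),
                    arm_id = c("20q", "20q", "20q", "5p", "20q", "8p"))
  dirs <- c("20q" = "gain_only", "8p" = "mixed", "5p" = "gain_only")
  aden <- recs(c("A", "B", "C", "X", "M"), rep(TRUE, 5))
  crc <- recs(c("A", "B", "C", "Y", "M"), rep(TRUE, 5))
  out <- nominate_drivers(aden, crc, dirs, ann)
  expect_setequal(out$gene[out$nominated], c("A", "B", "C"))
  expect_equal(sum(out$nominated), 3L)             # the three-gene overlap
  expect_false(out$nominated[out$gene == "X"])     # non-CAE arm
  expect_false(out$nominated[out$gene == "M"])     # mixed-direction 8p
  expect_false(out$nominated[out$gene == "Y"])     # CRC only
  # disjoint pass sets nominate nothing
  none <- nominate_drivers(recs("A", TRUE), recs("B", TRUE), dirs, ann)
  expect_equal(sum(none$nominated), 0L)
})

test_that("nomination is monotone in the pass sets", {
  recs <- function(genes) {
    d <- data.frame(gene = genes, pass = rep(TRUE, length(genes)))
    class(d) <- c("dosage_records", "data.frame")
    d
  }
  ann <- data.frame(gene = c("A", "B", "C"), arm_id = "20q")
  dirs <- c("20q" = "gain_only")
  before <- nominate_drivers(recs(c("A", "B")), recs(c("A", "B")), dirs, ann)
  after <- nominate_drivers(recs(c("A", "B", "C")), recs(c("A", "B", "C")),
                            dirs, ann)
  nominated_before <- before$gene[before$nominated]
  expect_true(all(nominated_before %in% after$gene[after$nominated]))
})
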