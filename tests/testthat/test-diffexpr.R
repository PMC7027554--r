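# logCPM, moderated differential expression, BH adjustment, gene ranking.

test_that("logcpm matches the stated formula and stays finite at zero", {
  counts <- matrix(c(10, 90, 10, 90), 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  lc <- logcpm(counts, pseudocount = 0.5)
  expect_equal(lc["a", "s1"], log2(10.5 / 101 * 1e6))
  expect_equal(lc["b", "s1"], log2(90.5 / 101 * 1e6))
  expect_equal(lc[, "s1"], lc[, "s2"])           # identical columns
  zero <- matrix(c(0, 50), 2, dimnames = list(c("a", "b"), "s1"))
  expect_true(all(is.finite(logcpm(zero))))
  expect_error(logcpm(matrix(c(0, 0), 2)), "all-zero")
})

test_that("moderated t reduces to the ordinary pooled t when variances are equal", {
  set.seed(2)
  m <- matrix(rnorm(80 * 12), 80, dimnames = list(NULL, paste0("s", 1:12)))
  A <- 1:6; B <- 7:12
  for (i in seq_len(nrow(m))) {      # force equal pooled variances
    ra <- m[i, A] - mean(m[i, A]); rb <- m[i, B] - mean(m[i, B])
    s <- sqrt((sum(ra^2) + sum(rb^2)) / 10)
    m[i, A] <- mean(m[i, A]) + ra / s
    m[i, B] <- mean(m[i, B]) + rb / s
  }
  de <- moderated_de(m, paste0("s", A), paste0("s", B))
  ord <- apply(m, 1, function(x) {
    s2 <- (sum((x[A] - mean(x[A]))^2) + sum((x[B] - mean(x[B]))^2)) / 10
    (mean(x[A]) - mean(x[B])) / sqrt(s2 * (1 / 6 + 1 / 6))
  })
  expect_equal(de$t, unname(ord), tolerance = 1e-12)
  expect_true(is.infinite(attr(de, "prior")$d0))
})

test_that("moderated statistics agree with the limma reference implementation", {
  set.seed(5)
  m <- matrix(rnorm(400 * 20, 5, 1), 400,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:20)))
  m[1:25, 1:10] <- m[1:25, 1:10] + 1.5
  m <- m * rep(runif(400, 0.5, 2), 20)          # gene-wise heteroskedasticity
  de <- moderated_de(m, paste0("s", 1:10), paste0("s", 11:20))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(1, 0), each = 10))))
  expect_equal(attr(de, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(de$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-6)
})

test_that("planted effects are recovered with controlled FDR", {
  set.seed(7)
  m <- matrix(rnorm(1000 * 20), 1000,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:20)))
  m[1:50, 1:10] <- m[1:50, 1:10] + 2
  de <- moderated_de(m, paste0("s", 1:10), paste0("s", 11:20))
  hit <- de$q <= 0.05
  expect_gte(mean(hit[1:50]), 0.9)
  expect_lte(sum(hit[-(1:50)]) / max(sum(hit), 1), 0.1)
})

test_that("protein-style missingness is gated per group and never imputed", {
  set.seed(8)
  m <- matrix(rnorm(50 * 10, 10), 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  m[1, 1:4] <- NA                                 # 1/5 observed in group A
  m[2, c(1, 6)] <- NA                             # 4/5 in both groups
  de <- moderated_de(m, paste0("s", 1:5), paste0("s", 6:10),
                     min_obs_frac = 0.6)
  expect_false(de$usable[1])
  expect_true(is.na(de$p[1]))
  expect_true(de$usable[2])
  expect_equal(de$n_A[2], 4L)
})

test_that("identical groups give t = 0 and p = 1", {
  m <- matrix(rep(c(5, 7, 6, 5, 7, 6), 3), 3, byrow = TRUE,
              dimnames = list(letters[1:3], paste0("s", 1:6)))
  de <- moderated_de(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de$t, rep(0, 3))
  expect_equal(de$p, rep(1, 3))
})

test_that("bh_adjust equals the brute-force step-up on enumerated grids", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  grid <- c(0.01, 0.2, 0.6, 1)
  for (len in 1:5) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    for (i in seq_len(nrow(combos))) {
      p <- combos[i, ]
      expect_equal(unname(bh_adjust(p)), bh_bruteforce(p))
    }
  }
  # NA handling: excluded from m, propagated in place
  q <- bh_adjust(c(0.02, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], bh_bruteforce(c(0.02, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("gene ranking is deterministic with documented tie-breaking", {
  de <- data.frame(gene = c("b", "a", "c", "d"),
                   logFC = c(2, 2, -1, 0.5),
                   t = 0, p = c(0.001, 0.001, 0.01, 1),
                   q = NA, n_A = 5, n_B = 5, usable = TRUE)
  rl <- rank_genes(de)
  expect_equal(rl$gene[1:2], c("a", "b"))          # tie broken by gene id
  expect_equal(rl$score[rl$gene == "d"], 0)        # p = 1 scores 0
  expect_equal(rl$gene[4], "c")                    # negative score last
  shuffled <- rank_genes(de[c(3, 1, 4, 2), ])
  expect_identical(rl, shuffled)
})
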