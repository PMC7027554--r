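# Ground-truth cohort generator.

test_that("the same config reproduces the full bundle bit for bit", {
  cfg <- tiny_sim(seed = 101)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the data
  c <- simulate_cohort(tiny_sim(seed = 102))
  expect_false(identical(a$rna_counts, c$rna_counts))
})

test_that("every planted HRA carries >= 2 CAEs; LRAs carry none and are MSS", {
  co <- simulate_cohort(tiny_sim(seed = 103))
  ts <- co$truth$samples
  expect_true(all(ts$n_planted_cae[ts$class == "HRA"] >= 2))
  expect_true(all(ts$n_planted_cae[ts$class == "LRA"] == 0))
  expect_true(all(ts$msi_status[ts$class %in% c("LRA", "HRA")] == "MSS"))
  expect_true(all(ts$n_planted_cae[ts$class == "normal"] == 0))
})

test_that("planted stroma medians sit at the configured class medians", {
  cfg <- sim_config()
  set.seed(105)
  expect_equal(median(sample_stroma(5000, "HRA", cfg)), 40.89,
               tolerance = 0.02)
  expect_equal(median(sample_stroma(5000, "LRA", cfg)), 27.20,
               tolerance = 0.02)
})

test_that("dosage effect has the closed-form fold change when noise vanishes", {
  # beta = 1, pure tumors, Poisson-limit counts, and no competing planted
  # effects (library composition stays comparable across classes): a
  # one-copy gain (CN log2 +0.585 vs 0) must shift RNA by the planted
  # multiplier 2^0.585
  cfg <- tiny_sim(seed = 106, nb_dispersion = 0,
                  purity = c(normal = 1, LRA = 1, HRA = 1, CRC = 1),
                  gain_copy_probs = 1,
                  n_de_up = 0, n_de_down = 0, n_stromal = 0, n_immune = 0,
                  n_planted_sets = 0)
  co <- simulate_cohort(cfg)
  tg <- co$truth$genes
  dg <- tg$gene[tg$dosage_driver & tg$arm_id == "20q"]
  at <- co$arm_truth[co$arm_truth$arm_id == "20q", ]
  gained <- at$sample_id[abs(at$planted_log2 - log2(1.5)) < 1e-9]
  flat <- at$sample_id[at$planted_log2 == 0]
  expect_gte(length(gained), 3)
  lc <- logcpm(co$rna_counts, pseudocount = 0.5)
  fc <- rowMeans(lc[dg, gained, drop = FALSE]) -
    rowMeans(lc[dg, flat, drop = FALSE])
  expect_equal(unname(2^fc), rep(1.5, length(dg)), tolerance = 0.1)
})

test_that("simulated counts match the configured NB mean and variance", {
  set.seed(107)
  mu <- 500; disp <- 0.05; n <- 4000
  x <- nb_counts(rep(mu, n), disp)
  expect_lt(abs(mean(x) / mu - 1), 0.05)
  expect_lt(abs(stats::var(x) / (mu + disp * mu^2) - 1), 0.05)
  # dispersion 0 degenerates to Poisson
  y <- nb_counts(rep(mu, n), 0)
  expect_lt(abs(stats::var(y) / mu - 1), 0.1)
})

test_that("planted LRAs always satisfy the stratifier rule at low noise", {
  cfg <- tiny_sim(seed = 108, bin_noise_sd = 0.05)
  co <- simulate_cohort(cfg)
  lra <- co$metadata$sample_id[co$metadata$class == "LRA"]
  for (id in lra) {
    seg <- segment_profile(co$bins[[id]])
    cae <- detect_caes(call_arms(seg, cfg$genome), sample_id = id)
    expect_equal(stratify_sample(cae, "MSS")$label, "LRA")
  }
})

test_that("MSI CRCs are planted with fewer copy-number events than MSS CRCs", {
  counts <- c(MSI = 0, MSS = 0); nsamp <- c(MSI = 0, MSS = 0)
  for (seed in 201:203) {
    ts <- simulate_cohort(tiny_sim(seed = seed))$truth$samples
    crc <- ts[ts$class == "CRC", ]
    for (st in c("MSI", "MSS")) {
      counts[st] <- counts[st] + sum(crc$n_planted_cae[crc$msi_status == st])
      nsamp[st] <- nsamp[st] + sum(crc$msi_status == st)
    }
  }
  expect_lt(counts["MSI"] / nsamp["MSI"], counts["MSS"] / nsamp["MSS"])
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(purity = c(normal = 1, LRA = 1.2, HRA = 0.7,
                                     CRC = 0.6)), "fractions")
  expect_error(sim_config(dosage_beta = -1), "beta")
  expect_error(sim_config(n_hra = -3), "counts")
  # more dosage genes than genes on CAE arms
  expect_error(simulate_cohort(tiny_sim(seed = 1, n_genes = 40,
                                        n_dosage_genes = 39)),
               "exceeds")
})
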