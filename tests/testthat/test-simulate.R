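test_that("simulation is deterministic and classes are structured as configured", {
  cfg <- small_sim_config()
  s1 <- simulate_study(cfg, seed = 9L)
  s2 <- simulate_study(cfg, seed = 9L)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sites, s2$sites)

  tr <- s1$truth
  expect_true(all(tr$class %in% c("neutral", "clinal", "inversion", "marker")))
  inv <- cfg$inversion
  expect_true(all(tr[class %in% c("inversion", "marker"),
                     arm == inv$arm & pos >= inv$start & pos <= inv$end]))
  # markers track the inversion frequency exactly
  mk <- tr[class == "marker"]
  expect_equal(mk$p_F, rep(inv$freqs[1], nrow(mk)))
  expect_equal(mk$p_M, rep(inv$freqs[3], nrow(mk)))
})

test_that("written simulation files are byte-identical under a fixed seed", {
  cfg <- small_sim_config(n_sites_per_arm = 300L)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_study(cfg, seed = 5L, dir = d1)
  simulate_study(cfg, seed = 5L, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("clinal truth frequencies rise monotonically with latitude", {
  tr <- small_sim()$truth[class == "clinal"]
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$p_F <= tr$p_P & tr$p_P <= tr$p_M))
  expect_true(all(tr$s1_true > 0 & tr$s2_true > 0))
})

test_that("a zero Balding-Nichols parameter collapses pools onto the ancestral frequency", {
  cfg <- small_sim_config(baseline_fst = 0, inversion = NULL,
                          clinal_frac = 0, n_sites_per_arm = 200L)
  tr <- simulate_frequencies(cfg, seed = 3L)
  expect_equal(tr$p_F, tr$p_P)
  expect_equal(tr$p_P, tr$p_M)
})

test_that("two-stage count sampling matches its sampling model", {
  pools1 <- pool_profiles("a", 10, 20L)
  cfg <- sim_config(pools = pools1, arms = c(X = 1e6),
                    n_sites_per_arm = 5000L, error_rate = 0,
                    baseline_fst = 0, clinal_frac = 0, inversion = NULL,
                    mean_coverage = 45)
  tr <- simulate_frequencies(cfg, seed = 11L)
  tr[, p_a := 0.5]  # fixed frequency for a clean expectation
  sites <- sample_pool_counts(tr, cfg, seed = 12L)
  cnt <- as.matrix(sites[, c("A_a", "T_a", "C_a", "G_a")])
  m <- rowSums(cnt)
  expect_true(all(m >= 1))  # zero-truncated depth
  alt_i <- match(tr$alt, c("A", "T", "C", "G"))
  altc <- cnt[cbind(seq_len(nrow(cnt)), alt_i)]
  fr <- altc / m
  # law of total expectation: mean read-level frequency ~ p within 3 SE
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se)

  # p = 0 with no error never produces alternate reads
  tr0 <- data.table::copy(tr)[, p_a := 0]
  s0 <- sample_pool_counts(tr0, cfg, seed = 13L)
  cnt0 <- as.matrix(s0[, c("A_a", "T_a", "C_a", "G_a")])
  expect_true(all(cnt0[cbind(seq_len(nrow(cnt0)), alt_i)] == 0))
})

test_that("pool-stage allele counts follow the binomial pmf", {
  pools1 <- pool_profiles("a", 10, 2L)
  cfg <- sim_config(pools = pools1, arms = c(X = 1e7),
                    n_sites_per_arm = 100000L, error_rate = 0,
                    baseline_fst = 0, clinal_frac = 0, inversion = NULL,
                    mean_coverage = 200)
  tr <- simulate_frequencies(cfg, seed = 21L)
  tr[, p_a := 0.5]
  sites <- sample_pool_counts(tr, cfg, seed = 22L)
  cnt <- as.matrix(sites[, c("A_a", "T_a", "C_a", "G_a")])
  m <- rowSums(cnt)
  alt_i <- match(tr$alt, c("A", "T", "C", "G"))
  fr <- cnt[cbind(seq_len(nrow(cnt)), alt_i)] / m
  # with n_chromosomes = 2 and p = 0.5, pool counts k in {0,1,2} with
  # probabilities (1/4, 1/2, 1/4); at depth ~200 the read frequency
  # concentrates near k/2, so classify and compare with the pmf
  k_hat <- round(fr * 2)
  ph <- tabulate(k_hat + 1L, 3) / length(k_hat)
  expect_equal(ph, c(0.25, 0.5, 0.25), tolerance = 0.02)
})

test_that("empirical pool frequencies converge to the truth without error", {
  cfg <- small_sim_config(error_rate = 0, mean_coverage = 100,
                          n_sites_per_arm = 3000L)
  sim <- simulate_study(cfg, seed = 31L)
  cnt_alt <- vapply(seq_len(nrow(sim$truth)), function(i) {
    as.numeric(sim$sites[[paste0(sim$truth$alt[i], "_F")]][i])
  }, numeric(1))
  m <- coverage_matrix(sim$sites, cfg$pools)[, 1]
  mad <- mean(abs(cnt_alt / m - sim$truth$p_F))
  # binomial noise at depth 100 from a pool of 78 chromosomes
  expect_lt(mad, 0.06)
})

test_that("simulated gene models are valid and within arm bounds", {
  cfg <- small_sim_config()
  gm <- simulate_gene_models(cfg, seed = 2L)
  g <- gm$genes
  expect_true(all(g$start <= g$end))
  expect_true(all(g$end <= cfg$arms[g$arm]))
  cds_len <- gm$cds[, .(len = sum(end - start + 1)), by = isoform]
  expect_true(all(cds_len$len %% 3 == 0))
  # features nest inside their gene span
  feat <- rbind(gm$exons, gm$cds[, !"phase"], gm$utr5, gm$utr3)
  j <- merge(feat, g, by = "gene_id", suffixes = c("", ".g"))
  expect_true(all(j$start >= j$start.g & j$end <= j$end.g))
})

test_that("truth table row count equals simulated site count", {
  sim <- small_sim()
  expect_equal(nrow(sim$truth), nrow(sim$sites))
})
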