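test_that("coverage caps follow the empirical quantile definition", {
  pools1 <- pool_profiles("a", 10, 10L)
  rows <- lapply(1:100, function(i) list(arm = "X", pos = i,
                                         counts = list(c(i, 0, 0, 0))))
  sites <- make_sites(rows, pools1)
  expect_equal(unname(compute_coverage_caps(sites, pools1, 0.02)["a"]), 98L)

  rows45 <- lapply(1:50, function(i) list(arm = "X", pos = i,
                                          counts = list(c(45, 0, 0, 0))))
  expect_equal(unname(compute_coverage_caps(make_sites(rows45, pools1),
                                            pools1)["a"]), 45L)
  expect_error(compute_coverage_caps(make_sites(list(), pools1), pools1),
               "zero sites")
})

test_that("the pooled minimum allele count rule decides polymorphism", {
  pools <- study_pools()
  cfg <- filter_config(caps = c(F = 1000L, P = 1000L, M = 1000L))
  # pooled A:120, T:6 -> SNP; A:120, T:5 -> not polymorphic
  sites <- make_sites(list(
    list(arm = "X", pos = 10, counts = list(c(40, 2, 0, 0), c(40, 2, 0, 0),
                                            c(40, 2, 0, 0))),
    list(arm = "X", pos = 20, counts = list(c(40, 2, 0, 0), c(40, 2, 0, 0),
                                            c(40, 1, 0, 0)))
  ), pools)
  snps <- call_snps(sites, pools, cfg)
  expect_equal(snps$pos, 10L)
  expect_equal(snps$major, "A")
  expect_equal(snps$minor, "T")
  expect_false(snps$multiallelic)
})

test_that("multiallelic sites keep the two most frequent alleles and flag it", {
  pools <- study_pools()
  cfg <- filter_config(caps = c(F = 1000L, P = 1000L, M = 1000L))
  sites <- make_sites(list(
    list(arm = "X", pos = 5, counts = list(c(20, 10, 3, 0), c(20, 10, 3, 0),
                                           c(10, 10, 2, 0)))
  ), pools)
  snps <- call_snps(sites, pools, cfg)
  expect_equal(snps$major, "A")   # 50 total
  expect_equal(snps$minor, "T")   # 30 total, C = 8 dropped
  expect_true(snps$multiallelic)
  expect_equal(snps$maj_M, 10)
  expect_equal(snps$min_M, 10)
  # coverage still counts all four nucleotides
  expect_equal(snps$cov_F, 33)
})

test_that("low coverage in any single pool drops the site", {
  pools <- study_pools()
  cfg <- filter_config(caps = c(F = 1000L, P = 1000L, M = 1000L))
  sites <- make_sites(list(
    list(arm = "X", pos = 1, counts = list(c(30, 10, 0, 0), c(30, 10, 0, 0),
                                           c(7, 2, 0, 0)))
  ), pools)
  expect_equal(nrow(call_snps(sites, pools, cfg)), 0L)
})

test_that("major/minor ties break alphabetically", {
  pools <- study_pools()
  cfg <- filter_config(caps = c(F = 1000L, P = 1000L, M = 1000L))
  sites <- make_sites(list(
    list(arm = "X", pos = 1, counts = list(c(0, 10, 0, 10), c(0, 10, 0, 10),
                                           c(0, 10, 0, 10)))
  ), pools)
  snps <- call_snps(sites, pools, cfg)
  expect_equal(snps$major, "G")  # G before T alphabetically
  expect_equal(snps$minor, "T")
})

test_that("region masks include and exclude sites as configured", {
  pools <- study_pools()
  base <- list(counts = list(c(30, 10, 0, 0), c(30, 10, 0, 0),
                             c(30, 10, 0, 0)))
  sites <- make_sites(list(
    c(list(arm = "X", pos = 100), base),
    c(list(arm = "X", pos = 200), base),
    c(list(arm = "X", pos = 300), base)
  ), pools)
  inc <- data.table::data.table(arm = "X", start = 50L, end = 250L)
  exc <- data.table::data.table(arm = "X", start = 150L, end = 250L)
  cfg <- filter_config(region_include = inc, region_exclude = exc,
                       caps = c(F = 1000L, P = 1000L, M = 1000L))
  snps <- call_snps(sites, pools, cfg)
  expect_equal(snps$pos, 100L)
})

test_that("filtering is idempotent with fixed caps", {
  sim <- small_sim()
  pools <- study_pools()
  caps <- compute_coverage_caps(sim$sites, pools)
  cfg <- filter_config(caps = caps)
  snps1 <- call_snps(sim$sites, pools, cfg)
  # re-filter the sites that passed: all of them must pass again
  passed <- sim$sites[paste(arm, pos) %in% paste(snps1$arm, snps1$pos)]
  snps2 <- call_snps(passed, pools, cfg)
  expect_equal(nrow(snps2), nrow(snps1))
  expect_equal(snps2$pos, snps1$pos)
})

test_that("planted SNPs with ample minor counts pass the filter", {
  cfg <- small_sim_config(error_rate = 0)
  sim <- simulate_study(cfg, seed = 77L)
  pools <- study_pools()
  caps <- compute_coverage_caps(sim$sites, pools)
  snps <- call_snps(sim$sites, pools, filter_config(caps = caps))
  # truth sites with expected pooled minor count >= 3 * b_total
  covm <- coverage_matrix(sim$sites, pools)
  exp_minor <- rowSums(vapply(seq_len(nrow(pools)), function(p) {
    pp <- sim$truth[[paste0("p_", pools$label[p])]]
    pmin(pp, 1 - pp) * covm[, p]
  }, numeric(nrow(sim$truth))))
  ok_cov <- rowSums(covm >= 10 & covm <= rep(caps, each = nrow(covm))) == 3
  strong <- which(exp_minor >= 18 & ok_cov)
  called <- paste(sim$truth$arm[strong], sim$truth$pos[strong]) %in%
    paste(snps$arm, snps$pos)
  expect_gte(mean(called), 0.99)
})
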