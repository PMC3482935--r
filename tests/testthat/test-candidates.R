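test_that("outlier selection flags exactly floor(tail * N), deterministically under ties", {
  set.seed(2)
  fst <- runif(10000)
  flags <- select_outliers(fst, 0.005)
  expect_equal(sum(flags), 50L)
  expect_true(min(fst[flags]) >= max(fst[!flags]) - 1e-12 ||
                sum(fst > min(fst[flags])) < 50)

  expect_warning(f2 <- select_outliers(runif(100), 0.005), "zero")
  expect_equal(sum(f2), 0L)

  # ties spanning the cutoff: resolved by smaller p then coordinates
  fst_t <- c(1, 1, 1, 1, rep(0, 96))
  p_t <- c(0.5, 0.01, 0.2, 0.01, rep(1, 96))
  pos_t <- seq_along(fst_t)
  f3 <- select_outliers(fst_t, 0.02, fet_p = p_t, arm = rep("X", 100),
                        pos = pos_t)
  expect_equal(sum(f3), 2L)
  expect_equal(which(f3), c(2L, 4L))  # smallest p, then position

  expect_error(select_outliers(rep(NA_real_, 5), 0.5), "no defined")
})

test_that("the exact test agrees with enumeration and with fisher.test", {
  expect_equal(fet_pvalues(10, 0, 0, 10), 2 / choose(20, 10))
  expect_equal(fet_pvalues(5, 5, 5, 5), 1)
  # transposition symmetry
  expect_equal(fet_pvalues(7, 2, 3, 9), fet_pvalues(7, 3, 2, 9))
  # degenerate margins
  expect_equal(fet_pvalues(0, 0, 5, 5), 1)
  expect_equal(fet_pvalues(0, 0, 0, 0), 1)

  set.seed(3)
  for (i in 1:50) {
    a <- rpois(1, 8); b <- rpois(1, 5); cc <- rpois(1, 5); d <- rpois(1, 8)
    expect_equal(fet_pvalues(a, b, cc, d), enum_fet(a, b, cc, d),
                 tolerance = 1e-12)
    expect_equal(fet_pvalues(a, b, cc, d),
                 stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH q-values reproduce the hand-computed step-up and dominate p", {
  expect_equal(fdr_qvalues(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5))
  expect_equal(fdr_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_qvalues(0.037), 0.037)
  set.seed(4)
  p <- runif(500)^2
  q <- fdr_qvalues(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # Storey rescale never exceeds BH
  expect_true(all(fdr_qvalues(p, pi0 = "storey") <= q + 1e-12))
})

test_that("SNP-to-gene assignment honours the 1-kb flank boundary exactly", {
  genes <- data.table::data.table(gene_id = c("gA", "gB"), arm = "X",
                                  start = c(5000L, 5600L),
                                  end = c(5500L, 6000L))
  asg <- assign_genes(rep("X", 4), c(4000L, 3999L, 5700L, 8000L), genes)
  # 4000 = start - 1000 -> assigned; 3999 -> not
  expect_true(any(asg$snp_idx == 1 & asg$gene_id == "gA"))
  expect_false(any(asg$snp_idx == 2))
  # inside two overlapping flanked genes -> both
  expect_setequal(asg[snp_idx == 3, gene_id], c("gA", "gB"))
  expect_false(any(asg$snp_idx == 4))
})

test_that("candidate flags require both outlier status and FDR significance", {
  snps <- small_snps()
  pools <- study_pools()
  cands <- call_candidates(snps, pools)
  expect_true(all(cands[candidate == TRUE, outlier]))
  expect_true(all(cands[candidate == TRUE, q < 0.01]))
  per_pair <- cands[, sum(outlier), by = pair]$V1
  expect_true(all(per_pair == floor(0.005 * nrow(snps))))
})

test_that("overlap metrics and the set-overlap permutation test behave at the extremes", {
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_fraction(c("a"), c("b", "c")), 0)
  b100 <- sprintf("g%03d", 1:100)
  expect_equal(overlap_fraction(b100[1:22], b100), 0.22)
  expect_true(is.na(overlap_fraction("a", character())))

  uni <- sprintf("g%03d", 1:1000)
  res <- compare_candidate_sets(uni[1:10], uni[500:509], uni,
                                n_perm = 200L, seed = 1L)
  expect_equal(res$overlap, 0)
  expect_gt(res$p, 0.9)

  res2 <- compare_candidate_sets(uni[1:10], uni[6:15], uni, n_perm = 999L,
                                 seed = 1L)
  expect_equal(res2$overlap, 0.5)
  expect_lte(res2$p, 0.005)

  res3 <- compare_candidate_sets(uni, uni, uni, n_perm = 10L, seed = 1L)
  expect_equal(res3$overlap, 1)
  expect_equal(res3$p, 1)
  expect_error(compare_candidate_sets(uni[1:2], uni[1:2], uni, n_perm = 0),
               "n_perm")
})
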