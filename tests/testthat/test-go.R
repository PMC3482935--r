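toy_go_world <- function(n_long = 10L, n_short = 10L, snps_per_long = 50L,
                         snps_per_short = 5L, seed = 1L) {
  set.seed(seed)
  # long genes hold 10x the SNPs of short genes, on one arm, non-overlapping
  genes <- data.table::data.table(
    gene_id = sprintf("g%02d", seq_len(n_long + n_short)),
    arm = "X",
    start = seq(1L, by = 20000L, length.out = n_long + n_short))
  genes[, end := start + c(rep(10000L, n_long), rep(1000L, n_short))]
  genes[, n_snps := c(rep(snps_per_long, n_long), rep(snps_per_short, n_short))]
  snp_rows <- data.table::rbindlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i]
    # keep SNPs > 1 kb inside the gene so each maps to exactly one gene
    span <- (g$end - g$start) - 2L
    data.table::data.table(pos = g$start + 1L + sort(sample.int(span, g$n_snps)))
  }))
  go_map <- list("GO:LONG" = genes$gene_id[seq_len(n_long)],
                 "GO:SHORT" = genes$gene_id[n_long + seq_len(n_short)],
                 "GO:MIX" = genes$gene_id[c(1:5, n_long + 1:5)],
                 "GO:TINY" = genes$gene_id[1:2])
  list(genes = genes[, .(gene_id, arm, start, end)],
       snp_arm = rep("X", nrow(snp_rows)), snp_pos = snp_rows$pos,
       go_map = go_map)
}

test_that("degenerate candidate sets give p = 1 everywhere", {
  w <- toy_go_world()
  # candidates = all SNPs: every permutation reproduces the observation
  res <- go_permutation_test(seq_along(w$snp_pos), w$snp_arm, w$snp_pos,
                             w$genes, w$go_map, n_perm = 100L, seed = 2L)
  expect_true(all(res$p == 1))
  # categories below min_genes are dropped
  expect_false("GO:TINY" %in% res$go)

  # a category that no candidate hits: p = 1
  short_snps <- which(w$snp_pos > w$genes$start[11])
  res2 <- go_permutation_test(short_snps[1:5], w$snp_arm, w$snp_pos,
                              w$genes, w$go_map, n_perm = 200L, seed = 2L)
  expect_equal(res2[go == "GO:LONG", observed], 0L)
  expect_equal(res2[go == "GO:LONG", p], 1)
})

test_that("the permutation test is deterministic under a fixed seed", {
  w <- toy_go_world()
  r1 <- go_permutation_test(1:30, w$snp_arm, w$snp_pos, w$genes, w$go_map,
                            n_perm = 300L, seed = 7L)
  r2 <- go_permutation_test(1:30, w$snp_arm, w$snp_pos, w$genes, w$go_map,
                            n_perm = 300L, seed = 7L)
  expect_identical(r1, r2)
})

test_that("adding a candidate SNP in a category's gene cannot raise its p", {
  w <- toy_go_world()
  # candidate sets differing by one SNP inside a GO:SHORT gene
  base <- c(1:20)
  extra_snp <- which(w$snp_pos > w$genes$start[15] &
                       w$snp_pos < w$genes$end[15])[1]
  r_base <- go_permutation_test(base, w$snp_arm, w$snp_pos, w$genes,
                                w$go_map, n_perm = 500L, seed = 9L)
  r_more <- go_permutation_test(c(base, extra_snp), w$snp_arm, w$snp_pos,
                                w$genes, w$go_map, n_perm = 500L, seed = 9L)
  expect_gte(r_more[go == "GO:SHORT", observed],
             r_base[go == "GO:SHORT", observed])
  # the permutation null barely moves, so the p-value cannot rise materially
  expect_lte(r_more[go == "GO:SHORT", p],
             r_base[go == "GO:SHORT", p] + 0.1)
})

test_that("permutation nulls absorb gene-length bias that the hypergeometric test inherits", {
  w <- toy_go_world()
  n_snp <- length(w$snp_pos)
  set.seed(11)
  perm_p <- numeric(40)
  naive_p <- numeric(40)
  for (i in 1:40) {
    cand <- sample.int(n_snp, 40)
    res <- go_permutation_test(cand, w$snp_arm, w$snp_pos, w$genes,
                               w$go_map, n_perm = 400L, seed = 100L + i)
    perm_p[i] <- res[go == "GO:LONG", p]
    cand_genes <- unique(assign_genes(w$snp_arm[cand], w$snp_pos[cand],
                                      w$genes)$gene_id)
    naive <- go_hypergeometric_test(cand_genes, w$genes$gene_id, w$go_map)
    naive_p[i] <- naive[go == "GO:LONG", p]
  }
  # random SNP draws hit mostly long genes: the naive gene-level test calls
  # the long category enriched far too often, the permutation test does not
  expect_gt(mean(naive_p < 0.05), 0.3)
  expect_lt(mean(perm_p < 0.05), 0.2)
})
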