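toy_gene_models <- function() {
  # gPlus: + strand, CDS 101..112 (ATG GGA AAA TAA)
  # gMinus: - strand, CDS 301..312, sequence given in transcription
  #         orientation (reverse complement of the genomic span)
  genes <- data.table::data.table(
    gene_id = c("gPlus", "gMinus"),
    arm = "X", strand = c("+", "-"),
    start = c(51L, 251L), end = c(162L, 362L))
  cds <- data.table::data.table(
    gene_id = c("gPlus", "gMinus"),
    isoform = c("gPlus.t1", "gMinus.t1"),
    arm = "X", start = c(101L, 301L), end = c(112L, 312L), phase = 0L)
  exons <- data.table::data.table(
    gene_id = c("gPlus", "gMinus"),
    isoform = c("gPlus.t1", "gMinus.t1"),
    arm = "X", start = c(61L, 261L), end = c(152L, 352L))
  utr5 <- data.table::data.table(
    gene_id = "gPlus", isoform = "gPlus.t1", arm = "X",
    start = 61L, end = 100L)
  utr3 <- data.table::data.table(
    gene_id = "gPlus", isoform = "gPlus.t1", arm = "X",
    start = 113L, end = 152L)
  list(genes = genes, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
}

toy_cds_seqs <- function() {
  c(gPlus = "ATGGGAAAATAA",
    # genomic 301..312 reads TTATTTTCCCAT; transcription orientation:
    gMinus = "ATGGGAAAATAA")
}

mk_snp <- function(pos, ref, alt) {
  data.table::data.table(arm = "X", pos = pos, ref = ref, major = ref,
                         minor = alt)
}

test_that("codon translation separates synonymous from nonsynonymous changes", {
  gm <- toy_gene_models()
  seqs <- toy_cds_seqs()
  # + strand: codon 2 is GGA at 104..106; third-position A->G is Gly->Gly
  eff <- classify_snps(mk_snp(106L, "A", "G"), gm, seqs)
  expect_equal(eff$feature, "synonymous_coding")
  expect_equal(eff$gene_id, "gPlus")
  # codon 3 is AAA at 107..109; first-position A->G is Lys->Glu
  eff2 <- classify_snps(mk_snp(107L, "A", "G"), gm, seqs)
  expect_equal(eff2$feature, "nonsynonymous_coding")
})

test_that("minus-strand codons are resolved in transcription orientation", {
  gm <- toy_gene_models()
  seqs <- toy_cds_seqs()
  # gMinus CDS occupies 301..312; transcription runs 312 -> 301.
  # offset of genomic position 307 is 312-307 = 5 (third base of codon 2,
  # i.e. the A of GGA); genomic base there is complement T.
  eff <- classify_snps(mk_snp(307L, "T", "C"), gm, seqs)
  # alt C complements to G: GGA -> GGG, synonymous
  expect_equal(eff$feature, "synonymous_coding")
  # offset of 306 is 6: first base of codon 3 (A of AAA); genomic T.
  # alt C -> transcribed G: AAA -> GAA, nonsynonymous
  eff2 <- classify_snps(mk_snp(306L, "T", "C"), gm, seqs)
  expect_equal(eff2$feature, "nonsynonymous_coding")
})

test_that("feature precedence and intergenic distance rules hold", {
  gm <- toy_gene_models()
  seqs <- toy_cds_seqs()
  # UTRs beat intron
  expect_equal(classify_snps(mk_snp(80L, "A", "T"), gm, seqs)$feature, "utr5")
  expect_equal(classify_snps(mk_snp(120L, "A", "T"), gm, seqs)$feature, "utr3")
  # inside the gene span but no exon feature: intron
  expect_equal(classify_snps(mk_snp(155L, "A", "T"), gm, seqs)$feature,
               "intron")
  # upstream of gPlus (+): before start within 1 kb
  expect_equal(classify_snps(mk_snp(40L, "A", "T"), gm, seqs)$feature,
               "upstream_1kb")
  # upstream of gMinus (-): after its end
  expect_equal(classify_snps(mk_snp(400L, "A", "T"), gm, seqs)$feature,
               "upstream_1kb")
  # between the genes: gPlus downstream (+) wins over nothing else at 200
  expect_equal(classify_snps(mk_snp(200L, "A", "T"), gm, seqs)$feature,
               "downstream_1kb")
  # far away: intergenic
  expect_equal(classify_snps(mk_snp(5000L, "A", "T"), gm, seqs)$feature,
               "intergenic")
  # intron in one gene beats downstream of another: SNP at 155 is intronic
  # in gPlus and < 1 kb downstream of nothing else here, covered above
})

test_that("a reference/CDS mismatch falls into the other category", {
  gm <- toy_gene_models()
  seqs <- toy_cds_seqs()
  # position 106 truly holds A; claim ref = C
  eff <- classify_snps(mk_snp(106L, "C", "G"), gm, seqs)
  expect_equal(eff$feature, "other")
})

test_that("classification is order-independent and single-valued", {
  gm <- toy_gene_models()
  seqs <- toy_cds_seqs()
  snps <- data.table::rbindlist(list(
    mk_snp(106L, "A", "G"), mk_snp(80L, "A", "T"), mk_snp(5000L, "A", "T")))
  e1 <- classify_snps(snps, gm, seqs)
  gm2 <- gm
  gm2$genes <- gm$genes[2:1]
  e2 <- classify_snps(snps, gm2, seqs)
  expect_equal(e1$feature, e2$feature)
  expect_equal(nrow(e1), nrow(snps))
})

test_that("feature enrichment tests match an independent contingency oracle", {
  cand <- c(rep("nonsynonymous_coding", 40), rep("intron", 160))
  bg <- c(rep("nonsynonymous_coding", 100), rep("intron", 1900))
  fe <- feature_enrichment(cand, bg)
  row <- fe[feature == "nonsynonymous_coding"]
  expect_equal(row$direction, "over")
  ct <- stats::chisq.test(matrix(c(40, 160, 100, 1900), 2, byrow = TRUE),
                          correct = FALSE)
  expect_equal(row$p, ct$p.value)
  expect_equal(row$statistic, unname(ct$statistic))
  expect_true(row$significant)

  # identical proportions: p ~ 1, no direction call needed
  fe2 <- feature_enrichment(c(rep("intron", 50), rep("utr5", 50)),
                            c(rep("intron", 500), rep("utr5", 500)))
  expect_gt(fe2[feature == "intron", p], 0.99)

  # small expected counts fall back to the exact test
  fe3 <- feature_enrichment(c(rep("utr5", 0), rep("intron", 100)),
                            c(rep("utr5", 8), rep("intron", 392)))
  expect_equal(fe3[feature == "utr5", method], "fisher")
  expect_equal(fe3[feature == "utr5", direction], "under")
  expect_equal(fe3[feature == "utr5", p], fet_pvalues(0, 100, 8, 392))
})

test_that("feature proportions over any SNP set sum to one", {
  snps <- small_snps()
  sim <- small_sim()
  set.seed(1)
  seqs <- clinepool:::random_cds_seqs(sim$gene_models, sim$truth)
  eff <- classify_snps(snps[1:500], sim$gene_models, seqs)
  expect_equal(nrow(eff), 500L)
  expect_equal(sum(table(eff$feature)), 500L)
  expect_true(all(eff$feature %in% clinepool:::FEATURE_LEVELS))
})
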