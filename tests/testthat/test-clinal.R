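mk_clinal_snps <- function(freqs, cov = 40L) {
  # one SNP with the given minor-allele frequencies in F, P, M
  minc <- as.integer(round(freqs * cov))
  data.table::data.table(
    arm = "X", pos = 1L, ref = "A", major = "A", minor = "T",
    multiallelic = FALSE,
    cov_F = cov, maj_F = cov - minc[1], min_F = minc[1], freq_F = minc[1] / cov,
    cov_P = cov, maj_P = cov - minc[2], min_P = minc[2], freq_P = minc[2] / cov,
    cov_M = cov, maj_M = cov - minc[3], min_M = minc[3], freq_M = minc[3] / cov)
}

test_that("slopes follow the latitude arithmetic of the three-pool design", {
  rec <- orient_and_slopes(mk_clinal_snps(c(0.10, 0.30, 0.50)), study_pools())
  expect_equal(rec$s1, 0.2 / (39.88 - 25.53))
  expect_equal(rec$s2, 0.2 / (44.02 - 39.88))
  expect_equal(rec$class, "++")
  expect_equal(rec$allele, "T")
  expect_equal(rec$freq_F, 0.10)
  expect_equal(rec$freq_M, 0.50)
})

test_that("orientation keeps the allele rising northwards and handles ties", {
  # minor falls south->north: the major allele is oriented instead
  rec <- orient_and_slopes(mk_clinal_snps(c(0.5, 0.3, 0.1)), study_pools())
  expect_equal(rec$allele, "A")
  expect_equal(rec$freq_F, 0.5)
  expect_equal(rec$freq_M, 0.9)
  expect_equal(rec$class, "++")

  # equal end frequencies: orientation tie -> class tie
  rec2 <- orient_and_slopes(mk_clinal_snps(c(0.3, 0.5, 0.3)), study_pools())
  expect_equal(rec2$class, "tie")

  # dip in the middle with a net rise: -+
  rec3 <- orient_and_slopes(mk_clinal_snps(c(0.5, 0.2, 0.6)), study_pools())
  expect_equal(rec3$allele, "T")
  expect_lt(rec3$s1, 0)
  expect_gt(rec3$s2, 0)
  expect_equal(rec3$class, "-+")

  expect_error(orient_and_slopes(mk_clinal_snps(c(0.1, 0.5, 0.9)),
                                 study_pools()[1:2]), "three pools")
})

test_that("orienting an already-oriented record changes nothing", {
  snps <- small_snps()
  r1 <- orient_and_slopes(snps, study_pools())
  # re-derive from the oriented frequencies: the oriented allele already
  # satisfies freq_M >= freq_F, so a second pass keeps every choice
  expect_true(all(r1$freq_M >= r1$freq_F))
  r2 <- orient_and_slopes(snps, study_pools())
  expect_identical(r1, r2)
})

test_that("trajectory classes partition the records", {
  cl <- orient_and_slopes(small_snps(), study_pools())
  expect_true(all(cl$class %in% c("++", "+-", "-+", "--", "tie")))
  expect_equal(sum(table(cl$class)), nrow(cl))
  # orientation guarantees no strictly falling trajectories
  expect_equal(sum(cl$class == "--"), 0L)
})

test_that("Clopper-Pearson limits match closed forms and the Beta oracle", {
  ci <- binomial_ci(c(0L, 20L, 10L), c(20L, 20L, 20L))
  expect_equal(ci[1, "lo"], c(lo = 0))
  expect_equal(ci[1, "hi"], c(hi = 1 - 0.025^(1 / 20)), tolerance = 1e-9)
  expect_equal(ci[2, ], c(lo = 0.025^(1 / 20), hi = 1), tolerance = 1e-9)
  # x = 10, n = 20: symmetric interval from the Beta quantile oracle
  expect_equal(unname(ci[3, ]),
               c(qbeta(0.025, 10, 11), qbeta(0.975, 11, 10)),
               tolerance = 1e-12)
  expect_equal(unname(round(ci[3, ], 5)), c(0.27196, 0.72804))
  expect_error(binomial_ci(1, 0), "n >= 1")
})

test_that("significance demands class ++ and disjoint intervals in all pairs", {
  # far-apart frequencies at high coverage: significant
  rec <- orient_and_slopes(mk_clinal_snps(c(0.05, 0.45, 0.90), cov = 200L),
                           study_pools())
  expect_equal(rec$class, "++")
  expect_true(rec$significant)

  # same trajectory at low coverage: intervals overlap, not significant
  rec2 <- orient_and_slopes(mk_clinal_snps(c(0.30, 0.40, 0.50), cov = 20L),
                            study_pools())
  expect_equal(rec2$class, "++")
  expect_false(rec2$significant)
})

test_that("touching confidence intervals are not disjoint", {
  # engineered: F interval hi equals P interval lo is practically impossible
  # with real qbeta values, so verify via the rule on a borderline case:
  # two pools with identical counts share identical intervals -> overlap
  rec <- orient_and_slopes(mk_clinal_snps(c(0.3, 0.3, 0.6), cov = 30L),
                           study_pools())
  expect_false(rec$significant)
})

test_that("the core clinal set unions ++ candidates across pairs", {
  clinal <- data.table::data.table(
    arm = "X", pos = 1:4, class = c("++", "++", "+-", "++"))
  cand <- data.table::data.table(
    pair = c("FM", "PM", "FM", "FP"),
    arm = "X", pos = c(1L, 1L, 3L, 5L),
    candidate = TRUE)
  core <- core_clinal_set(clinal, cand)
  # SNP 1 qualifies twice but appears once; SNP 3 is +-; SNP 5 not ++
  expect_equal(core$pos, 1L)
  expect_equal(core$pairs, "FM,PM")
})

test_that("under the ++ ordering, disjoint consecutive intervals imply disjoint ends", {
  snps <- small_snps()
  rec <- orient_and_slopes(snps, study_pools())
  pp <- rec[class == "++"]
  consec <- pp$hi_F < pp$lo_P & pp$hi_P < pp$lo_M
  ends <- pp$hi_F < pp$lo_M
  expect_true(all(!consec | ends))
})
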