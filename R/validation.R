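#' Calibration experiments for the pool-seq estimators
#'
#' These functions re-run the package's estimators on synthetic data drawn
#' under known truth and return the calibration quantities: they back the
#' package's validation suite and the reproduction script. All are
#' deterministic given `seed`.
#'
#' @name calibration
NULL

# zero-truncated Poisson depths
rdepth <- function(n, lambda, min = 1L) {
  stats::qpois(stats::runif(n, stats::ppois(min - 1L, lambda), 1), lambda)
}

#' @describeIn calibration Unbiasedness of the corrected per-site pi under
#'   two-stage sampling (pool counts binomial in the pool size, reads
#'   binomial in the pool frequency): mean of pi_site over `n_sites`
#'   replicate sites against the true expected pairwise diversity
#'   2 E[p(1-p)], with the Monte-Carlo standard error.
#' @param seed Integer seed.
#' @param n_sites Number of replicate sites.
#' @param n_chromosomes Pool size in chromosomes.
#' @param mean_coverage Mean sequencing depth.
#' @export
calibrate_pi <- function(seed = 1L, n_sites = 100000L, n_chromosomes = 78L,
                         mean_coverage = 45) {
  set.seed(seed)
  p <- stats::runif(n_sites, 0.05, 0.95)
  k <- stats::rbinom(n_sites, n_chromosomes, p)
  m <- rdepth(n_sites, mean_coverage, min = 2L)
  x <- stats::rbinom(n_sites, m, k / n_chromosomes)
  pi_hat <- pi_site(cbind(x, m - x), n_chromosomes)
  truth <- mean(2 * p * (1 - p))
  list(pi_mean = mean(pi_hat), pi_truth = truth,
       se = stats::sd(pi_hat) / sqrt(n_sites),
       z = abs(mean(pi_hat) - truth) / (stats::sd(pi_hat) / sqrt(n_sites)),
       n = n_sites)
}

#' @describeIn calibration Recovery of the per-site mutation parameter
#'   theta by the detectability-corrected Watterson estimator: sites are
#'   polymorphic in the pool sample with probability theta * a_n (allele
#'   count i with weight 1/i), reads are resampled, and a site counts as
#'   segregating when both alleles reach the minimum count `b`.
#' @param theta True per-site theta.
#' @param b Minimum allele count.
#' @export
calibrate_theta <- function(seed = 1L, n_sites = 100000L, theta = 0.01,
                            n_chromosomes = 78L, mean_coverage = 45,
                            b = 2L) {
  set.seed(seed)
  i_all <- seq_len(n_chromosomes - 1)
  a_n <- sum(1 / i_all)
  poly <- stats::runif(n_sites) < theta * a_n
  m <- rdepth(n_sites, mean_coverage, min = 2L * b)
  x <- integer(n_sites)
  if (any(poly)) {
    i <- sample(i_all, sum(poly), replace = TRUE, prob = 1 / i_all)
    x[poly] <- stats::rbinom(sum(poly), m[poly], i / n_chromosomes)
  }
  seg <- pmin(x, m - x) >= b
  astar <- watterson_denominator_cached(n_chromosomes, m, b)
  theta_hat <- mean(seg / astar)
  list(theta_hat = theta_hat, theta_truth = theta,
       rel_error = abs(theta_hat - theta) / theta, n = n_sites)
}

#' @describeIn calibration Differentiation calibration on a neutral
#'   Balding-Nichols background at the study design's coverage: SNP-wise
#'   F_ST between the southern and northern pools over `n_sites` called
#'   SNPs, summarised by the per-SNP median and by the ratio-of-averages
#'   form sum(pi_total - pi_within)/sum(pi_total), together with the
#'   truth-level (frequency-based) median. Note the expected Gst of two
#'   demes each at divergence F from their common ancestor is
#'   (F/2)/(1 - F/2), not F.
#' @param f Balding-Nichols differentiation parameter.
#' @export
calibrate_fst <- function(seed = 1L, n_sites = 50000L, f = 0.02) {
  pools <- study_pools()[c(1, 3)]
  cfg <- sim_config(pools = pools, arms = c(A = n_sites * 100),
                    n_sites_per_arm = n_sites, baseline_fst = f,
                    clinal_frac = 0, inversion = NULL)
  truth <- simulate_frequencies(cfg, seed)
  sites <- sample_pool_counts(truth, cfg, seed + 1L)
  caps <- compute_coverage_caps(sites, pools)
  snps <- call_snps(sites, pools, filter_config(caps = caps))
  fst <- fst_site(snps, pools, 1, 2)

  li <- pools$label[1]; lj <- pools$label[2]
  ci <- cbind(snps[[paste0("maj_", li)]], snps[[paste0("min_", li)]])
  cj <- cbind(snps[[paste0("maj_", lj)]], snps[[paste0("min_", lj)]])
  pw <- (pi_site(ci, pools$n_chromosomes[1]) +
           pi_site(cj, pools$n_chromosomes[2])) / 2
  pt <- pi_site(ci + cj, sum(pools$n_chromosomes))
  p1 <- truth[[paste0("p_", li)]]; p2 <- truth[[paste0("p_", lj)]]
  piw_t <- p1 * (1 - p1) + p2 * (1 - p2)
  pbar <- (p1 + p2) / 2
  pit_t <- 2 * pbar * (1 - pbar)
  fst_t <- (pit_t - piw_t) / pit_t
  list(f = f,
       median_fst = stats::median(fst, na.rm = TRUE),
       ratio_fst = sum(pt - pw, na.rm = TRUE) / sum(pt, na.rm = TRUE),
       truth_median_fst = stats::median(fst_t[pit_t > 0]),
       expected_gst = (f / 2) / (1 - f / 2),
       n = nrow(snps))
}

#' @describeIn calibration Parameter recovery of the candidate pipeline:
#'   `n_clinal` planted clinal SNPs (frequency change `delta_p` across the
#'   cline) among `n_neutral` neutral SNPs on a Balding-Nichols background,
#'   at the study's pool sizes, latitudes and coverage. Returns the
#'   fraction of planted SNPs called as southern-northern-pair candidates,
#'   the neutral false-positive fraction, and the fraction of recovered
#'   planted SNPs classified "++".
#' @param n_neutral,n_clinal Composition of the simulated SNP set.
#' @param delta_p Planted frequency change across the cline.
#' @param baseline_fst Neutral background differentiation.
#' @export
validate_candidate_recovery <- function(seed = 1L, n_neutral = 50000L,
                                        n_clinal = 100L, delta_p = 0.5,
                                        baseline_fst = 0.02) {
  n_tot <- n_neutral + n_clinal
  cfg <- sim_config(arms = c(A = n_tot * 100), n_sites_per_arm = n_tot,
                    clinal_frac = n_clinal / n_tot, delta_p = delta_p,
                    baseline_fst = baseline_fst, inversion = NULL)
  pools <- cfg$pools
  truth <- simulate_frequencies(cfg, seed)
  sites <- sample_pool_counts(truth, cfg, seed + 1L)
  caps <- compute_coverage_caps(sites, pools)
  snps <- call_snps(sites, pools, filter_config(caps = caps))
  main_pair <- paste0(pools$label[which.min(pools$latitude)],
                      pools$label[which.max(pools$latitude)])
  cands <- call_candidates(snps, pools)[pair == main_pair]
  cl <- orient_and_slopes(snps, pools)

  key_t <- paste(truth$arm, truth$pos)
  key_s <- paste(snps$arm, snps$pos)
  planted <- key_t[truth$class == "clinal"]
  is_cand <- cands$candidate
  cand_keys <- key_s[is_cand]
  recovered <- planted %in% cand_keys
  neutral_keys <- key_t[truth$class == "neutral"]
  n_fp <- sum(cand_keys %in% neutral_keys)
  pp_keys <- key_s[cl$class == "++"]
  rec_pp <- planted[recovered] %in% pp_keys
  list(pair = main_pair,
       recovery = mean(recovered),
       false_positive_rate = n_fp / length(neutral_keys),
       plusplus_fraction = if (any(recovered)) mean(rec_pp) else NA_real_,
       n_planted = length(planted), n_candidates = sum(is_cand),
       n = n_tot)
}

#' @describeIn calibration False discovery control under the global null:
#'   pools share identical frequencies at every site; reports the fraction
#'   of called SNPs with q < `q_max` for the southern-northern pair,
#'   averaged over `n_seeds` independent simulations.
#' @param n_seeds Number of independent null simulations.
#' @param q_max FDR threshold.
#' @export
validate_fdr_null <- function(seed = 1L, n_seeds = 10L, n_sites = 50000L,
                              q_max = 0.01) {
  rates <- vapply(seq_len(n_seeds), function(k) {
    cfg <- sim_config(arms = c(A = n_sites * 100), n_sites_per_arm = n_sites,
                      baseline_fst = 0, clinal_frac = 0, inversion = NULL)
    pools <- cfg$pools
    truth <- simulate_frequencies(cfg, seed + 2L * k)
    sites <- sample_pool_counts(truth, cfg, seed + 2L * k + 1L)
    snps <- call_snps(sites, pools,
                      filter_config(caps = compute_coverage_caps(sites, pools)))
    p <- fet_pvalues(snps$maj_F, snps$min_F, snps$maj_M, snps$min_M)
    mean(fdr_qvalues(p) < q_max)
  }, numeric(1))
  list(mean_rate = mean(rates), max_rate = max(rates), rates = rates,
       n = n_sites * n_seeds)
}

#' @describeIn calibration Empirical coverage of the Clopper-Pearson
#'   interval at the study's read depth: for each true frequency,
#'   `n_rep` binomial draws at `n_trials` trials; coverage is the fraction
#'   of intervals containing the truth (exactness guarantees >= nominal).
#' @param p_values True binomial proportions to check.
#' @param n_trials Binomial sample size (read depth).
#' @param n_rep Replicates per proportion.
#' @param level Confidence level.
#' @export
validate_ci_coverage <- function(seed = 1L, p_values = c(0.1, 0.3, 0.5),
                                 n_trials = 45L, n_rep = 10000L,
                                 level = 0.95) {
  set.seed(seed)
  cov <- vapply(p_values, function(p) {
    x <- stats::rbinom(n_rep, n_trials, p)
    ci <- binomial_ci(x, rep(n_trials, n_rep), level)
    mean(ci[, "lo"] <= p & p <= ci[, "hi"])
  }, numeric(1))
  names(cov) <- paste0("p", p_values)
  list(coverage = cov, min_coverage = min(cov),
       x0_bound = binomial_ci(0L, n_trials, level)[, "hi"],
       x0_closed_form = 1 - ((1 - level) / 2)^(1 / n_trials),
       n = n_rep * length(p_values))
}

# gene-length-bias fixture: long genes hold ~10x the SNPs of short genes
length_bias_world <- function(seed = 1L, n_long = 100L, n_short = 100L,
                              snps_per_long = 20L, snps_per_short = 2L) {
  set.seed(seed)
  n_gene <- n_long + n_short
  genes <- data.table::data.table(
    gene_id = sprintf("g%03d", seq_len(n_gene)), arm = "X",
    start = seq(1L, by = 30000L, length.out = n_gene))
  genes[, end := start + c(rep(20000L, n_long), rep(2000L, n_short))]
  per <- c(rep(snps_per_long, n_long), rep(snps_per_short, n_short))
  pos <- unlist(lapply(seq_len(n_gene), function(i) {
    genes$start[i] + 1L + sort(sample.int(genes$end[i] - genes$start[i] - 2L,
                                          per[i]))
  }))
  go_map <- list("GO:LONG" = genes$gene_id[seq_len(n_long)],
                 "GO:SHORT" = genes$gene_id[n_long + seq_len(n_short)])
  list(genes = genes[, .(gene_id, arm, start, end)],
       snp_arm = rep("X", length(pos)), snp_pos = pos, go_map = go_map)
}

#' @describeIn calibration Null calibration of the SNP-resampling GO test
#'   on a gene-length-biased fixture (long genes hold ten times the SNPs of
#'   short genes): `n_rep` random candidate draws, each tested at `n_perm`
#'   permutations; returns the Kolmogorov-Smirnov uniformity p-value of the
#'   long-gene category's empirical p-values, and the fraction of
#'   replicates in which a naive gene-level hypergeometric test calls that
#'   category enriched at 0.05 (its anti-conservatism under length bias).
#' @param n_rep Calibration replicates.
#' @param n_perm Permutations per replicate.
#' @param n_cand Candidate SNPs drawn per replicate.
#' @export
validate_go_calibration <- function(seed = 1L, n_rep = 200L, n_perm = 10000L,
                                    n_cand = 80L) {
  w <- length_bias_world(seed)
  n_snp <- length(w$snp_pos)
  set.seed(seed + 1L)
  draw_seeds <- sample.int(1e6, n_rep)
  perm_p <- numeric(n_rep)
  naive_p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(draw_seeds[r])
    cand <- sample.int(n_snp, n_cand)
    res <- go_permutation_test(cand, w$snp_arm, w$snp_pos, w$genes,
                               w$go_map, n_perm = n_perm,
                               seed = draw_seeds[r] + 1L)
    perm_p[r] <- res[go == "GO:LONG", p]
    cand_genes <- unique(assign_genes(w$snp_arm[cand], w$snp_pos[cand],
                                      w$genes)$gene_id)
    naive_p[r] <- go_hypergeometric_test(cand_genes, w$genes$gene_id,
                                         w$go_map)[go == "GO:LONG", p]
  }
  # permutation p-values are discrete, so use the asymptotic statistic
  ks <- suppressWarnings(stats::ks.test(perm_p, "punif", exact = FALSE))
  list(ks_p = ks$p.value,
       perm_rejection_rate = mean(perm_p < 0.05),
       naive_rejection_rate = mean(naive_p < 0.05),
       n = n_rep)
}

#' @describeIn calibration Recovery of the planted inversion structure:
#'   the default two-arm design with an inversion block (per-pool
#'   frequencies `q`, linkage 0.8) on one arm; returns the
#'   southern-northern pair's inside-block candidate enrichment p, the
#'   in/out median F_ST, the near-null pair's enrichment p, and the
#'   marker-frequency medians per pool.
#' @param n_sites_per_arm Sites per simulated arm.
#' @export
validate_inversion_recovery <- function(seed = 1L, n_sites_per_arm = 20000L) {
  cfg <- sim_config(arms = c("2L" = 5e6, "3R" = 5e6),
                    n_sites_per_arm = n_sites_per_arm,
                    inversion = list(name = "In(3R)P", arm = "3R",
                                     start = 1.5e6, end = 3.5e6,
                                     freqs = c(0.5, 0.05, 0.05),
                                     linkage = 0.8, frac_linked = 0.5,
                                     n_markers = 3L),
                    clinal_frac = 0)
  pools <- cfg$pools
  truth <- simulate_frequencies(cfg, seed)
  sites <- sample_pool_counts(truth, cfg, seed + 1L)
  snps <- call_snps(sites, pools,
                    filter_config(caps = compute_coverage_caps(sites, pools)))
  cands <- call_candidates(snps, pools)
  fst <- fst_all_pairs(snps, pools)
  region <- list(arm = "3R", start = 1.5e6, end = 3.5e6)
  fm <- inversion_enrichment(cands[pair == "FM"], region)
  pm <- inversion_enrichment(cands[pair == "PM"], region)
  sh <- inversion_fst_shift(fst[pair == "FM"], region)
  mk <- truth[class == "marker"]
  markers <- data.table::data.table(id = paste0("mk", seq_len(nrow(mk))),
                                    arm = mk$arm, pos = mk$pos,
                                    inv_allele = mk$alt)
  mf <- marker_frequencies(sites, pools, markers, seed = seed + 2L)
  list(fm_enrichment_p = fm$p, fm_direction = fm$direction,
       pm_enrichment_p = pm$p,
       fm_median_fst_inside = sh$median_inside,
       fm_median_fst_outside = sh$median_outside,
       fm_fst_shift_p = sh$p,
       marker_median = mf$median, q_true = cfg$inversion$freqs,
       n = nrow(snps))
}

#' @describeIn calibration Decay-profile contrast on linkage-free data:
#'   planted clinal candidates on a long arm, flanked by independent
#'   neutral SNPs; returns the difference between the candidate and
#'   matched-background median -log10(p) beyond 10 kb (expected ~0 without
#'   linkage), plus the same contrast on the inversion simulation where the
#'   linked block keeps flanking SNPs differentiated (expected elevated).
#' @export
validate_decay <- function(seed = 1L) {
  # linkage-free: 20 planted candidates, single 20-Mb arm
  n_tot <- 20020L
  cfg <- sim_config(arms = c(A = 2e7), n_sites_per_arm = n_tot,
                    clinal_frac = 20 / n_tot, delta_p = 0.6,
                    inversion = NULL)
  pools <- cfg$pools
  truth <- simulate_frequencies(cfg, seed)
  sites <- sample_pool_counts(truth, cfg, seed + 1L)
  snps <- call_snps(sites, pools,
                    filter_config(caps = compute_coverage_caps(sites, pools)))
  cands <- call_candidates(snps, pools)[pair == "FM"]
  dcfg <- decay_config(window = 100L, span = 100000L,
                       background_min_distance = 500000L, seed = seed + 2L)
  snps_p <- cands[, .(arm, pos, fet_p)]
  focal <- cands[candidate == TRUE, .(arm, pos)]
  prof_c <- decay_profile(focal, snps_p, dcfg)
  prof_b <- suppressWarnings(background_profile(focal, snps_p, dcfg))
  far <- function(p) p[abs(offset) > 100 & n_snps > 0, median_nlp]
  flat_diff <- abs(stats::median(far(prof_c)) - stats::median(far(prof_b)))

  # inversion block: candidates inside the block sit among linked,
  # differentiated flanking SNPs
  inv <- validate_inversion_block_decay(seed)
  list(flat_diff = flat_diff, inversion_plateau_diff = inv$plateau_diff,
       n = n_tot)
}

validate_inversion_block_decay <- function(seed = 1L) {
  cfg <- sim_config(arms = c("3R" = 2e7),
                    n_sites_per_arm = 20000L,
                    inversion = list(name = "In(3R)P", arm = "3R",
                                     start = 6e6, end = 14e6,
                                     freqs = c(0.5, 0.05, 0.05),
                                     linkage = 0.8, frac_linked = 0.5,
                                     n_markers = 0L),
                    clinal_frac = 0)
  pools <- cfg$pools
  truth <- simulate_frequencies(cfg, seed + 10L)
  sites <- sample_pool_counts(truth, cfg, seed + 11L)
  snps <- call_snps(sites, pools,
                    filter_config(caps = compute_coverage_caps(sites, pools)))
  cands <- call_candidates(snps, pools)[pair == "FM"]
  dcfg <- decay_config(window = 100L, span = 100000L,
                       background_min_distance = 500000L, seed = seed + 12L)
  snps_p <- cands[, .(arm, pos, fet_p)]
  inside <- cands$candidate & cands$pos >= 6e6 & cands$pos <= 14e6
  focal <- cands[inside, .(arm, pos)]
  prof_c <- decay_profile(focal, snps_p, dcfg)
  prof_b <- suppressWarnings(background_profile(focal, snps_p, dcfg))
  far <- function(p) p[abs(offset) > 100 & n_snps > 0, median_nlp]
  list(plateau_diff = stats::median(far(prof_c)) -
         stats::median(far(prof_b)))
}
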