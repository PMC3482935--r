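#' Run the full analysis pipeline on a simulated or on-disk study
#'
#' Orchestrates: simulation (unless input files are supplied), sync
#' reading, SNP filtering, per-pool diversity, pairwise F_ST, candidate
#' calling, effect classification, GO enrichment, inversion analysis,
#' clinal trajectory classification and decay profiling. Every stage writes
#' a headered TSV artifact into `out_dir` and logs record counts, so stages
#' can be inspected and re-run; reruns with the same config and seed are
#' byte-identical.
#'
#' @param out_dir Output directory for all artifacts.
#' @param config A [sim_config()] describing the synthetic study.
#' @param seed Integer master seed.
#' @param n_perm_go Permutations for the GO test (default 2000 for a quick
#'   run; increase for production use).
#' @param quiet Suppress per-stage messages.
#' @return Named list of in-memory results and artifact paths.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1L,
                         n_perm_go = 2000L, quiet = FALSE) {
  log <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log("simulate: seed %d", seed)
  sim <- simulate_study(config, seed, dir = file.path(out_dir, "input"))
  pools <- config$pools
  sites <- read_sync(sim$paths$sync, pools)
  log("sites read: %d", nrow(sites))

  exclude <- read_mask_bed(sim$paths$mask)
  fcfg <- filter_config(region_exclude = exclude)
  caps <- compute_coverage_caps(sites, pools, fcfg$max_coverage_quantile)
  fcfg$caps <- caps
  snps <- call_snps(sites, pools, fcfg)
  write_snps(snps, file.path(out_dir, "snps.tsv"))
  log("filter: %d sites -> %d SNPs (caps %s)", nrow(sites), nrow(snps),
      paste(caps, collapse = "/"))

  div <- site_diversity(sites, pools, b = 2L,
                        min_coverage = fcfg$min_coverage, caps = caps)
  win <- data.table::rbindlist(lapply(pools$label, function(l) {
    w1 <- window_average(div$arm, div$pos, div[[paste0("pi_", l)]],
                         div[[paste0("valid_", l)]])
    w1[, `:=`(pool = l, statistic = "pi")]
    w2 <- window_average(div$arm, div$pos, div[[paste0("theta_", l)]],
                         div[[paste0("valid_", l)]])
    w2[, `:=`(pool = l, statistic = "theta")]
    rbind(w1, w2)
  }))
  data.table::fwrite(win, file.path(out_dir, "diversity_windows.tsv"),
                     sep = "\t")
  log("diversity: %d windows", nrow(win))

  fst <- fst_all_pairs(snps, pools)
  data.table::fwrite(fst, file.path(out_dir, "fst.tsv"), sep = "\t")

  cands <- call_candidates(snps, pools, candidate_config(),
                           genes = sim$gene_models$genes)
  data.table::fwrite(cands, file.path(out_dir, "candidates.tsv"), sep = "\t")
  log("candidates: %s",
      paste(cands[, sprintf("%s=%d", pair[1], sum(candidate)), by = pair]$V1,
            collapse = " "))

  cds_seqs <- Biostrings::readDNAStringSet(sim$paths$cds)
  eff <- classify_snps(snps, sim$gene_models, cds_seqs)
  data.table::fwrite(eff, file.path(out_dir, "effects.tsv"), sep = "\t")

  tajima <- data.table::rbindlist(lapply(unique(sites$arm), function(a) {
    d <- tajimas_d(sites[arm == a], pools, seed = seed + 20L)
    data.table::data.table(arm = a, pool = names(d), D = unname(d))
  }))
  data.table::fwrite(tajima, file.path(out_dir, "tajimas_d.tsv"), sep = "\t")

  # feature and GO enrichment for the most distant pair's candidates
  far_pair <- unique(cands$pair)
  main_pair <- paste0(pools$label[which.min(pools$latitude)],
                      pools$label[which.max(pools$latitude)])
  if (!main_pair %in% far_pair) main_pair <- far_pair[1]
  cand_main <- cands[pair == main_pair & candidate == TRUE]
  key <- paste(snps$arm, snps$pos)
  cand_idx <- match(paste(cand_main$arm, cand_main$pos), key)

  feat <- NULL
  if (length(cand_idx) > 0) {
    feat <- feature_enrichment(eff$feature[cand_idx],
                               eff$feature[-cand_idx])
    data.table::fwrite(feat, file.path(out_dir, "feature_enrichment.tsv"),
                       sep = "\t")
  }

  go <- NULL
  if (length(cand_idx) >= 5) {
    go <- go_permutation_test(cand_idx, snps$arm, snps$pos,
                              sim$gene_models$genes, sim$go_map,
                              n_perm = n_perm_go, seed = seed + 10L)
    data.table::fwrite(go, file.path(out_dir, "go_enrichment.tsv"),
                       sep = "\t")
    log("go: %d categories tested", nrow(go))
  }

  invres <- NULL
  if (!is.null(config$inversion)) {
    invcfg <- read_inversion_config(sim$paths$inversion)
    region <- invcfg[c("arm", "start", "end")]
    enr <- lapply(split(cands, cands$pair), inversion_enrichment,
                  region = region)
    shift <- lapply(split(fst, fst$pair), inversion_fst_shift,
                    region = region)
    mk <- marker_frequencies(sites, pools, invcfg$markers,
                             seed = seed + 11L)
    invres <- list(enrichment = enr, fst_shift = shift, markers = mk)
    inv_tab <- data.table::rbindlist(lapply(names(enr), function(pr) {
      data.table::data.table(pair = pr, enrichment_p = enr[[pr]]$p,
                             direction = enr[[pr]]$direction,
                             wilcox_p = shift[[pr]]$p,
                             median_fst_inside = shift[[pr]]$median_inside,
                             median_fst_outside = shift[[pr]]$median_outside)
    }))
    data.table::fwrite(inv_tab, file.path(out_dir, "inversions.tsv"),
                       sep = "\t")
  }

  clinal <- orient_and_slopes(snps, pools)
  core <- core_clinal_set(clinal, cands)
  data.table::fwrite(core, file.path(out_dir, "clinal_core.tsv"), sep = "\t")
  log("clinal core set: %d SNPs (%d significant)", nrow(core),
      sum(core$significant))

  decay <- NULL
  if (nrow(cand_main) > 0) {
    dcfg <- decay_config(seed = seed + 12L)
    snps_p <- cands[pair == main_pair, .(arm, pos, fet_p)]
    prof_c <- decay_profile(cand_main[, .(arm, pos)], snps_p, dcfg)
    prof_b <- tryCatch(
      suppressWarnings(background_profile(cand_main[, .(arm, pos)], snps_p,
                                          dcfg)),
      error = function(e) NULL)
    decay <- rbind(prof_c, prof_b)
    data.table::fwrite(decay, file.path(out_dir, "decay.tsv"), sep = "\t")
  }

  # report tables: candidate F_ST summary and feature proportions
  cand_summary <- cands[candidate == TRUE,
                        .(mean_fst = mean(fst), se_fst = stats::sd(fst) / sqrt(.N),
                          min_fst = min(fst), max_fst = max(fst),
                          min_nlq = min(-log10(q)), max_nlq = max(-log10(q)),
                          n_candidates = .N),
                        by = pair]
  data.table::fwrite(cand_summary, file.path(out_dir, "candidate_summary.tsv"),
                     sep = "\t")

  list(sim = sim, pools = pools, snps = snps, diversity_windows = win,
       tajimas_d = tajima, fst = fst, candidates = cands, effects = eff,
       feature_enrichment = feat, go = go, inversion = invres,
       clinal = clinal, clinal_core = core, decay = decay,
       candidate_summary = cand_summary, caps = caps, main_pair = main_pair,
       out_dir = out_dir)
}
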