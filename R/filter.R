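#' SNP-definition filter configuration
#'
#' Defaults follow the standard pool-seq site filters: per-pool coverage at
#' least 10 and at most the per-pool empirical upper 2% coverage cap, and a
#' pooled minor-allele count of at least 6 summed over all pools (a minimum
#' of two per population on average in a three-pool design).
#'
#' @param min_coverage Minimum per-pool nucleotide coverage.
#' @param max_coverage_quantile Upper tail fraction defining the per-pool
#'   coverage cap (sites above the cap are treated as putative CNVs).
#' @param min_minor_total Minimum summed count of the second most frequent
#'   allele across pools for a site to be called polymorphic.
#' @param region_include Optional mask of regions to keep (e.g. normally
#'   recombining regions); NULL keeps all.
#' @param region_exclude Optional mask of regions to drop (repeats/indels).
#' @param caps Optional per-pool integer coverage caps; computed from the
#'   data via [compute_coverage_caps()] when NULL.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 10L, max_coverage_quantile = 0.02,
                          min_minor_total = 6L, region_include = NULL,
                          region_exclude = NULL, caps = NULL) {
  stopifnot(min_coverage >= 1, max_coverage_quantile > 0,
            max_coverage_quantile < 1, min_minor_total >= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 max_coverage_quantile = max_coverage_quantile,
                 min_minor_total = as.integer(min_minor_total),
                 region_include = region_include,
                 region_exclude = region_exclude, caps = caps),
            class = "filter_config")
}

#' Per-pool empirical coverage caps
#'
#' The cap is the floored empirical (1 - quantile) quantile (linear
#' interpolation definition) of each pool's nucleotide coverage; sites with
#' coverage above the cap in any pool are excluded downstream.
#'
#' @param sites Site-count table.
#' @param pools Pool table.
#' @param quantile Upper tail fraction (default 0.02).
#' @return Named integer vector of caps, one per pool.
#' @export
compute_coverage_caps <- function(sites, pools, quantile = 0.02) {
  if (nrow(sites) == 0) stop("cannot compute coverage caps from zero sites")
  covm <- coverage_matrix(sites, pools)
  caps <- floor(apply(covm, 2, stats::quantile, probs = 1 - quantile,
                      names = FALSE, type = 7))
  stats::setNames(as.integer(caps), pools$label)
}

#' The study's normally recombining region spans
#'
#' 1-based inclusive spans of the euchromatic, normally recombining parts of
#' the five major chromosome arms of the D. melanogaster reference,
#' excluding gene-poor telomeric/centromeric low-recombination regions.
#'
#' @return A mask `data.table` (`arm`, `start`, `end`).
#' @export
recombining_regions <- function() {
  data.table::data.table(
    arm = c("X", "2L", "2R", "3L", "3R"),
    start = c(1036552L, 844225L, 6063980L, 447386L, 7940899L),
    end = c(20902578L, 19946732L, 20322335L, 18392988L, 27237549L)
  )
}

#' Call SNPs from pooled site counts
#'
#' A site passes when (a) every pool's nucleotide coverage lies within
#' `[min_coverage, cap]`, (b) its position lies inside the include mask and
#' outside the exclude mask, and (c) the counts summed across pools carry at
#' least two alleles, the second most frequent totalling at least
#' `min_minor_total`. The major/minor alleles are the two most frequent by
#' summed counts (ties broken alphabetically); sites with a third allele
#' present are flagged multiallelic but reduced to their two most frequent
#' alleles.
#'
#' @param sites Site-count table.
#' @param pools Pool table.
#' @param cfg A [filter_config()].
#' @return A SNP `data.table`: `arm`, `pos`, `ref`, `major`, `minor`,
#'   `multiallelic`, and per pool `cov_<label>` (full nucleotide coverage),
#'   `maj_<label>`, `min_<label>` (counts of the two chosen alleles) and
#'   `freq_<label>` (minor count / (major + minor counts)).
#' @export
call_snps <- function(sites, pools, cfg = filter_config()) {
  caps <- cfg$caps
  if (is.null(caps)) {
    caps <- compute_coverage_caps(sites, pools, cfg$max_coverage_quantile)
  }
  covm <- coverage_matrix(sites, pools)
  ok_cov <- rep(TRUE, nrow(sites))
  for (p in seq_len(nrow(pools))) {
    ok_cov <- ok_cov & covm[, p] >= cfg$min_coverage & covm[, p] <= caps[p]
  }
  ok_reg <- in_mask(sites$arm, sites$pos, cfg$region_include)
  if (!is.null(cfg$region_exclude)) {
    ok_reg <- ok_reg & !in_mask(sites$arm, sites$pos, cfg$region_exclude)
  }
  keep <- which(ok_cov & ok_reg)
  if (!length(keep)) return(empty_snps(pools))

  tot <- vapply(NUCS, function(b) {
    rowSums(base_matrix(sites, b, pools))[keep]
  }, numeric(length(keep)))
  if (length(keep) == 1L) tot <- matrix(tot, nrow = 1,
                                        dimnames = list(NULL, NUCS))
  # rank alleles by summed count, ties alphabetical (columns already A<C<G<T
  # after reordering)
  ord_cols <- order(NUCS)  # alphabetical order of columns
  tot_a <- tot[, ord_cols, drop = FALSE]
  nuc_a <- NUCS[ord_cols]
  rk <- t(apply(tot_a, 1, function(x) order(-x)))
  n1 <- nuc_a[rk[, 1]]; n2 <- nuc_a[rk[, 2]]
  c2 <- tot_a[cbind(seq_along(n2), rk[, 2])]
  c3 <- tot_a[cbind(seq_along(n2), rk[, 3])]
  poly <- c2 >= cfg$min_minor_total
  idx <- keep[poly]
  if (!length(idx)) return(empty_snps(pools))
  snps <- data.table::data.table(
    arm = sites$arm[idx], pos = sites$pos[idx], ref = sites$ref[idx],
    major = n1[poly], minor = n2[poly], multiallelic = c3[poly] > 0
  )
  for (p in seq_len(nrow(pools))) {
    lab <- pools$label[p]
    cnt <- vapply(NUCS, function(b) base_matrix(sites, b, pools)[idx, p],
                  numeric(length(idx)))
    if (length(idx) == 1L) cnt <- matrix(cnt, nrow = 1,
                                         dimnames = list(NULL, NUCS))
    majc <- cnt[cbind(seq_len(nrow(snps)), match(snps$major, NUCS))]
    minc <- cnt[cbind(seq_len(nrow(snps)), match(snps$minor, NUCS))]
    snps[, (paste0("cov_", lab)) := covm[idx, p]]
    snps[, (paste0("maj_", lab)) := majc]
    snps[, (paste0("min_", lab)) := minc]
    snps[, (paste0("freq_", lab)) := minc / pmax(1, majc + minc)]
  }
  snps[]
}

empty_snps <- function(pools) {
  snps <- data.table::data.table(arm = character(), pos = integer(),
                                 ref = character(), major = character(),
                                 minor = character(), multiallelic = logical())
  for (lab in pools$label) {
    snps[, (paste0("cov_", lab)) := numeric()]
    snps[, (paste0("maj_", lab)) := numeric()]
    snps[, (paste0("min_", lab)) := numeric()]
    snps[, (paste0("freq_", lab)) := numeric()]
  }
  snps[]
}

#' Read/write the SNP table produced by [call_snps()]
#' @param path Path to a TSV.
#' @return The SNP `data.table`.
#' @export
read_snps <- function(path) data.table::fread(path, sep = "\t")

#' @rdname read_snps
#' @param snps SNP table.
#' @export
write_snps <- function(snps, path) {
  data.table::fwrite(snps, path, sep = "\t")
  invisible(path)
}
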