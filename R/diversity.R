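#' Pool- and coverage-corrected nucleotide diversity at a site
#'
#' For a pool of `n` chromosomes sequenced to nucleotide coverage
#' M = sum(counts), the unbiased per-site heterozygosity is
#' pi = n/(n-1) * M/(M-1) * (1 - sum((c_a/M)^2)): the inner term is the raw
#' read heterozygosity, the M/(M-1) factor corrects for resampling the same
#' read, and n/(n-1) for resampling the same chromosome.
#'
#' @param counts Numeric matrix of allele counts, sites x alleles (any
#'   number of allele columns; rows are sites).
#' @param n Pool size in chromosomes.
#' @return Numeric vector of per-site pi; NA where coverage < 2.
#' @export
pi_site <- function(counts, n) {
  counts <- as.matrix(counts)
  m <- rowSums(counts)
  het <- 1 - rowSums((counts / m)^2)
  out <- (n / (n - 1)) * (m / (m - 1)) * het
  out[m < 2] <- NA_real_
  out
}

#' Detectability-corrected Watterson denominator for pooled data
#'
#' a*(n, M, b) = sum_{i=1}^{n-1} (1/i) * P(b <= K <= M - b) with
#' K ~ Binomial(M, i/n): the classical harmonic sum, with each term weighted
#' by the probability that an allele at pool frequency i/n is actually seen
#' at least `b` times (for both alleles) in M reads. The per-site Watterson
#' estimate is S/a* with S in {0,1} under the same minimum count b.
#'
#' @param n Pool size in chromosomes.
#' @param m Nucleotide coverage (vectorised).
#' @param b Minimum allele count used to call a site segregating.
#' @return Numeric vector a*(n, m, b) parallel to `m`.
#' @export
watterson_denominator <- function(n, m, b = 2L) {
  if (any(b > m / 2)) stop("minimum count b must satisfy b <= M/2")
  vapply(m, function(mm) {
    i <- seq_len(n - 1)
    sum((1 / i) * (stats::pbinom(mm - b, mm, i / n) -
                     stats::pbinom(b - 1, mm, i / n)))
  }, numeric(1))
}

# a* over a vector of coverages with caching of the unique values
watterson_denominator_cached <- function(n, m, b) {
  um <- sort(unique(m))
  a <- watterson_denominator(n, um, b)
  a[match(m, um)]
}

#' Per-pool site diversity statistics
#'
#' Computes, for every input site and pool, the corrected per-site pi, the
#' segregating-site indicator under minimum count `b`, and the per-site
#' Watterson contribution S/a*(n, M, b). Sites outside
#' `[min_coverage, cap]` in a pool are marked invalid for that pool.
#'
#' @param sites Site-count table.
#' @param pools Pool table.
#' @param b Minimum allele count for segregating-site calls (default 2).
#' @param min_coverage,caps Coverage validity bounds (caps as from
#'   [compute_coverage_caps()]; NULL means no upper bound).
#' @return A `data.table` with `arm`, `pos` and per pool `pi_<label>`,
#'   `theta_<label>`, `seg_<label>`, `valid_<label>`.
#' @export
site_diversity <- function(sites, pools, b = 2L, min_coverage = 10L,
                           caps = NULL) {
  out <- sites[, .(arm, pos)]
  for (p in seq_len(nrow(pools))) {
    lab <- pools$label[p]
    n <- pools$n_chromosomes[p]
    cnt <- vapply(NUCS, function(bb) as.numeric(sites[[paste0(bb, "_", lab)]]),
                  numeric(nrow(sites)))
    if (nrow(sites) == 1L) cnt <- matrix(cnt, nrow = 1)
    m <- rowSums(cnt)
    srt <- t(apply(cnt, 1, sort, decreasing = TRUE))
    seg <- srt[, 2] >= b
    valid <- m >= max(min_coverage, 2 * b)
    if (!is.null(caps)) valid <- valid & m <= caps[[lab]]
    pi <- pi_site(cnt, n)
    theta <- rep(NA_real_, length(m))
    ok <- valid & m >= 2 * b
    if (any(ok)) {
      theta[ok] <- as.numeric(seg[ok]) /
        watterson_denominator_cached(n, m[ok], b)
    }
    out[, (paste0("pi_", lab)) := pi]
    out[, (paste0("theta_", lab)) := theta]
    out[, (paste0("seg_", lab)) := seg]
    out[, (paste0("valid_", lab)) := valid]
  }
  out[]
}

# multivariate hypergeometric subsample of count rows to m0 reads
subsample_counts <- function(cnt, m0) {
  m <- rowSums(cnt)
  out <- matrix(0, nrow(cnt), ncol(cnt))
  remaining <- m
  take <- rep(m0, nrow(cnt))
  for (j in seq_len(ncol(cnt))) {
    remaining <- remaining - cnt[, j]
    x <- stats::rhyper(nrow(cnt), cnt[, j], remaining, take)
    out[, j] <- x
    take <- take - x
  }
  out
}

#' Tajima's D for a set of sites, per pool
#'
#' Reads are first subsampled without replacement to a uniform coverage
#' `target_coverage` (sites below it are dropped), removing the dependence
#' of D on variable depth; pi and Watterson's theta are recomputed at the
#' uniform depth with minimum count `b`, and D is normalised with Tajima's
#' constants evaluated at nominal sample size min(n, target_coverage).
#' D only supports relative comparisons between pools, not absolute
#' interpretation.
#'
#' @param sites Site-count table (one region, e.g. one window or arm).
#' @param pools Pool table.
#' @param target_coverage Uniform subsampling depth (default 25).
#' @param b Minimum allele count after subsampling (default 1).
#' @param seed Seed for the subsampling.
#' @return Named numeric vector of D per pool (NA where no segregating
#'   sites remain).
#' @export
tajimas_d <- function(sites, pools, target_coverage = 25L, b = 1L, seed = 1L) {
  set.seed(seed)
  m0 <- as.integer(target_coverage)
  out <- stats::setNames(rep(NA_real_, nrow(pools)), pools$label)
  for (p in seq_len(nrow(pools))) {
    lab <- pools$label[p]
    n <- pools$n_chromosomes[p]
    cnt <- vapply(NUCS, function(bb) as.numeric(sites[[paste0(bb, "_", lab)]]),
                  numeric(nrow(sites)))
    if (nrow(sites) == 1L) cnt <- matrix(cnt, nrow = 1)
    keep <- rowSums(cnt) >= m0
    if (!any(keep)) next
    sub <- subsample_counts(cnt[keep, , drop = FALSE], m0)
    seg <- apply(sub, 1, function(x) sort(x, decreasing = TRUE)[2]) >= b
    s <- sum(seg)
    if (s == 0) next
    pi_sum <- sum(pi_site(sub, n))
    astar <- watterson_denominator(n, m0, b)
    theta_sum <- s / astar
    nn <- min(n, m0)
    a1 <- sum(1 / seq_len(nn - 1)); a2 <- sum(1 / seq_len(nn - 1)^2)
    b1 <- (nn + 1) / (3 * (nn - 1)); b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    out[lab] <- (pi_sum - theta_sum) / sqrt(e1 * s + e2 * s * (s - 1))
  }
  out
}

#' Average site statistics in non-overlapping windows
#'
#' Windows tile each arm on a fixed grid (window k covers positions
#' (k*size, (k+1)*size]). The window mean uses valid sites only; a window is
#' flagged invalid when fewer than `validity` of its sites are valid.
#'
#' @param arm,pos,value,valid Parallel site vectors (`valid` logical;
#'   defaults to all valid).
#' @param window Window size in bp (default 200 kb).
#' @param validity Minimum valid-site fraction for a trustworthy window.
#' @return A `data.table`: `arm`, `start`, `end`, `mean`, `n_snps`,
#'   `n_valid`, `valid`.
#' @export
window_average <- function(arm, pos, value, valid = NULL, window = 200000L,
                           validity = 0.6) {
  if (is.null(valid)) valid <- rep(TRUE, length(pos))
  valid <- valid & !is.na(value)
  dt <- data.table::data.table(arm = arm, pos = pos, value = value,
                               ok = valid)
  dt[, win := (pos - 1L) %/% as.integer(window)]
  res <- dt[, .(mean = if (any(ok)) mean(value[ok]) else NA_real_,
                n_snps = .N, n_valid = sum(ok)),
            by = .(arm, win)]
  res[, `:=`(start = win * as.integer(window) + 1L,
             end = (win + 1L) * as.integer(window))]
  res[, valid := n_snps > 0 & n_valid / n_snps >= validity]
  data.table::setorder(res, arm, start)
  res[, .(arm, start, end, mean, n_snps, n_valid, valid)]
}
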