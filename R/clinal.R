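#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The Beta-quantile formulation of the exact interval (equivalently
#' expressible through F-distribution quantiles): the lower limit is 0 when
#' x = 0 and the upper limit 1 when x = n. Vectorised.
#'
#' @param x Successes (allele read counts).
#' @param n Trials (read coverage), n >= 1.
#' @param level Confidence level (default 0.95).
#' @return A two-column matrix `lo`, `hi`.
#' @export
binomial_ci <- function(x, n, level = 0.95) {
  stopifnot(all(n >= 1), all(x >= 0), all(x <= n))
  a <- (1 - level) / 2
  lo <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lo = lo, hi = hi)
}

#' Sign-based trajectory class from the two latitude slopes
#'
#' "++" when both slopes are strictly positive, "+-" and "-+" for the mixed
#' sign patterns, "--" when both are negative, and "tie" when either slope
#' is exactly zero (excluded from the core clinal set for determinism).
#'
#' @param s1,s2 Slope vectors (frequency per degree latitude).
#' @return Character vector of classes.
#' @export
classify_trajectory <- function(s1, s2) {
  data.table::fcase(
    s1 == 0 | s2 == 0, "tie",
    s1 > 0 & s2 > 0, "++",
    s1 > 0 & s2 < 0, "+-",
    s1 < 0 & s2 > 0, "-+",
    default = "--"
  )
}

#' Orient SNP alleles south-to-north and compute latitude slopes
#'
#' For every SNP, picks whichever of the two alleles does not decrease in
#' frequency from the southernmost to the northernmost pool (ties keep the
#' minor allele), then computes the two slopes of frequency on latitude
#' between consecutive pools (south-to-middle: s1; middle-to-north: s2),
#' the trajectory class, exact binomial confidence limits per pool (trials
#' = reads carrying either allele), and the significance flag: class "++"
#' with all three pairwise confidence intervals disjoint (closed intervals;
#' touching endpoints do not count as disjoint).
#'
#' @param snps SNP table from [call_snps()].
#' @param pools Pool table (exactly three pools required).
#' @param level Confidence level for the intervals.
#' @param ci_trials "reads" (default; trials = major + minor read count) or
#'   "min_chrom" (trials capped at the pool's chromosome count).
#' @return A `data.table`: `arm`, `pos`, `allele`, per-pool `freq_`, `x_`,
#'   `n_`, `lo_`, `hi_` (south-to-north order), `s1`, `s2`, `class`,
#'   `significant`.
#' @export
orient_and_slopes <- function(snps, pools, level = 0.95,
                              ci_trials = c("reads", "min_chrom")) {
  if (nrow(pools) != 3) stop("clinal trajectories need exactly three pools")
  ci_trials <- match.arg(ci_trials)
  ord <- order(pools$latitude)
  labs <- pools$label[ord]
  lat <- pools$latitude[ord]
  x <- lapply(labs, function(l) snps[[paste0("min_", l)]])
  m <- lapply(labs, function(l) {
    snps[[paste0("maj_", l)]] + snps[[paste0("min_", l)]]
  })
  fmin <- lapply(seq_len(3), function(i) x[[i]] / pmax(1, m[[i]]))
  # orientation: keep the allele that rises (or stays) south -> north
  use_minor <- fmin[[3]] >= fmin[[1]]
  allele <- ifelse(use_minor, snps$minor, snps$major)
  out <- data.table::data.table(arm = snps$arm, pos = snps$pos,
                                allele = allele)
  freqs <- list(); los <- list(); his <- list()
  for (i in seq_len(3)) {
    xi <- ifelse(use_minor, x[[i]], m[[i]] - x[[i]])
    ni <- m[[i]]
    if (ci_trials == "min_chrom") {
      nc <- pools$n_chromosomes[ord[i]]
      xi2 <- round(xi / pmax(1, ni) * pmin(ni, nc))
      ni2 <- pmin(ni, nc)
      ci <- binomial_ci(xi2, pmax(1, ni2), level)
    } else {
      ci <- binomial_ci(xi, pmax(1, ni), level)
    }
    fi <- xi / pmax(1, ni)
    freqs[[i]] <- fi; los[[i]] <- ci[, "lo"]; his[[i]] <- ci[, "hi"]
    out[, (paste0("freq_", labs[i])) := fi]
    out[, (paste0("x_", labs[i])) := xi]
    out[, (paste0("n_", labs[i])) := ni]
    out[, (paste0("lo_", labs[i])) := ci[, "lo"]]
    out[, (paste0("hi_", labs[i])) := ci[, "hi"]]
  }
  out[, s1 := (freqs[[2]] - freqs[[1]]) / (lat[2] - lat[1])]
  out[, s2 := (freqs[[3]] - freqs[[2]]) / (lat[3] - lat[2])]
  out[, class := classify_trajectory(s1, s2)]
  out[freqs[[1]] == freqs[[3]], class := "tie"]
  disjoint <- function(i, j) his[[i]] < los[[j]] | his[[j]] < los[[i]]
  out[, significant := class == "++" & disjoint(1, 2) & disjoint(2, 3) &
        disjoint(1, 3)]
  out[]
}

#' Merge per-pair candidate records into the core clinal set
#'
#' The core ("plus_plus") set is the union, over the pairwise candidate
#' sets, of candidate SNPs with trajectory class "++", de-duplicated by
#' (arm, position). A SNP qualifying in at least one pair's candidate set
#' is included.
#'
#' @param clinal Clinal record table from [orient_and_slopes()].
#' @param cand_dt Long candidate table from [call_candidates()].
#' @return The subset of `clinal` forming the core set, with an added
#'   `pairs` column listing the qualifying pairs.
#' @export
core_clinal_set <- function(clinal, cand_dt) {
  cand <- cand_dt[candidate == TRUE, .(pair, arm, pos)]
  pp <- clinal[class == "++"]
  hit <- cand[pp, on = c("arm", "pos"), nomatch = NULL]
  if (nrow(hit) == 0) return(pp[0][, pairs := character()])
  qual <- hit[, .(pairs = paste(sort(unique(pair)), collapse = ",")),
              by = .(arm, pos)]
  res <- pp[qual, on = c("arm", "pos")]
  data.table::setorder(res, arm, pos)
  res[]
}
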