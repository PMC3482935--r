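#' Decay-of-significance profile configuration
#'
#' @param window Bin width in bp (100 for the coarse profile, 10 for the
#'   fine one).
#' @param span Half-width of the profiled region in bp (100 kb coarse,
#'   500 bp fine).
#' @param background_min_distance Minimum distance of background focal SNPs
#'   from any candidate (default 500 kb).
#' @param seed Seed for the background draw.
#' @return A list of class `decay_config`.
#' @export
decay_config <- function(window = 100L, span = 100000L,
                         background_min_distance = 500000L, seed = 1L) {
  if (span %% window != 0) stop("window must divide span")
  structure(list(window = as.integer(window), span = as.integer(span),
                 background_min_distance = as.integer(background_min_distance),
                 seed = as.integer(seed)),
            class = "decay_config")
}

#' Median significance of SNPs flanking a focal set, by distance bin
#'
#' For each focal SNP, every other SNP within +- span is binned by the
#' signed distance d = flanking position - focal position into bins
#' floor(d / window); -log10(p) values are pooled across all focal SNPs per
#' bin and the median reported. Each focal SNP's own p-value is excluded
#' (so bin 0 reflects only its immediate neighbours).
#'
#' @param focal `data.table` with `arm`, `pos` (the focal SNPs).
#' @param snps_p `data.table` with `arm`, `pos`, `fet_p` for all SNPs.
#' @param cfg A [decay_config()].
#' @param label Label stored in the result (e.g. "candidates").
#' @return A `data.table`: `offset` (bin index), `median_nlp`, `n_snps`,
#'   `set` = label.
#' @export
decay_profile <- function(focal, snps_p, cfg = decay_config(),
                          label = "candidates") {
  if (nrow(focal) == 0) stop("focal SNP set is empty")
  f <- data.table::data.table(arm = focal$arm, fpos = focal$pos,
                              start = focal$pos - cfg$span,
                              end = focal$pos + cfg$span)
  s <- data.table::data.table(arm = snps_p$arm, start = snps_p$pos,
                              end = snps_p$pos, spos = snps_p$pos,
                              nlp = -log10(pmax(snps_p$fet_p, 1e-300)))
  data.table::setkey(s, arm, start, end)
  ov <- data.table::foverlaps(f, s, type = "any", nomatch = NULL)
  ov <- ov[spos != fpos]
  ov[, bin := (spos - fpos) %/% cfg$window]
  prof <- ov[, .(median_nlp = stats::median(nlp), n_snps = .N), by = bin]
  grid <- data.table::data.table(
    bin = seq(-cfg$span %/% cfg$window, cfg$span %/% cfg$window - 1L))
  prof <- prof[grid, on = "bin"]
  prof[is.na(n_snps), n_snps := 0L]
  data.table::setorder(prof, bin)
  prof[, set := label]
  data.table::setnames(prof, "bin", "offset")
  prof[]
}

#' Matched random background profile
#'
#' Per arm, draws (seeded, without replacement) as many background focal
#' SNPs as that arm has candidates, each at least
#' `background_min_distance` from every candidate on the arm, then profiles
#' them with [decay_profile()]. When too few eligible SNPs exist the draw
#' shrinks to the achievable size with a warning.
#'
#' @param candidates `data.table` with `arm`, `pos` of candidate SNPs.
#' @param snps_p All SNPs with `arm`, `pos`, `fet_p`.
#' @param cfg A [decay_config()].
#' @return A profile `data.table` labelled "background" (zero rows if no
#'   eligible background SNP exists).
#' @export
background_profile <- function(candidates, snps_p, cfg = decay_config()) {
  set.seed(cfg$seed)
  picks <- list()
  for (a in unique(candidates$arm)) {
    cand_pos <- sort(candidates[arm == a, pos])
    snp_pos <- snps_p[arm == a & !(pos %in% cand_pos), pos]
    if (!length(snp_pos)) next
    iv <- findInterval(snp_pos, cand_pos)
    d_left <- ifelse(iv >= 1, snp_pos - cand_pos[pmax(iv, 1)], Inf)
    d_right <- ifelse(iv < length(cand_pos),
                      cand_pos[pmin(iv + 1L, length(cand_pos))] - snp_pos, Inf)
    eligible <- snp_pos[pmin(d_left, d_right) >= cfg$background_min_distance]
    want <- length(cand_pos)
    if (length(eligible) < want) {
      warning(sprintf("arm %s: only %d of %d background SNPs available",
                      a, length(eligible), want))
      want <- length(eligible)
    }
    if (want > 0) {
      picks[[a]] <- data.table::data.table(arm = a,
                                           pos = sample(eligible, want))
    }
  }
  if (!length(picks)) {
    warning("no eligible background SNPs; returning empty profile")
    return(data.table::data.table(offset = integer(), median_nlp = numeric(),
                                  n_snps = integer(), set = character()))
  }
  decay_profile(data.table::rbindlist(picks), snps_p, cfg,
                label = "background")
}
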