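#' Read an inversion configuration YAML
#'
#' Expected keys: `name`, `arm`, `start`, `end` (1-based inclusive
#' breakpoint-delimited span) and a `markers` list of
#' `{id, arm, pos, inv_allele}` diagnostic marker SNPs.
#'
#' @param path Path to a YAML file.
#' @return A list with `name`, `arm`, `start`, `end` and a `markers`
#'   `data.table`.
#' @export
read_inversion_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mk <- if (length(cfg$markers)) {
    data.table::rbindlist(lapply(cfg$markers, function(m) {
      data.table::data.table(id = m$id, arm = m$arm, pos = as.integer(m$pos),
                             inv_allele = m$inv_allele)
    }))
  } else {
    data.table::data.table(id = character(), arm = character(),
                           pos = integer(), inv_allele = character())
  }
  list(name = cfg$name, arm = cfg$arm, start = as.integer(cfg$start),
       end = as.integer(cfg$end), markers = mk)
}

#' Candidate enrichment inside an inversion span
#'
#' Two-sided Fisher exact test on the 2x2 table (candidate vs not) x
#' (inside vs outside the span), restricted to the inversion's arm.
#'
#' @param cand_dt One pair's candidate table (`arm`, `pos`, `candidate`).
#' @param region List with `arm`, `start`, `end`.
#' @return List: `p`, `direction` ("enriched"/"depleted"/"none"),
#'   `inside_frac`, `outside_frac`, counts. `p` is NA when a stratum is
#'   empty or the arm has no candidates.
#' @export
inversion_enrichment <- function(cand_dt, region) {
  d <- cand_dt[arm == region$arm]
  inside <- d$pos >= region$start & d$pos <= region$end
  a <- sum(d$candidate & inside); b <- sum(!d$candidate & inside)
  cc <- sum(d$candidate & !inside); dd <- sum(!d$candidate & !inside)
  if ((a + b) == 0 || (cc + dd) == 0 || (a + cc) == 0) {
    return(list(p = NA_real_, direction = NA_character_,
                inside_frac = NA_real_, outside_frac = NA_real_,
                n_inside = a + b, n_outside = cc + dd))
  }
  p <- fet_pvalues(a, b, cc, dd)
  fi <- a / (a + b); fo <- cc / (cc + dd)
  list(p = p,
       direction = if (fi > fo) "enriched" else if (fi < fo) "depleted"
                   else "none",
       inside_frac = fi, outside_frac = fo,
       n_inside = a + b, n_outside = cc + dd)
}

#' F_ST shift inside an inversion span
#'
#' Two-sided Wilcoxon rank-sum test of SNP-wise F_ST inside vs outside the
#' span (same arm), with stratum medians.
#'
#' @param fst_dt One pair's F_ST table (`arm`, `pos`, `fst`).
#' @param region List with `arm`, `start`, `end`.
#' @param min_snps Minimum SNPs per stratum (default 10; smaller strata are
#'   flagged and give NA).
#' @return List: `p`, `median_inside`, `median_outside`, `n_inside`,
#'   `n_outside`, `ok`.
#' @export
inversion_fst_shift <- function(fst_dt, region, min_snps = 10L) {
  d <- fst_dt[arm == region$arm & !is.na(fst)]
  inside <- d$pos >= region$start & d$pos <= region$end
  xi <- d$fst[inside]; xo <- d$fst[!inside]
  ok <- length(xi) >= min_snps && length(xo) >= min_snps
  p <- NA_real_
  if (ok) {
    if (length(unique(c(xi, xo))) == 1L) {
      p <- 1
    } else {
      p <- suppressWarnings(stats::wilcox.test(xi, xo)$p.value)
    }
  }
  list(p = p, median_inside = stats::median(xi),
       median_outside = stats::median(xo),
       n_inside = length(xi), n_outside = length(xo), ok = ok)
}

#' Inversion frequencies from diagnostic marker SNPs
#'
#' Per marker and pool, the inversion-associated allele frequency is its
#' read count divided by the nucleotide coverage; the per-pool summary is
#' the median across markers. Marker homogeneity within each pool is tested
#' with an exact test on the K x 2 (marker x allele) count table
#' (Monte-Carlo exact for K > 2, seeded).
#'
#' @param sites Site-count table containing the marker positions.
#' @param pools Pool table.
#' @param markers Marker table (`id`, `arm`, `pos`, `inv_allele`).
#' @param b_homogeneity Monte-Carlo replicates for the K x 2 exact test.
#' @param seed Seed for the Monte-Carlo test.
#' @return List: `freqs` (data.table marker x pool), `median` (named vector
#'   per pool), `homogeneity_p` (named vector per pool; NA with < 2
#'   markers).
#' @export
marker_frequencies <- function(sites, pools, markers, b_homogeneity = 10000L,
                               seed = 1L) {
  idx <- match(paste(markers$arm, markers$pos),
               paste(sites$arm, sites$pos))
  miss <- is.na(idx)
  if (any(miss)) {
    warning("markers missing from the site table: ",
            paste(markers$id[miss], collapse = ", "))
    markers <- markers[!miss]
    idx <- idx[!miss]
  }
  if (!nrow(markers)) stop("no marker present in the site table")
  rows <- list()
  med <- stats::setNames(rep(NA_real_, nrow(pools)), pools$label)
  hom <- stats::setNames(rep(NA_real_, nrow(pools)), pools$label)
  covm <- coverage_matrix(sites, pools)
  set.seed(seed)
  for (p in seq_len(nrow(pools))) {
    lab <- pools$label[p]
    invc <- vapply(seq_len(nrow(markers)), function(i) {
      as.numeric(sites[[paste0(markers$inv_allele[i], "_", lab)]][idx[i]])
    }, numeric(1))
    m <- covm[idx, p]
    freq <- ifelse(m > 0, invc / m, 0)
    rows[[lab]] <- data.table::data.table(id = markers$id, pool = lab,
                                          inv_count = invc, coverage = m,
                                          freq = freq)
    med[lab] <- stats::median(freq)
    if (nrow(markers) >= 2) {
      tab <- cbind(invc, m - invc)
      hom[lab] <- if (nrow(markers) > 2) {
        stats::fisher.test(tab, simulate.p.value = TRUE,
                           B = b_homogeneity)$p.value
      } else {
        stats::fisher.test(tab)$p.value
      }
    }
  }
  list(freqs = data.table::rbindlist(rows), median = med,
       homogeneity_p = hom)
}
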