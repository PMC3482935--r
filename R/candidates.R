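#' Candidate-calling configuration
#'
#' @param outlier_tail Upper tail fraction of the SNP-wise F_ST distribution
#'   defining outliers (default 0.005, i.e. the top 0.5%).
#' @param q_max FDR threshold on exact-test q-values (default 0.01).
#' @param gene_tail Upper tail fraction for the gene-based alternative
#'   (default 0.05).
#' @param flank Gene flank in bp for SNP-to-gene assignment (default 1000).
#' @return A list of class `candidate_config`.
#' @export
candidate_config <- function(outlier_tail = 0.005, q_max = 0.01,
                             gene_tail = 0.05, flank = 1000L) {
  stopifnot(outlier_tail > 0, outlier_tail < 1, gene_tail > 0, gene_tail < 1,
            q_max > 0, q_max <= 1)
  structure(list(outlier_tail = outlier_tail, q_max = q_max,
                 gene_tail = gene_tail, flank = as.integer(flank)),
            class = "candidate_config")
}

#' Rank-based upper-tail outlier selection
#'
#' Flags the floor(tail * N) top-ranked values. Ties at the cutoff are
#' broken by smaller exact-test p-value, then by (arm, position), so exactly
#' k values are flagged deterministically.
#'
#' @param fst Numeric vector (NA allowed; never flagged).
#' @param tail Upper tail fraction.
#' @param fet_p Optional tie-break p-values.
#' @param arm,pos Optional tie-break coordinates.
#' @return Logical vector of outlier flags.
#' @export
select_outliers <- function(fst, tail = 0.005, fet_p = NULL, arm = NULL,
                            pos = NULL) {
  n <- sum(!is.na(fst))
  if (n == 0) stop("no defined values to select outliers from")
  k <- floor(tail * n)
  flags <- rep(FALSE, length(fst))
  if (k == 0) {
    warning("outlier tail of ", tail, " selects zero of ", n, " SNPs")
    return(flags)
  }
  if (is.null(fet_p)) fet_p <- rep(0, length(fst))
  if (is.null(arm)) arm <- rep("", length(fst))
  if (is.null(pos)) pos <- seq_along(fst)
  ord <- order(-fst, fet_p, arm, pos, na.last = TRUE)
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Two-sided Fisher exact test for 2x2 tables, vectorised
#'
#' The p-value is the sum of hypergeometric probabilities (margins fixed) of
#' all tables at most as probable as the observed one, with a relative
#' tolerance of 1e-7 for floating-point ties. Degenerate tables with a zero
#' margin give p = 1.
#'
#' @param a,b,c,d Non-negative integer vectors: tables `[[a, b], [c, d]]`.
#' @return Numeric vector of two-sided p-values.
#' @export
fet_pvalues <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  r1 <- a + b; r2 <- c + d; k <- a + c
  lo <- pmax(0, k - r2); hi <- pmin(k, r1)
  p <- rep(1, length(a))
  nontriv <- hi > lo
  if (!any(nontriv)) return(p)
  w <- which(nontriv)
  len <- hi[w] - lo[w] + 1L
  rows <- rep(w, len)
  x <- sequence(len) - 1L + rep(lo[w], len)
  probs <- stats::dhyper(x, r1[rows], r2[rows], k[rows])
  obs <- stats::dhyper(a, r1, r2, k)
  keep <- probs <= obs[rows] * (1 + 1e-7)
  sums <- rowsum(probs * keep, rows)
  p[w] <- pmin(1, sums[match(w, as.integer(rownames(sums)))])
  p
}

#' @rdname fet_pvalues
#' @export
fisher_exact_2x2 <- function(a, b, c, d) fet_pvalues(a, b, c, d)

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with the null proportion fixed at 1 (conservative;
#' q >= p elementwise). An optional Storey-lambda estimate of the null
#' proportion rescales the q-values.
#'
#' @param p Numeric vector of p-values.
#' @param pi0 Either 1 (default) or "storey" for the lambda = 0.5 Storey
#'   estimate.
#' @return Numeric vector of q-values.
#' @export
fdr_qvalues <- function(p, pi0 = 1) {
  q <- stats::p.adjust(p, method = "BH")
  if (identical(pi0, "storey")) {
    lambda <- 0.5
    pi0_hat <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
    q <- pmin(1, q * pi0_hat)
  }
  q
}

#' Assign SNPs to genes within a flank
#'
#' A SNP is assigned to every gene whose span, extended by `flank` bp on
#' both sides, contains it; overlapping genes all receive the SNP.
#'
#' @param arm,pos Parallel SNP coordinate vectors.
#' @param genes Gene table (`gene_id`, `arm`, `start`, `end`).
#' @param flank Flank in bp (default 1000).
#' @return A `data.table`: `snp_idx` (index into the input), `gene_id`.
#' @export
assign_genes <- function(arm, pos, genes, flank = 1000L) {
  snp_gr <- GenomicRanges::GRanges(arm, IRanges::IRanges(pos, pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$arm, IRanges::IRanges(pmax(1L, genes$start - flank),
                                genes$end + flank))
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  data.table::data.table(snp_idx = S4Vectors::queryHits(ov),
                         gene_id = genes$gene_id[S4Vectors::subjectHits(ov)])
}

#' Call candidate SNPs for every pool pair
#'
#' For each pair: SNP-wise F_ST, a two-sided Fisher exact test on the
#' major/minor count table, BH q-values over all polymorphic SNPs, outlier
#' flags for the upper `outlier_tail` of the F_ST distribution, and the
#' candidate flag = outlier AND q < `q_max`. When gene models are supplied,
#' candidate SNPs carry comma-separated gene assignments (span +- flank).
#'
#' @param snps SNP table from [call_snps()].
#' @param pools Pool table.
#' @param cfg A [candidate_config()].
#' @param genes Optional gene table.
#' @return A long `data.table`: `pair`, `arm`, `pos`, `fst`, `fet_p`, `q`,
#'   `outlier`, `candidate`, `gene_ids`.
#' @export
call_candidates <- function(snps, pools, cfg = candidate_config(),
                            genes = NULL) {
  pairs <- pool_pairs(pools)
  gene_ids <- NULL
  if (!is.null(genes)) {
    asg <- assign_genes(snps$arm, snps$pos, genes, cfg$flank)
    gene_ids <- rep(NA_character_, nrow(snps))
    if (nrow(asg)) {
      coll <- asg[, .(g = paste(sort(gene_id), collapse = ",")), by = snp_idx]
      gene_ids[coll$snp_idx] <- coll$g
    }
  }
  out <- lapply(seq_len(nrow(pairs)), function(kk) {
    i <- pairs$i[kk]; j <- pairs$j[kk]
    li <- pools$label[i]; lj <- pools$label[j]
    fst <- fst_site(snps, pools, i, j)
    p <- fet_pvalues(snps[[paste0("maj_", li)]], snps[[paste0("min_", li)]],
                     snps[[paste0("maj_", lj)]], snps[[paste0("min_", lj)]])
    q <- fdr_qvalues(p)
    outlier <- select_outliers(fst, cfg$outlier_tail, fet_p = p,
                               arm = snps$arm, pos = snps$pos)
    dt <- data.table::data.table(
      pair = pairs$pair[kk], arm = snps$arm, pos = snps$pos, fst = fst,
      fet_p = p, q = q, outlier = outlier,
      candidate = outlier & q < cfg$q_max)
    dt[, gene_ids := if (is.null(gene_ids)) NA_character_ else gene_ids]
    dt
  })
  data.table::rbindlist(out)
}

#' Gene-based candidate genes (upper tail of gene-wise mean F_ST)
#'
#' @param gene_fst One pair's gene F_ST table from [fst_gene()].
#' @param tail Upper tail fraction (default 0.05).
#' @return Character vector of candidate gene ids.
#' @export
gene_based_candidates <- function(gene_fst, tail = 0.05) {
  flags <- select_outliers(gene_fst$fst, tail, arm = gene_fst$gene_id,
                           pos = seq_len(nrow(gene_fst)))
  gene_fst$gene_id[flags]
}

#' Overlap of a gene set with a reference gene set
#'
#' |A intersect B| / |B|, with B the reference (e.g. gene-based) set.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return Fraction in [0, 1]; NA when B is empty.
#' @export
overlap_fraction <- function(set_a, set_b) {
  if (!length(set_b)) return(NA_real_)
  length(intersect(set_a, set_b)) / length(unique(set_b))
}

#' Permutation test for the overlap of two gene sets
#'
#' The observed overlap fraction |A intersect B| / |B| is compared with the
#' overlap of random sets of size |A| drawn uniformly from the universe.
#'
#' @param set1,set2 Character vectors (subsets of `universe`).
#' @param universe Character vector of all eligible genes.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `overlap` (fraction of set2 shared), `p` (permutation
#'   p-value, add-one corrected).
#' @export
compare_candidate_sets <- function(set1, set2, universe, n_perm = 10000L,
                                   seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!all(set1 %in% universe) || !all(set2 %in% universe)) {
    stop("both sets must be subsets of the universe")
  }
  set.seed(seed)
  obs <- overlap_fraction(set1, set2)
  n1 <- length(unique(set1))
  b <- unique(set2)
  hits <- vapply(seq_len(n_perm), function(i) {
    length(intersect(sample(universe, n1), b))
  }, numeric(1)) / length(b)
  list(overlap = obs, p = (1 + sum(hits >= obs)) / (1 + n_perm))
}
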