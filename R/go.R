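#' Gene-length-corrected GO enrichment by SNP-resampling permutation
#'
#' The observed statistic for a category is the number of distinct
#' candidate genes annotated to it (complete linkage of SNPs within genes).
#' The null is built by repeatedly drawing |candidates| SNPs uniformly
#' without replacement from all SNPs and recounting distinct genes per
#' category, so genes with many SNPs (long genes) are hit proportionally
#' often under the null, removing the gene-length bias of naive gene-level
#' tests. Empirical p-values are add-one corrected and BH-adjusted.
#'
#' @param cand_idx Integer indices of candidate SNPs within `snp_arm`/`snp_pos`.
#' @param snp_arm,snp_pos Coordinates of all SNPs (the sampling universe).
#' @param genes Gene table (`gene_id`, `arm`, `start`, `end`).
#' @param go_map Named list GO id -> gene ids.
#' @param n_perm Number of permutations (>= 100).
#' @param min_genes Categories with fewer annotated genes (among the
#'   supplied gene models) are dropped (default 5).
#' @param flank SNP-to-gene flank in bp (default 1000; overlapping genes all
#'   count).
#' @param seed Integer seed.
#' @return A `data.table`: `go`, `n_genes`, `observed`, `mean_perm`, `p`,
#'   `fdr`, sorted by p.
#' @export
go_permutation_test <- function(cand_idx, snp_arm, snp_pos, genes, go_map,
                                n_perm = 10000L, min_genes = 5L,
                                flank = 1000L, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  keep <- vapply(go_map, function(g) sum(g %in% genes$gene_id) >= min_genes,
                 logical(1))
  go_map <- go_map[keep]
  if (!length(go_map)) stop("no GO category has >= min_genes annotated genes")
  cats <- names(go_map)

  snp2gene <- assign_genes(snp_arm, snp_pos, genes, flank)
  gene2cat <- data.table::data.table(
    gene_id = unlist(go_map, use.names = FALSE),
    go = rep(cats, lengths(go_map)))

  count_cats <- function(hit_dt) {
    # hit_dt: (grp, snp_idx); returns (grp, go, n distinct genes)
    g <- snp2gene[hit_dt, on = "snp_idx", nomatch = NULL,
                  allow.cartesian = TRUE]
    g <- unique(g[, .(grp, gene_id)])
    gc <- gene2cat[g, on = "gene_id", nomatch = NULL, allow.cartesian = TRUE]
    # rows are unique by (grp, gene_id, go), so .N counts distinct genes
    gc[, .(n = .N), by = .(grp, go)]
  }

  obs <- count_cats(data.table::data.table(grp = 1L, snp_idx = cand_idx))
  observed <- stats::setNames(rep(0L, length(cats)), cats)
  observed[obs$go] <- obs$n

  k <- length(cand_idx)
  n_snp <- length(snp_pos)
  perm_idx <- unlist(lapply(seq_len(n_perm),
                            function(i) sample.int(n_snp, k)))
  perm_dt <- data.table::data.table(grp = rep(seq_len(n_perm), each = k),
                                    snp_idx = perm_idx)
  pc <- count_cats(perm_dt)

  res <- data.table::rbindlist(lapply(cats, function(cat) {
    cnts <- pc[go == cat, n]
    ge <- sum(cnts >= observed[[cat]]) +
      if (observed[[cat]] == 0) n_perm - length(cnts) else 0L
    data.table::data.table(
      go = cat,
      n_genes = sum(go_map[[cat]] %in% genes$gene_id),
      observed = observed[[cat]],
      mean_perm = sum(cnts) / n_perm,
      p = (1 + ge) / (1 + n_perm))
  }))
  res[, fdr := fdr_qvalues(p)]
  data.table::setorder(res, p, go)
  res[]
}

#' Naive gene-level hypergeometric GO test (no length correction)
#'
#' Upper-tail hypergeometric test on distinct candidate genes per category
#' against the gene universe. Provided as the uncorrected baseline that the
#' SNP-resampling permutation test improves upon: because long genes
#' collect more SNPs, this test is anti-conservative for categories of long
#' genes.
#'
#' @param cand_genes Character vector of candidate gene ids.
#' @param universe Character vector of all genes.
#' @param go_map Named list GO id -> gene ids.
#' @param min_genes Minimum annotated genes per category.
#' @return A `data.table`: `go`, `n_genes`, `observed`, `p`.
#' @export
go_hypergeometric_test <- function(cand_genes, universe, go_map,
                                   min_genes = 5L) {
  cand_genes <- unique(intersect(cand_genes, universe))
  n_univ <- length(unique(universe))
  n_cand <- length(cand_genes)
  keep <- vapply(go_map, function(g) sum(g %in% universe) >= min_genes,
                 logical(1))
  data.table::rbindlist(lapply(names(go_map[keep]), function(cat) {
    in_cat <- intersect(go_map[[cat]], universe)
    k <- length(unique(in_cat))
    obs <- length(intersect(cand_genes, in_cat))
    data.table::data.table(
      go = cat, n_genes = k, observed = obs,
      p = stats::phyper(obs - 1, k, n_univ - k, n_cand, lower.tail = FALSE))
  }))
}
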