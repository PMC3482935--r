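#' SNP-wise pairwise F_ST between two pools
#'
#' The pi-based form: pi_within is the average of the two pools' corrected
#' per-site pi (each with its own pool size and coverage); pi_total is the
#' corrected pi of the summed counts with pool size n_i + n_j and coverage
#' M_i + M_j; F_ST = (pi_total - pi_within) / pi_total. Counts are the
#' major/minor reduction of the SNP table; negative values are retained and
#' F_ST is NA where pi_total is zero.
#'
#' @param snps SNP table from [call_snps()].
#' @param pools Pool table.
#' @param i,j Row indices of the two pools in `pools`.
#' @return Numeric vector of per-SNP F_ST.
#' @export
fst_site <- function(snps, pools, i, j) {
  li <- pools$label[i]; lj <- pools$label[j]
  ci <- cbind(snps[[paste0("maj_", li)]], snps[[paste0("min_", li)]])
  cj <- cbind(snps[[paste0("maj_", lj)]], snps[[paste0("min_", lj)]])
  pi_i <- pi_site(ci, pools$n_chromosomes[i])
  pi_j <- pi_site(cj, pools$n_chromosomes[j])
  pi_within <- (pi_i + pi_j) / 2
  pi_total <- pi_site(ci + cj, pools$n_chromosomes[i] + pools$n_chromosomes[j])
  fst <- (pi_total - pi_within) / pi_total
  fst[!is.na(pi_total) & pi_total == 0] <- NA_real_
  fst
}

#' SNP-wise F_ST for all pool pairs
#'
#' @param snps SNP table.
#' @param pools Pool table.
#' @return A long `data.table`: `pair`, `arm`, `pos`, `fst`.
#' @export
fst_all_pairs <- function(snps, pools) {
  pairs <- pool_pairs(pools)
  data.table::rbindlist(lapply(seq_len(nrow(pairs)), function(k) {
    data.table::data.table(pair = pairs$pair[k], arm = snps$arm,
                           pos = snps$pos,
                           fst = fst_site(snps, pools, pairs$i[k], pairs$j[k]))
  }))
}

#' Gene-wise mean F_ST
#'
#' Mean of defined SNP-wise F_ST over all polymorphic SNPs within the gene
#' span extended by `flank` bp on both sides; a SNP inside several
#' (overlapping) flanked genes contributes to each of them. Genes without
#' SNPs are omitted.
#'
#' @param fst_dt Long F_ST table from [fst_all_pairs()] (or one pair's rows).
#' @param genes Gene table (`gene_id`, `arm`, `start`, `end`).
#' @param flank Flank size in bp (default 1000).
#' @return A `data.table`: `pair`, `gene_id`, `fst`, `n_snps`.
#' @export
fst_gene <- function(fst_dt, genes, flank = 1000L) {
  snp_gr <- GenomicRanges::GRanges(fst_dt$arm,
                                   IRanges::IRanges(fst_dt$pos, fst_dt$pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$arm, IRanges::IRanges(pmax(1L, genes$start - flank),
                                genes$end + flank))
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  hit <- data.table::data.table(
    pair = fst_dt$pair[S4Vectors::queryHits(ov)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    fst = fst_dt$fst[S4Vectors::queryHits(ov)])
  res <- hit[!is.na(fst), .(fst = mean(fst), n_snps = .N),
             by = .(pair, gene_id)]
  data.table::setorder(res, pair, gene_id)
  res[]
}

#' Windowed mean F_ST
#'
#' @param fst_dt Long F_ST table (one pair or several; windows are computed
#'   within pair).
#' @param window Window size in bp.
#' @param validity Minimum defined-F_ST fraction for a valid window.
#' @return A `data.table` of window means per pair.
#' @export
fst_windows <- function(fst_dt, window = 200000L, validity = 0.6) {
  data.table::rbindlist(lapply(split(fst_dt, fst_dt$pair), function(d) {
    w <- window_average(d$arm, d$pos, d$fst, valid = !is.na(d$fst),
                        window = window, validity = validity)
    w[, pair := d$pair[1]]
    data.table::setcolorder(w, "pair")
    w
  }))
}
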