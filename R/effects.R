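FEATURE_LEVELS <- c("nonsynonymous_coding", "synonymous_coding", "utr5",
                    "utr3", "intron", "upstream_1kb", "downstream_1kb",
                    "other", "intergenic")

# per-isoform CDS spans with cumulative 0-based offsets in transcription order
cds_layout <- function(gene_models) {
  cds <- data.table::copy(gene_models$cds)
  strand <- stats::setNames(gene_models$genes$strand,
                            gene_models$genes$gene_id)
  cds[, strand := strand[gene_id]]
  cds[, ord := data.table::fifelse(strand == "+", start, -start)]
  data.table::setorder(cds, isoform, ord)
  cds[, len := end - start + 1L]
  cds[, cum0 := cumsum(len) - len, by = isoform]
  cds[]
}

# map positions onto CDS offsets; returns snp_idx, gene_id, isoform,
# strand, offset (0-based within the spliced CDS, transcription orientation)
cds_offsets <- function(arm, pos, gene_models) {
  lay <- cds_layout(gene_models)
  if (nrow(lay) == 0) {
    return(data.table::data.table(snp_idx = integer(), gene_id = character(),
                                  isoform = character(), strand = character(),
                                  offset = integer()))
  }
  q <- GenomicRanges::GRanges(arm, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(lay$arm, IRanges::IRanges(lay$start, lay$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  off <- ifelse(lay$strand[si] == "+",
                lay$cum0[si] + (pos[qi] - lay$start[si]),
                lay$cum0[si] + (lay$end[si] - pos[qi]))
  data.table::data.table(snp_idx = qi, gene_id = lay$gene_id[si],
                         isoform = lay$isoform[si], strand = lay$strand[si],
                         offset = as.integer(off))
}

revcomp1 <- function(x) chartr("ATCG", "TAGC", x)

#' Classify SNPs into genome-feature categories
#'
#' Each SNP receives exactly one feature by fixed precedence:
#' nonsynonymous > synonymous > 5'UTR > 3'UTR > intron > 1-kb upstream >
#' 1-kb downstream > intergenic, evaluated across all isoforms and genes
#' covering the SNP. Synonymous/nonsynonymous status translates the
#' reference and alternate codons with the standard genetic code,
#' strand-aware; CDS positions whose reference base disagrees with the
#' supplied CDS sequence (phase inconsistency) fall into "other".
#'
#' @param snps SNP table with `arm`, `pos`, `ref`, `major`, `minor`.
#' @param gene_models Gene-model list from [read_gff()].
#' @param cds_seqs Named character vector (or `Biostrings::DNAStringSet`) of
#'   spliced CDS sequences per gene, in transcription orientation.
#' @param flank Up/downstream flank in bp (default 1000).
#' @return A `data.table`: `arm`, `pos`, `feature`, `gene_id` (NA for
#'   intergenic).
#' @export
classify_snps <- function(snps, gene_models, cds_seqs = NULL, flank = 1000L) {
  if (inherits(cds_seqs, "XStringSet")) {
    cds_seqs <- stats::setNames(as.character(cds_seqs), names(cds_seqs))
  }
  n <- nrow(snps)
  rank <- rep(match("intergenic", FEATURE_LEVELS), n)
  gene <- rep(NA_character_, n)
  force_other <- rep(FALSE, n)
  assign_better <- function(idx, level, gid) {
    r <- match(level, FEATURE_LEVELS)
    upd <- which(r < rank[idx])
    rank[idx[upd]] <<- r
    gene[idx[upd]] <<- gid[upd]
  }
  genes <- gene_models$genes
  q <- GenomicRanges::GRanges(snps$arm, IRanges::IRanges(snps$pos, snps$pos))
  hit_tab <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    s <- GenomicRanges::GRanges(tab$arm, IRanges::IRanges(tab$start, tab$end))
    ov <- GenomicRanges::findOverlaps(q, s)
    list(q = S4Vectors::queryHits(ov), s = S4Vectors::subjectHits(ov))
  }

  # coding: translate reference vs alternate codon per isoform hit
  hits <- cds_offsets(snps$arm, snps$pos, gene_models)
  if (nrow(hits) && !is.null(cds_seqs)) {
    hits[, `:=`(ref = snps$ref[snp_idx], major = snps$major[snp_idx],
                minor = snps$minor[snp_idx])]
    # alternate allele: the most frequent of major/minor that differs from ref
    hits[, alt := data.table::fifelse(major != ref, major, minor)]
    gc <- Biostrings::GENETIC_CODE
    for (i in seq_len(nrow(hits))) {
      seq <- cds_seqs[[hits$gene_id[i]]]
      if (is.null(seq) || is.na(seq)) next
      off <- hits$offset[i]
      cod_start <- (off %/% 3L) * 3L + 1L
      if (cod_start + 2L > nchar(seq)) next
      codon <- substr(seq, cod_start, cod_start + 2L)
      pos_in <- off %% 3L + 1L
      refb <- hits$ref[i]; altb <- hits$alt[i]
      if (hits$strand[i] == "-") {
        refb <- revcomp1(refb); altb <- revcomp1(altb)
      }
      si <- hits$snp_idx[i]
      if (substr(codon, pos_in, pos_in) != refb) {
        # reference disagreement: unclassifiable coding position
        force_other[si] <- TRUE
        gene[si] <- hits$gene_id[i]
        next
      }
      alt_codon <- codon
      substr(alt_codon, pos_in, pos_in) <- altb
      lvl <- if (identical(gc[[codon]], gc[[alt_codon]])) {
        "synonymous_coding"
      } else "nonsynonymous_coding"
      assign_better(si, lvl, hits$gene_id[i])
    }
  } else if (nrow(hits)) {
    # CDS hit but no sequence: cannot resolve the codon
    force_other[hits$snp_idx] <- TRUE
    gene[hits$snp_idx] <- hits$gene_id
  }

  for (fs in list(list(tab = gene_models$utr5, lvl = "utr5"),
                    list(tab = gene_models$utr3, lvl = "utr3"))) {
    h <- hit_tab(fs$tab)
    if (!is.null(h)) assign_better(h$q, fs$lvl, fs$tab$gene_id[h$s])
  }
  h <- hit_tab(genes)
  if (!is.null(h)) assign_better(h$q, "intron", genes$gene_id[h$s])

  up <- data.table::copy(genes)
  up[, `:=`(s2 = data.table::fifelse(strand == "+", pmax(1L, start - flank),
                                     end + 1L),
            e2 = data.table::fifelse(strand == "+", start - 1L, end + flank))]
  dn <- data.table::copy(genes)
  dn[, `:=`(s2 = data.table::fifelse(strand == "+", end + 1L,
                                     pmax(1L, start - flank)),
            e2 = data.table::fifelse(strand == "+", end + flank, start - 1L))]
  for (fs in list(list(tab = up, lvl = "upstream_1kb"),
                    list(tab = dn, lvl = "downstream_1kb"))) {
    t2 <- fs$tab[s2 <= e2, .(arm, start = s2, end = e2, gene_id)]
    h <- hit_tab(t2)
    if (!is.null(h)) assign_better(h$q, fs$lvl, t2$gene_id[h$s])
  }

  # a CDS position that could not be resolved against the supplied sequence
  # stays "other" unless another isoform classified it as coding
  syn_rank <- match("synonymous_coding", FEATURE_LEVELS)
  unresolved <- force_other & rank > syn_rank
  rank[unresolved] <- match("other", FEATURE_LEVELS)

  data.table::data.table(arm = snps$arm, pos = snps$pos,
                         feature = FEATURE_LEVELS[rank], gene_id = gene)
}

#' Feature over/underrepresentation of candidate SNPs
#'
#' Per feature, a 2x2 contingency test (feature vs not, candidates vs
#' background excluding candidates): chi-squared without continuity
#' correction, with a Fisher exact fallback (flagged) when any expected
#' cell is below 5.
#'
#' @param cand_features Feature vector (or classification table) of
#'   candidate SNPs.
#' @param bg_features Feature vector of the background SNP set (candidates
#'   are removed by position when tables are given; when vectors are given
#'   the background is assumed to already exclude candidates).
#' @param alpha Significance level (default 0.01).
#' @return A `data.table`: `feature`, `n_cand`, `prop_cand`, `n_bg`,
#'   `prop_bg`, `statistic`, `p`, `direction`, `method`, `significant`.
#' @export
feature_enrichment <- function(cand_features, bg_features, alpha = 0.01) {
  if (is.data.frame(cand_features)) cand_features <- cand_features$feature
  if (is.data.frame(bg_features)) bg_features <- bg_features$feature
  nc <- length(cand_features); nb <- length(bg_features)
  out <- lapply(FEATURE_LEVELS, function(f) {
    a <- sum(cand_features == f); b <- nc - a
    cc <- sum(bg_features == f); d <- nb - cc
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (a + cc == 0) {
      return(data.table::data.table(feature = f, n_cand = a,
                                    prop_cand = a / nc, n_bg = cc,
                                    prop_bg = cc / nb,
                                    statistic = NA_real_, p = NA_real_,
                                    direction = NA_character_,
                                    method = "none", significant = FALSE))
    }
    if (any(expected < 5)) {
      p <- fet_pvalues(a, b, cc, d)
      stat <- NA_real_
      method <- "fisher"
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      p <- ct$p.value
      stat <- unname(ct$statistic)
      method <- "chisq"
    }
    dirn <- if (a / nc > cc / nb) "over" else if (a / nc < cc / nb) "under"
            else NA_character_
    data.table::data.table(feature = f, n_cand = a, prop_cand = a / nc,
                           n_bg = cc, prop_bg = cc / nb, statistic = stat,
                           p = p, direction = dirn, method = method,
                           significant = !is.na(p) & p < alpha)
  })
  data.table::rbindlist(out)
}
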