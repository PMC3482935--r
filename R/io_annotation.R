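#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/UTR features linked by ID/Parent attributes.
#' Multi-isoform genes are merged to the union transcribed span (one row per
#' gene), while per-isoform CDS spans (with phase) are retained for effect
#' calling.
#'
#' @param path Path to a GFF3 file.
#' @return A list with elements `genes` (data.table: gene_id, arm, strand,
#'   start, end), and per-isoform feature tables `exons`, `cds`, `utr5`,
#'   `utr3` (data.table: gene_id, isoform, arm, start, end; `cds` also has
#'   `phase`). Coordinates are 1-based inclusive.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  dt <- data.table::data.table(
    arm = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(
      if (!is.null(gr$Parent)) gr$Parent else replicate(length(gr), character()),
      function(x) if (length(x)) x[1] else NA_character_, character(1)),
    phase = if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_
  )
  gene_rows <- dt[type == "gene"]
  mrna <- dt[type == "mRNA"]
  tx2gene <- stats::setNames(mrna$parent, mrna$id)

  sub_gene <- function(sub) {
    g <- tx2gene[sub$parent]
    # features attached directly to a gene are allowed
    g[is.na(g)] <- sub$parent[is.na(g)]
    sub[, gene_id := g]
    sub[, isoform := parent]
    sub[, .(gene_id, isoform, arm, start, end, phase)]
  }
  exons <- sub_gene(dt[type == "exon"])
  cds <- sub_gene(dt[type == "CDS"])
  if (any(is.na(cds$phase))) {
    warning("CDS features without phase; assuming phase 0")
    cds[is.na(phase), phase := 0L]
  }
  utr5 <- sub_gene(dt[type %in% c("five_prime_UTR", "5UTR")])
  utr3 <- sub_gene(dt[type %in% c("three_prime_UTR", "3UTR")])

  span_src <- rbind(
    gene_rows[, .(gene_id = id, arm, strand, start, end)],
    mrna[, .(gene_id = tx2gene[id], arm, strand, start, end)]
  )
  genes <- span_src[!is.na(gene_id),
                    .(arm = arm[1], strand = strand[1],
                      start = min(start), end = max(end)),
                    by = gene_id]
  data.table::setorder(genes, arm, start, end, gene_id)
  list(genes = genes[], exons = exons[, !"phase"], cds = cds,
       utr5 = utr5[, !"phase"], utr3 = utr3[, !"phase"])
}

#' Read a BED mask into 1-based inclusive intervals
#'
#' BED is 0-based half-open on disk; intervals are converted to the package's
#' 1-based inclusive convention, then sorted and merged.
#'
#' @param path Path to a BED file.
#' @return A `data.table` with columns `arm`, `start`, `end` (1-based
#'   inclusive, sorted, non-overlapping).
#' @export
read_mask_bed <- function(path) {
  gr <- GenomicRanges::reduce(rtracklayer::import(path, format = "bed"))
  dt <- data.table::data.table(
    arm = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  data.table::setorder(dt, arm, start)
  dt[]
}

#' Normalize an interval table into a sorted, merged mask
#'
#' @param dt A data.frame/data.table with columns `arm`, `start`, `end`
#'   (1-based inclusive).
#' @return A sorted, non-overlapping `data.table` mask.
#' @export
mask_set <- function(dt) {
  dt <- data.table::as.data.table(dt)[, .(arm, start = as.integer(start),
                                          end = as.integer(end))]
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    dt$arm, IRanges::IRanges(dt$start, dt$end)))
  out <- data.table::data.table(
    arm = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
  data.table::setorder(out, arm, start)
  out[]
}

#' Membership of positions in a mask
#'
#' @param arm,pos Parallel vectors of arm names and 1-based positions.
#' @param mask Mask table (`arm`, `start`, `end`), or NULL.
#' @return Logical vector: TRUE where (arm, pos) falls inside any interval.
#'   All TRUE when `mask` is NULL; all FALSE when the mask is empty.
#' @export
in_mask <- function(arm, pos, mask) {
  if (is.null(mask)) return(rep(TRUE, length(pos)))
  if (nrow(mask) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(arm, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(mask$arm, IRanges::IRanges(mask$start, mask$end))
  IRanges::overlapsAny(q, s)
}

#' Read gene-to-GO-category associations
#'
#' @param path Path to the association file.
#' @param dialect "tsv" for a two-column `gene_id<TAB>go_id` table (header
#'   optional, detected by a `GO:` prefix in column 2), or "gaf" for GO
#'   annotation format (gene id from column 2, GO id from column 5, comment
#'   lines starting with `!` skipped).
#' @return Named list mapping each GO id to the character vector of distinct
#'   annotated gene ids.
#' @export
read_go_associations <- function(path, dialect = c("tsv", "gaf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            colClasses = "character")
    if (ncol(dt) < 2) stop("GO TSV must have two columns: gene_id, go_id")
    # drop a header row if present
    if (nrow(dt) && !startsWith(dt[[2]][1], "GO:")) dt <- dt[-1]
    map <- data.table::data.table(gene = dt[[1]], go = dt[[2]])
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (!length(lines)) return(structure(list(), names = character()))
    f <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                           colClasses = "character")
    if (ncol(f) < 5) stop("GAF lines must have at least 5 columns")
    map <- data.table::data.table(gene = f[[2]], go = f[[5]])
  }
  map <- unique(map)
  split(map$gene, map$go)
}

#' Write a GO association table (two-column TSV)
#' @param go_map Named list GO id -> gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_associations <- function(go_map, path) {
  dt <- data.table::data.table(
    gene = unlist(go_map, use.names = FALSE),
    go = rep(names(go_map), lengths(go_map))
  )
  data.table::fwrite(dt[, .(gene, go)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}
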