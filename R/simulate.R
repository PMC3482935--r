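#' Simulation configuration for a three-population clinal pool-seq study
#'
#' Defaults emulate the east-coast study design: three pools of wild-caught
#' females (Florida/Pennsylvania/Maine pool sizes and latitudes), ~45-fold
#' mean sequencing coverage, a small per-read-base error rate, a
#' Balding-Nichols neutral background, a minority of clinal SNPs whose
#' frequencies increase linearly with latitude, and one inversion-linked
#' block with diagnostic marker SNPs (frequencies >= 0.5 in the south,
#' ~0.05 further north, as for In(3R)Payne).
#'
#' @param pools Pool table (default [study_pools()]).
#' @param arms Named numeric vector of arm lengths in bp.
#' @param n_sites_per_arm Number of polymorphic sites simulated per arm.
#' @param mean_coverage Mean of the (zero-truncated) Poisson read depth.
#' @param error_rate Per read-base probability of miscalling to a uniformly
#'   chosen other nucleotide.
#' @param baseline_fst Balding-Nichols differentiation parameter F of the
#'   neutral background (0 collapses all pools onto the ancestral frequency).
#' @param ancestral_shape Two Beta shape parameters for the ancestral allele
#'   frequency (U-shaped spectrum by default).
#' @param ancestral_range Truncation bounds for the ancestral frequency.
#' @param clinal_frac Fraction of sites given a clinal trajectory.
#' @param delta_p Total allele-frequency change of clinal SNPs across the
#'   full latitude range (south to north).
#' @param inversion NULL, or a list with `name`, `arm`, `start`, `end`,
#'   `freqs` (per-pool inversion frequency), `linkage` (L in [0,1]),
#'   `frac_linked` (fraction of in-span sites linked to the inversion) and
#'   `n_markers` (fully diagnostic marker SNPs, frequency = inversion
#'   frequency exactly).
#' @param genes List controlling the synthetic gene models: `short_len`,
#'   `long_len`, `frac_long`, `spacing`, `utr_len`.
#' @param n_go_categories Number of random GO categories to emit (plus one
#'   long-gene-only category for gene-length-bias checks).
#' @param mask_frac Fraction of each arm covered by the repeat/indel
#'   exclusion mask (one interval per arm).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pools = study_pools(),
                       arms = c("2L" = 5e6, "2R" = 5e6, "3R" = 5e6),
                       n_sites_per_arm = 20000L,
                       mean_coverage = 45,
                       error_rate = 0.001,
                       baseline_fst = 0.02,
                       ancestral_shape = c(0.2, 0.2),
                       ancestral_range = c(0.05, 0.95),
                       clinal_frac = 0.002,
                       delta_p = 0.5,
                       inversion = list(name = "In(3R)P", arm = "3R",
                                        start = 1.5e6, end = 3.5e6,
                                        freqs = c(0.5, 0.05, 0.05),
                                        linkage = 0.8, frac_linked = 0.5,
                                        n_markers = 3L),
                       genes = list(short_len = 2000L, long_len = 20000L,
                                    frac_long = 0.1, spacing = 2000L,
                                    utr_len = 200L),
                       n_go_categories = 15L,
                       mask_frac = 0.01) {
  stopifnot(mean_coverage > 0, error_rate >= 0, error_rate < 1,
            baseline_fst >= 0, baseline_fst < 1,
            clinal_frac >= 0, clinal_frac <= 1,
            delta_p >= 0, delta_p <= 1)
  if (!is.null(inversion)) {
    stopifnot(inversion$arm %in% names(arms),
              inversion$start >= 1,
              inversion$linkage >= 0, inversion$linkage <= 1,
              all(inversion$freqs >= 0), all(inversion$freqs <= 1),
              length(inversion$freqs) == nrow(pools))
    if (inversion$end > arms[[inversion$arm]]) {
      stop("inversion span lies outside its arm")
    }
  }
  structure(list(pools = pools, arms = arms,
                 n_sites_per_arm = as.integer(n_sites_per_arm),
                 mean_coverage = mean_coverage, error_rate = error_rate,
                 baseline_fst = baseline_fst,
                 ancestral_shape = ancestral_shape,
                 ancestral_range = ancestral_range,
                 clinal_frac = clinal_frac, delta_p = delta_p,
                 inversion = inversion, genes = genes,
                 n_go_categories = as.integer(n_go_categories),
                 mask_frac = mask_frac),
            class = "sim_config")
}

rbeta_trunc <- function(n, a, b, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, a, b), stats::pbeta(hi, a, b))
  stats::qbeta(u, a, b)
}

balding_nichols <- function(p0, f, n_pools) {
  n <- length(p0)
  if (f <= 0) {
    return(matrix(rep(p0, n_pools), nrow = n))
  }
  s1 <- p0 * (1 - f) / f
  s2 <- (1 - p0) * (1 - f) / f
  m <- matrix(NA_real_, n, n_pools)
  for (p in seq_len(n_pools)) m[, p] <- stats::rbeta(n, s1, s2)
  m
}

#' Simulate true per-pool allele frequencies with known class labels
#'
#' Neutral sites draw an ancestral frequency from a truncated Beta and
#' per-pool frequencies from the Balding-Nichols model; clinal sites change
#' linearly with latitude by `delta_p` across the cline (truncated to
#' [0.02, 0.98]); inversion-linked sites inside the inversion span follow
#' p = L q d + (1 - L d) p_neutral where q is the per-pool inversion
#' frequency, d = 1 marks the linked allele and L is the linkage
#' coefficient; marker SNPs track the inversion frequency exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `data.table` (the truth table) with columns `arm`, `pos`,
#'   `ref`, `alt`, `class` (neutral/clinal/inversion/marker), one `p_<label>`
#'   column of true alternate-allele frequencies per pool, and true latitude
#'   slopes `s1_true`, `s2_true`.
#' @export
simulate_frequencies <- function(config, seed = 1L) {
  set.seed(seed)
  pools <- config$pools
  np <- nrow(pools)
  lat <- pools$latitude
  out <- list()
  for (arm in names(config$arms)) {
    len <- config$arms[[arm]]
    ns <- config$n_sites_per_arm
    pos <- sort(sample.int(len - 200L, ns) + 100L)
    ref <- sample(NUCS, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUCS, r), 1L), character(1))
    cls <- rep("neutral", ns)
    inv <- config$inversion
    in_span <- if (!is.null(inv) && inv$arm == arm) {
      pos >= inv$start & pos <= inv$end
    } else rep(FALSE, ns)
    if (any(in_span)) {
      linked <- in_span & stats::runif(ns) < inv$frac_linked
      cls[linked] <- "inversion"
      # diagnostic markers: evenly spread inside the span
      if (inv$n_markers > 0) {
        span_idx <- which(in_span)
        mk <- span_idx[round(seq(1, length(span_idx),
                                 length.out = inv$n_markers))]
        cls[mk] <- "marker"
      }
    }
    free <- which(cls == "neutral" & !in_span)
    n_clinal <- round(config$clinal_frac * ns)
    if (n_clinal > 0 && length(free) > 0) {
      cl <- sample(free, min(n_clinal, length(free)))
      cls[cl] <- "clinal"
    }

    p0 <- rbeta_trunc(ns, config$ancestral_shape[1], config$ancestral_shape[2],
                      config$ancestral_range[1], config$ancestral_range[2])
    pmat <- balding_nichols(p0, config$baseline_fst, np)

    is_cl <- cls == "clinal"
    if (any(is_cl)) {
      p_south <- stats::runif(sum(is_cl), 0.02,
                              max(0.02, 0.98 - config$delta_p))
      rellat <- (lat - min(lat)) / (max(lat) - min(lat))
      pcl <- outer(p_south, rellat * config$delta_p, "+")
      pmat[is_cl, ] <- pmin(pmax(pcl, 0.02), 0.98)
    }
    if (!is.null(inv) && inv$arm == arm) {
      q <- inv$freqs
      is_inv <- cls == "inversion"
      if (any(is_inv)) {
        L <- inv$linkage
        for (p in seq_len(np)) {
          pmat[is_inv, p] <- L * q[p] + (1 - L) * pmat[is_inv, p]
        }
      }
      is_mk <- cls == "marker"
      if (any(is_mk)) pmat[is_mk, ] <- matrix(rep(q, each = sum(is_mk)),
                                              ncol = np)
    }
    dt <- data.table::data.table(arm = arm, pos = pos, ref = ref, alt = alt,
                                 class = cls)
    for (p in seq_len(np)) dt[, (paste0("p_", pools$label[p])) := pmat[, p]]
    out[[arm]] <- dt
  }
  truth <- data.table::rbindlist(out)
  if (np == 3) {
    ord <- order(pools$latitude)
    pm <- as.matrix(truth[, paste0("p_", pools$label[ord]), with = FALSE])
    dl <- diff(pools$latitude[ord])
    truth[, s1_true := (pm[, 2] - pm[, 1]) / dl[1]]
    truth[, s2_true := (pm[, 3] - pm[, 2]) / dl[2]]
  } else {
    truth[, `:=`(s1_true = NA_real_, s2_true = NA_real_)]
  }
  truth[]
}

# multinomial split of e errors over three alternative nucleotides
split3 <- function(e) {
  e1 <- stats::rbinom(length(e), e, 1 / 3)
  e2 <- stats::rbinom(length(e), e - e1, 1 / 2)
  cbind(e1, e2, e - e1 - e2)
}

#' Draw pooled read counts from true frequencies
#'
#' Two-stage sampling: the pool's alternate-allele count is binomial in the
#' number of chromosomes, read depth is zero-truncated Poisson, reads are
#' binomial in the pool allele frequency, and each read miscalls to a
#' uniformly chosen other nucleotide with probability `error_rate`.
#'
#' @param truth Truth table from [simulate_frequencies()].
#' @param config The same [sim_config()].
#' @param seed Integer seed.
#' @return A site-count `data.table` in the layout of [read_sync()].
#' @export
sample_pool_counts <- function(truth, config, seed = 1L) {
  set.seed(seed)
  pools <- config$pools
  ns <- nrow(truth)
  ref_i <- match(truth$ref, NUCS)
  alt_i <- match(truth$alt, NUCS)
  others <- t(vapply(1:4, function(i) setdiff(1:4, i), integer(3)))
  sites <- truth[, .(arm, pos, ref)]
  lam <- config$mean_coverage
  eps <- config$error_rate
  for (p in seq_len(nrow(pools))) {
    nchr <- pools$n_chromosomes[p]
    pp <- truth[[paste0("p_", pools$label[p])]]
    k <- stats::rbinom(ns, nchr, pp)
    # zero-truncated Poisson depth
    m <- stats::qpois(stats::runif(ns, stats::dpois(0, lam), 1), lam)
    alt_reads <- stats::rbinom(ns, m, k / nchr)
    ref_reads <- m - alt_reads
    cnt <- matrix(0L, ns, 4)
    keep_ref <- stats::rbinom(ns, ref_reads, 1 - eps)
    keep_alt <- stats::rbinom(ns, alt_reads, 1 - eps)
    cnt[cbind(seq_len(ns), ref_i)] <- keep_ref
    cnt[cbind(seq_len(ns), alt_i)] <- cnt[cbind(seq_len(ns), alt_i)] + keep_alt
    if (eps > 0) {
      for (src in list(cbind(ref_reads - keep_ref, ref_i),
                       cbind(alt_reads - keep_alt, alt_i))) {
        e3 <- split3(src[, 1])
        for (j in 1:3) {
          idx <- cbind(seq_len(ns), others[cbind(src[, 2], rep(j, ns))])
          cnt[idx] <- cnt[idx] + e3[, j]
        }
      }
    }
    lab <- pools$label[p]
    for (b in 1:4) sites[, (paste0(NUCS[b], "_", lab)) := cnt[, b]]
    sites[, (paste0("N_", lab)) := 0L]
    sites[, (paste0("del_", lab)) := 0L]
  }
  sites[]
}

#' Generate synthetic gene models tiling the simulated arms
#'
#' Genes alternate strands along each arm, separated by `spacing` bp; a
#' fraction `frac_long` are long (for gene-length-bias checks). Each gene
#' has a 5' UTR, two CDS exons separated by one intron, and a 3' UTR; CDS
#' length is a multiple of three.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Gene-model list in the layout of [read_gff()].
#' @export
simulate_gene_models <- function(config, seed = 1L) {
  set.seed(seed)
  g <- config$genes
  rows_genes <- list(); rows_feat <- list()
  gi <- 0L
  for (arm in names(config$arms)) {
    len <- config$arms[[arm]]
    pos <- 1L + g$spacing
    strand <- "+"
    while (TRUE) {
      glen <- if (stats::runif(1) < g$frac_long) g$long_len else g$short_len
      if (pos + glen - 1 > len - g$spacing) break
      gi <- gi + 1L
      gene_id <- sprintf("g%05d", gi)
      start <- pos; end <- pos + glen - 1L
      u <- g$utr_len
      cds_total <- glen - 2L * u
      cds_total <- cds_total - (cds_total %% 3L)
      intron_len <- glen - 2L * u - cds_total  # 0..2 leftover absorbed below
      # put half the CDS in each exon, intron of ~10% gene length between
      intron_len <- max(60L, round(glen * 0.1))
      cds_total <- glen - 2L * u - intron_len
      cds_total <- cds_total - (cds_total %% 3L)
      intron_len <- glen - 2L * u - cds_total
      c1 <- (cds_total %/% 2L) - ((cds_total %/% 2L) %% 3L)
      c2 <- cds_total - c1
      if (strand == "+") {
        utr5 <- c(start, start + u - 1L)
        cds_a <- c(start + u, start + u + c1 - 1L)
        cds_b <- c(cds_a[2] + intron_len + 1L, cds_a[2] + intron_len + c2)
        utr3 <- c(end - u + 1L, end)
        exon1 <- c(start, cds_a[2]); exon2 <- c(cds_b[1], end)
        phase_a <- 0L; phase_b <- (3L - (c1 %% 3L)) %% 3L
        cds_rows <- rbind(c(cds_a, phase_a), c(cds_b, phase_b))
      } else {
        utr3 <- c(start, start + u - 1L)
        cds_b <- c(start + u, start + u + c2 - 1L)
        cds_a <- c(cds_b[2] + intron_len + 1L, cds_b[2] + intron_len + c1)
        utr5 <- c(end - u + 1L, end)
        exon1 <- c(start, cds_b[2]); exon2 <- c(cds_a[1], end)
        phase_a <- 0L; phase_b <- (3L - (c1 %% 3L)) %% 3L
        cds_rows <- rbind(c(cds_a, phase_a), c(cds_b, phase_b))
      }
      iso <- paste0(gene_id, ".t1")
      rows_genes[[gi]] <- data.table::data.table(
        gene_id = gene_id, arm = arm, strand = strand,
        start = start, end = end)
      rows_feat[[gi]] <- data.table::data.table(
        gene_id = gene_id, isoform = iso, arm = arm,
        type = c("exon", "exon", "CDS", "CDS", "utr5", "utr3"),
        start = c(exon1[1], exon2[1], cds_rows[1, 1], cds_rows[2, 1],
                  utr5[1], utr3[1]),
        end = c(exon1[2], exon2[2], cds_rows[1, 2], cds_rows[2, 2],
                utr5[2], utr3[2]),
        phase = c(NA, NA, cds_rows[1, 3], cds_rows[2, 3], NA, NA))
      pos <- end + g$spacing + 1L
      strand <- if (strand == "+") "-" else "+"
    }
  }
  genes <- data.table::rbindlist(rows_genes)
  feat <- data.table::rbindlist(rows_feat)
  feat[, phase := as.integer(phase)]
  list(genes = genes,
       exons = feat[type == "exon", .(gene_id, isoform, arm, start, end)],
       cds = feat[type == "CDS", .(gene_id, isoform, arm, start, end, phase)],
       utr5 = feat[type == "utr5", .(gene_id, isoform, arm, start, end)],
       utr3 = feat[type == "utr3", .(gene_id, isoform, arm, start, end)])
}

#' Random GO associations over simulated genes
#'
#' Each gene receives one to three random categories; one extra category
#' (`GO:LONGBIAS`) contains only long genes, providing a built-in fixture
#' for gene-length-bias calibration.
#'
#' @param gene_models From [simulate_gene_models()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Named list GO id -> gene ids.
#' @export
simulate_go_map <- function(gene_models, config, seed = 1L) {
  set.seed(seed)
  genes <- gene_models$genes
  cats <- sprintf("GO:%07d", seq_len(config$n_go_categories))
  assoc <- lapply(seq_len(nrow(genes)), function(i) {
    sample(cats, sample(1:3, 1))
  })
  dt <- data.table::data.table(
    gene = rep(genes$gene_id, lengths(assoc)),
    go = unlist(assoc))
  long <- genes[end - start + 1L >= config$genes$long_len, gene_id]
  if (length(long)) {
    dt <- rbind(dt, data.table::data.table(gene = long, go = "GO:LONGBIAS"))
  }
  dt <- unique(dt)
  split(dt$gene, dt$go)
}

random_cds_seqs <- function(gene_models, truth) {
  cds <- data.table::copy(gene_models$cds)
  genes <- gene_models$genes
  lay <- cds_layout(gene_models)
  seqs <- lapply(split(lay, lay$gene_id), function(gl) {
    total <- sum(gl$end - gl$start + 1L)
    paste(sample(NUCS, total, replace = TRUE), collapse = "")
  })
  # overwrite bases at simulated SNP positions with the true ref allele
  hits <- cds_offsets(truth$arm, truth$pos, gene_models)
  if (nrow(hits)) {
    hits[, ref := truth$ref[snp_idx]]
    strand <- stats::setNames(genes$strand, genes$gene_id)
    for (i in seq_len(nrow(hits))) {
      g <- hits$gene_id[i]
      b <- hits$ref[i]
      if (strand[[g]] == "-") b <- chartr("ATCG", "TAGC", b)
      substr(seqs[[g]], hits$offset[i] + 1L, hits$offset[i] + 1L) <- b
    }
  }
  unlist(seqs)
}

#' Write a complete simulated study to disk
#'
#' Emits the sync file, pool table, truth table, GFF3 gene models, CDS
#' FASTA, GO association TSV, repeat-mask BED and inversion YAML config.
#'
#' @param truth Truth table.
#' @param sites Site counts from [sample_pool_counts()].
#' @param gene_models From [simulate_gene_models()].
#' @param go_map From [simulate_go_map()].
#' @param config The [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Seed used for the residual randomness in CDS sequences and
#'   mask placement.
#' @return Named list of file paths.
#' @export
write_simulation <- function(truth, sites, gene_models, go_map, config, dir,
                             seed = 1L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    sync = file.path(dir, "counts.sync"),
    pools = file.path(dir, "pools.tsv"),
    truth = file.path(dir, "truth.tsv"),
    gff = file.path(dir, "genes.gff3"),
    cds = file.path(dir, "cds.fasta"),
    go = file.path(dir, "go.tsv"),
    mask = file.path(dir, "mask_exclude.bed"),
    inversion = file.path(dir, "inversion.yaml")
  )
  write_sync(sites, config$pools, paths$sync)
  write_pools(config$pools, paths$pools)
  data.table::fwrite(truth, paths$truth, sep = "\t")
  write_gene_models_gff3(gene_models, paths$gff)
  seqs <- random_cds_seqs(gene_models, truth)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), paths$cds)
  write_go_associations(go_map, paths$go)
  # one masked interval per arm, centred at 3/4 of the arm
  mask <- data.table::rbindlist(lapply(names(config$arms), function(a) {
    len <- config$arms[[a]]
    w <- round(len * config$mask_frac)
    s <- round(len * 0.75)
    data.table::data.table(arm = a, start0 = s - 1L, end0 = s + w - 1L)
  }))
  writeLines(sprintf("%s\t%d\t%d", mask$arm, mask$start0, mask$end0),
             paths$mask)
  inv <- config$inversion
  if (!is.null(inv)) {
    mk <- truth[class == "marker"]
    yaml::write_yaml(list(
      name = inv$name, arm = inv$arm,
      start = as.integer(inv$start), end = as.integer(inv$end),
      markers = lapply(seq_len(nrow(mk)), function(i) list(
        id = sprintf("%s_mk%d", inv$name, i),
        arm = mk$arm[i], pos = mk$pos[i], inv_allele = mk$alt[i]))
    ), paths$inversion)
  }
  paths
}

write_gene_models_gff3 <- function(gm, path) {
  mk_gr <- function(dt, type, id = NULL, parent = NULL, phase = NULL) {
    gr <- GenomicRanges::GRanges(
      dt$arm, IRanges::IRanges(dt$start, dt$end),
      strand = if ("strand" %in% names(dt)) dt$strand else "*")
    gr$type <- type
    gr$ID <- id
    gr$Parent <- if (is.null(parent)) IRanges::CharacterList(vector("list", nrow(dt)))
                 else IRanges::CharacterList(as.list(parent))
    gr$phase <- if (is.null(phase)) rep(NA_integer_, nrow(dt)) else phase
    gr
  }
  genes <- gm$genes
  iso <- unique(gm$exons[, .(gene_id, isoform)])
  iso <- merge(iso, genes, by = "gene_id")
  all <- c(
    mk_gr(genes, "gene", id = genes$gene_id),
    mk_gr(iso, "mRNA", id = iso$isoform, parent = iso$gene_id),
    mk_gr(merge(gm$exons, genes[, .(gene_id, strand)], by = "gene_id"),
          "exon", parent = merge(gm$exons, genes[, .(gene_id, strand)],
                                 by = "gene_id")$isoform),
    mk_gr(merge(gm$cds, genes[, .(gene_id, strand)], by = "gene_id"),
          "CDS", parent = merge(gm$cds, genes[, .(gene_id, strand)],
                                by = "gene_id")$isoform,
          phase = merge(gm$cds, genes[, .(gene_id, strand)],
                        by = "gene_id")$phase),
    mk_gr(merge(gm$utr5, genes[, .(gene_id, strand)], by = "gene_id"),
          "five_prime_UTR",
          parent = merge(gm$utr5, genes[, .(gene_id, strand)],
                         by = "gene_id")$isoform),
    mk_gr(merge(gm$utr3, genes[, .(gene_id, strand)], by = "gene_id"),
          "three_prime_UTR",
          parent = merge(gm$utr3, genes[, .(gene_id, strand)],
                         by = "gene_id")$isoform)
  )
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' One-call simulation of a full study
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; sub-stages use offsets of it so the whole
#'   output is a deterministic function of (config, seed).
#' @param dir Optional output directory; when given, all files are written.
#' @return List with `truth`, `sites`, `gene_models`, `go_map` and (when
#'   `dir` is given) `paths`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L, dir = NULL) {
  truth <- simulate_frequencies(config, seed)
  sites <- sample_pool_counts(truth, config, seed + 1L)
  gm <- simulate_gene_models(config, seed + 2L)
  go_map <- simulate_go_map(gm, config, seed + 3L)
  res <- list(truth = truth, sites = sites, gene_models = gm, go_map = go_map)
  if (!is.null(dir)) {
    res$paths <- write_simulation(truth, sites, gm, go_map, config, dir,
                                  seed + 4L)
  }
  res
}
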