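.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "arm", "pos", "ref", "value", "ok", "win", "n_snps", "n_valid",
  "valid", "gene_id", "isoform", "parent", "phase", "type", "id", "strand",
  "start", "end", "gene", "go", "pair", "fst", "snp_idx", "candidate",
  "grp", "n", "fdr", "p", "s1", "s2", "s1_true", "s2_true", "class",
  "significant", "bin", "spos", "fpos", "nlp", "set", "group", "r",
  "ord", "len", "cum0", "major", "minor", "alt", "s2e", "s2b", "e2",
  "freq", "pairs", "fet_p", "q", "outlier", "gene_ids", "median_nlp",
  "mean_perm", "observed", "n_genes", "statistic", "pool", "offset"
))
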