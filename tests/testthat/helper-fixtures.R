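# Shared fixtures built in code. The small simulated study is computed once
# per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(...) {
  defaults <- list(
    arms = c("2L" = 5e5, "3R" = 5e5),
    n_sites_per_arm = 2000L,
    clinal_frac = 0.005,
    inversion = list(name = "In(3R)P", arm = "3R", start = 1.5e5,
                     end = 3.5e5, freqs = c(0.5, 0.05, 0.05),
                     linkage = 0.8, frac_linked = 0.5, n_markers = 3L)
  )
  args <- utils::modifyList(defaults, list(...), keep.null = TRUE)
  do.call(sim_config, args)
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_study(small_sim_config(), seed = 42L)
  }
  .fixture_env$sim
}

small_snps <- function() {
  if (is.null(.fixture_env$snps)) {
    sim <- small_sim()
    pools <- study_pools()
    caps <- compute_coverage_caps(sim$sites, pools)
    .fixture_env$snps <- call_snps(sim$sites, pools, filter_config(caps = caps))
  }
  .fixture_env$snps
}

# hand-construct a three-pool site-count table from per-pool A/T/C/G counts;
# `counts` is a list of length-4 integer vectors per pool, one site
make_sites <- function(rows, pools = study_pools()) {
  dt <- data.table::rbindlist(lapply(rows, function(r) {
    d <- data.table::data.table(arm = r$arm, pos = r$pos,
                                ref = if (is.null(r$ref)) "A" else r$ref)
    for (p in seq_len(nrow(pools))) {
      lab <- pools$label[p]
      cnt <- r$counts[[p]]
      for (b in seq_along(c("A", "T", "C", "G"))) {
        d[, (paste0(c("A", "T", "C", "G")[b], "_", lab)) := cnt[b]]
      }
      d[, (paste0("N_", lab)) := 0L]
      d[, (paste0("del_", lab)) := 0L]
    }
    d
  }))
  dt
}

# independent brute-force Watterson denominator (double sum over i and k,
# computed from binomial coefficients, not distribution functions)
brute_watterson <- function(n, m, b) {
  s <- 0
  k <- b:(m - b)
  for (i in seq_len(n - 1)) {
    s <- s + (1 / i) * sum(choose(m, k) * (i / n)^k * (1 - i / n)^(m - k))
  }
  s
}

# independent straight-line FST from two pools' (major, minor) counts
brute_fst <- function(ci, ni, cj, nj) {
  pi1 <- (ni / (ni - 1)) * (sum(ci) / (sum(ci) - 1)) *
    (1 - sum((ci / sum(ci))^2))
  pi2 <- (nj / (nj - 1)) * (sum(cj) / (sum(cj) - 1)) *
    (1 - sum((cj / sum(cj))^2))
  ct <- ci + cj
  nt <- ni + nj
  pit <- (nt / (nt - 1)) * (sum(ct) / (sum(ct) - 1)) *
    (1 - sum((ct / sum(ct))^2))
  (pit - (pi1 + pi2) / 2) / pit
}

# independent two-sided FET by explicit enumeration with lchoose arithmetic
enum_fet <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  lp <- lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(n, k)
  p <- exp(lp)
  obs <- p[xs == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

write_toy_gff <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}
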