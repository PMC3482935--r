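---
title: "Methods: pool-seq estimators and the clinal candidate pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq estimators and the clinal candidate pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinepool)
library(data.table)
```

## The problem

Pool-seq estimates allele frequencies of a population sample by sequencing a
single DNA pool made from many individuals. Read counts at a site are then a
two-stage sample: first `n` chromosomes are drawn from the population (the
pool), then `M` reads are drawn (with replacement, to a good approximation)
from those chromosomes. Every statistic in this package corrects for both
stages. The package implements the analysis of a three-population
latitudinal design — a southern, an intermediate and a northern pool of
*Drosophila melanogaster* females (78, 204 and 172 chromosomes at 25.53,
39.88 and 44.02 degrees north) sequenced to roughly 45-fold coverage — but
all pool metadata are configurable (`pool_profiles()`).

## Site filtering

SNPs are called from sync-format counts with three rules
(`filter_config()`, `call_snps()`):

* per-pool nucleotide coverage at least 10 (low-coverage sites carry little
  power) and at most the pool's empirical upper-2% coverage cap (sites
  above it are likely collapsed copy-number variants). Caps are computed
  from the data (`compute_coverage_caps()`) because absolute caps are
  dataset-specific; the floored type-7 quantile is used for determinism;
* a site is polymorphic only if the second most frequent allele, summed
  over all pools, reaches 6 reads — about two per population on average —
  which suppresses sequencing-error pseudo-SNPs;
* optional include/exclude masks; `recombining_regions()` ships the
  standard normally recombining euchromatic spans of the five major fly
  arms, and repeat/indel masks are read from BED.

We require the coverage bounds in **every** pool (the stricter of the two
readings); sites failing anywhere are dropped for all pools, keeping all
pairwise comparisons on one SNP set. Major/minor ties break alphabetically.
Multiallelic sites are reduced to their two most frequent alleles and
flagged; all downstream tests use only those two alleles.

## Diversity estimators

For counts `c_a` with coverage `M = sum(c_a)` from a pool of `n`
chromosomes,

$$\hat\pi = \frac{n}{n-1}\,\frac{M}{M-1}\Big(1 - \sum_a (c_a/M)^2\Big),$$

which is unbiased for the expected pairwise diversity `2p(1-p)` under the
two-stage model: `M/(M-1)` undoes read resampling, `n/(n-1)` undoes
chromosome sampling (`calibrate_pi()` verifies this to Monte-Carlo
precision). The minimum-count truncation applied during SNP calling biases
windowed π slightly downward; as in standard pool-seq practice the
statistic is used comparatively and the calibration quantifies the clean
(unfiltered) case.

Watterson's θ uses a detectability-corrected denominator: an allele at pool
frequency `i/n` is only observed as segregating if both alleles reach the
minimum count `b` among `M` reads, so

$$a^*(n, M, b) = \sum_{i=1}^{n-1}\frac{1}{i}\,
  P\{b \le K \le M-b\},\qquad K \sim \mathrm{Bin}(M, i/n),$$

and the per-site estimate is `S/a*` with `S` the 0/1 segregating indicator
under the same `b`. `calibrate_theta()` recovers a simulated θ within a few
percent at 10^5 sites.

Tajima's D is depth-sensitive, so reads are first subsampled without
replacement (multivariate hypergeometric, seeded) to a uniform 25x; sites
below 25x are dropped rather than up-sampled. π and θ are recomputed at the
uniform depth with `b = 1` and D is normalised with Tajima's constants at
nominal sample size `min(n, 25)`. D supports only relative comparisons
between pools — the absolute scale depends on depth and window size.

Window summaries use non-overlapping 200-kb windows; a window is flagged
invalid when fewer than 60% of its SNPs meet the coverage criteria.

## Differentiation and candidate SNPs

SNP-wise pairwise F_ST is the π-based form: `pi_within` is the mean of the
two pools' corrected π; `pi_total` is the corrected π of the summed counts
at pool size `n_i + n_j` and coverage `M_i + M_j`;
`F_ST = (pi_total - pi_within)/pi_total`. Negative estimates are retained
(they only populate the lower tail; candidate calling uses the upper tail),
and sites with zero total diversity are undefined. Two properties of this
estimator matter for interpretation:

* for two demes each at divergence `F` from their (unobserved) common
  ancestor, its expectation is `(F/2)/(1-F/2)`, not `F` — the classical
  two-deme Gst;
* the per-SNP sampling distribution at ~45x is wide and right-skewed, so
  the **median** per-SNP estimate sits well below the ratio-of-averages
  estimate; `calibrate_fst()` reports both. For identical finite count
  vectors the estimate is slightly negative (the corrections of
  `pi_total` are evaluated at `2M` reads), another well-known artifact of
  this family of estimators.

Candidates are called in two gates (`call_candidates()`): the upper 0.5%
rank tail of the SNP-wise F_ST distribution (ties broken by smaller exact
test p, then position — exactly `floor(0.005 N)` SNPs), intersected with
two-sided Fisher exact tests on the major/minor count table at
Benjamini-Hochberg `q < 0.01`. FET p-values and q-values are computed for
**all** SNPs, not only outliers — the decay profile needs them, and the
multiple-testing universe is then explicit. BH with the null proportion
fixed at 1 is the default (reproducible, conservative); a Storey-lambda
rescale is available. A gene-based alternative ranks genes by mean F_ST
over all SNPs in the span ±1 kb and takes the upper 5% tail
(`gene_based_candidates()`), with `overlap_fraction()` and
`compare_candidate_sets()` quantifying agreement.

The decay profile (`decay_profile()`) pools `-log10(p)` of all SNPs
flanking each candidate into signed `floor(d/window)` bins (100-bp bins
over ±100 kb, or 10-bp bins over ±500 bp) and reports bin medians, with
each focal SNP's own p-value excluded at offset zero; medians are pooled
across focal SNPs rather than median-of-medians. The matched background
(`background_profile()`) draws, per arm, as many non-candidate focals as
there are candidates, each at least 500 kb from every candidate, seeded.

## Effects, GO, inversions, clines

`classify_snps()` assigns exactly one feature per SNP by fixed precedence
(nonsynonymous > synonymous > 5'UTR > 3'UTR > intron > 1-kb upstream >
1-kb downstream > other > intergenic), evaluated over all isoforms of all
covering genes; synonymy translates the reference and alternate codons with
the standard genetic code, strand-aware, against supplied spliced CDS
sequences. CDS positions whose reference base contradicts the supplied
sequence go to "other", as do CDS hits without sequence.
`feature_enrichment()` contrasts candidates against the background with 2x2
chi-squared tests (no continuity correction) at alpha 0.01, falling back to
the exact test when any expected cell is below 5.

GO enrichment resamples SNPs, not genes (`go_permutation_test()`): the
statistic is the number of distinct candidate genes annotated to a
category ("complete linkage" of SNPs within a gene), and the null redraws
candidate-set-sized SNP sets uniformly, so long genes are hit as often as
their SNP content dictates. This removes the gene-length bias that makes a
naive gene-level hypergeometric test anti-conservative for long-gene
categories (`validate_go_calibration()` demonstrates both halves).
Categories with fewer than 5 annotated genes are dropped; the default here
is 10^4-10^5 permutations (production analyses used orders of magnitude
more; empirical p-values are add-one corrected either way).

Inversion analysis treats breakpoint spans as configuration
(`read_inversion_config()`): candidate enrichment inside vs outside the
span on the same arm by exact test, F_ST elevation by Wilcoxon rank-sum,
and inversion frequency from diagnostic marker SNPs (median across markers;
K x 2 marker homogeneity by exact test, Monte-Carlo and seeded for K > 2).
An indel marker used in fly work is represented by a SNP surrogate — indel
genotyping is out of scope.

Clinal trajectories (`orient_and_slopes()`) condition each SNP on the
allele that does not fall from south to north, compute the two latitude
slopes (south-middle, middle-north, in frequency per degree), and classify
their sign pattern; zero slopes are "tie" and excluded from the core set
for determinism. The core "plus-plus" set unions ++ SNPs over the pairwise
candidate sets — a SNP ++ in one pair's set is admitted even if another
pair carries it with a different class flag, with the qualifying pairs
recorded. Significance requires all three pairwise exact
(Clopper-Pearson/Beta-quantile) 95% confidence intervals to be disjoint;
touching endpoints do not count. The binomial trials are the reads
carrying either chosen allele (the observed trials); capping at the pool
chromosome count is available (`ci_trials = "min_chrom"`) since read depth
can exceed the number of independent chromosomes.

## The synthetic study

`sim_config()`/`simulate_study()` emulate the design: ancestral frequencies
from a truncated Beta(0.2, 0.2) (a U-shaped spectrum, as typical for
site-frequency data, truncated to [0.05, 0.95] so every simulated site is a
real polymorphism), per-pool neutral frequencies from the Balding-Nichols
model at baseline F = 0.02, a configurable fraction of clinal SNPs linear
in latitude (truncated to [0.02, 0.98]), an inversion-linked block
(`p = Lqd + (1-Ld)p_neutral`, with marker SNPs tracking the inversion
frequency q = (0.5, 0.05, 0.05) exactly), zero-truncated Poisson depth at
mean 45 and a 0.001 per-read-base error rate to a uniformly chosen other
nucleotide. Gene models tile the arms (two CDS exons, UTRs, one intron;
a long-gene class for length-bias checks), with CDS FASTA, GO table, mask
BED and inversion YAML written alongside the sync file; everything is
byte-deterministic given the seed. Deliberately **not** modelled:
haplotype structure/LD (the inversion is a frequency-level construct,
sufficient to reproduce block-elevated differentiation and the decay
plateau, but flanking SNPs outside the block are independent),
isofemale-line relatedness (the estimators ignore it too), and empirical
per-position coverage profiles (depth is "highly uniform" in this design,
so Poisson is adequate). Passing tests therefore validate estimator
arithmetic and pipeline logic, not robustness to LD or cryptic structure
in real data.

Default problem sizes are chosen for a desk-scale run: 20,000 sites per
simulated arm in the pipeline default, 50,000-site calibration runs,
10^4 permutations and 200 calibration replicates for the GO test. All are
arguments.

## Numerical and design notes

* Exact 2x2 tests sum hypergeometric probabilities at most `(1 + 1e-7)`
  times the observed table's probability (the float-tie guard used by
  standard implementations); the vectorised implementation is checked
  against full enumeration for every table with margins up to 30.
* BH q-values come from `p.adjust`; with the null proportion at 1 they
  dominate the raw p-values elementwise.
* Subsampling, permutation, background draws and Monte-Carlo exact tests
  are all seeded; identical configuration and seed reproduce every artifact
  byte for byte.
* The coverage-cap quantile is floored to an integer so the cap is itself
  an attainable coverage.
* Windowed recovery, unbiasedness and power properties are re-derived at
  run time by the `calibrate_*`/`validate_*` family; the repository's
  reproduction script (`scripts/acceptance.R`) writes exactly those
  numbers.

## Known limitations

* The per-SNP median of the F_ST estimator is not an unbiased reading of
  the Balding-Nichols parameter (see above); use the ratio-of-averages
  summary for calibration against simulation truth.
* At ~45x with the pinned filters, recovery of planted clinal SNPs with a
  0.5 frequency span is limited by the empirical outlier cutoff
  (~60-70%); the exact-test gate alone would recover slightly more.
* Effect classification handles SNVs only (no MNVs, splice or start/stop
  annotations), and GO annotations are taken as given (no graph
  propagation).
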