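---
title: "Standardized dAF genome scans for parallel adaptation in pool-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized dAF genome scans for parallel adaptation in pool-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a migratory (anadromous) fish species repeatedly founds landlocked
freshwater populations, each founding event is an independent natural
experiment in adaptation to the same environmental change. Comparing the
genomes of anadromous and freshwater population pairs across several
independent lineages asks two questions at once: *where* in the genome did
selection act, and *how often did it reuse the same variants or loci* —
that is, how parallel is adaptation at the molecular level?

Pooled sequencing (pool-seq) makes this affordable: tens of individuals per
population are sequenced as one library, and allele frequencies are
estimated from read counts. The cost is that individual genotypes are gone;
every statistic must work directly on per-pool allele counts, and read
sampling noise is part of the model.

`poolscan` implements the complete analysis path from Popoolation2 `sync`
count tables to outlier regions, parallelism percentages and cross-lineage
convergence tests, plus a synthetic data generator with known truth so the
whole pipeline can be validated end to end.

## The core statistic

For a lineage with anadromous pools $a \in A$ and freshwater pools
$f \in F$, the raw signal at SNP $s$ for the pair $(a, f)$ is the absolute
allele-frequency difference

$$\Delta \mathrm{AF}_{s,(a,f)} = \left| p_{s,f} - p_{s,a} \right|,$$

where $p$ is the minor-allele read frequency. The absolute value is used
because allele labels carry no polarity across populations; the statistic
is one-sided on magnitude.

Raw $\Delta \mathrm{AF}$ baselines differ between pairs — pairs of
populations separated by more drift have larger differences everywhere. To
make pairs comparable, each pair's values are standardized against that
pair's *genome-wide* distribution:

$$z_{s,(a,f)} = \frac{\Delta \mathrm{AF}_{s,(a,f)} - \mu_{(a,f)}}
{\sigma_{(a,f)}},$$

with $\mu$ and $\sigma$ the mean and (population-form, divide-by-$n$)
standard deviation over all SNPs of the lineage. The per-SNP scan statistic
is the average over all $|A| \times |F|$ pairs:

$$\bar z_s = \frac{1}{|A||F|} \sum_{(a,f)} z_{s,(a,f)}.$$

A SNP with a large $\bar z_s$ is unusually differentiated between the two
life histories *consistently across pool pairs*, which is the signature of
selection associated with the freshwater habit rather than pool-specific
drift. If any pair has zero genome-wide variance the run stops with an
error naming the pair — that indicates degenerate input, not a value to
silently impute.

## SNP filters

`call_snps()` applies count-level filters before any statistic is
computed. All defaults can be changed through arguments or the pipeline
config:

- **Biallelic, lineage-wide**: summing counts over the lineage's pools,
  exactly two of A/C/G/T are observed. Triallelic sites are more likely
  alignment artefacts, and the dAF statistic is defined for two alleles.
- **Minor-allele count ≥ 4** (summed over pools): removes singleton-like
  sequencing errors.
- **Per-pool coverage in [10, 2 × pool mean]**: the lower bound controls
  frequency-estimation noise; the upper bound removes collapsed repeats.
  Each pool's genome-wide mean coverage is computed over *all* input sites
  before filtering, so the bound does not drift with the filter itself.
- **Indel proximity**: SNPs within 10 bp of a known indel position are
  dropped (`filter_near_indels()`), because alignment around indels
  produces spurious variants.

`N` and deletion read counts contribute to coverage (they are real reads at
the site) but never to allele calls or frequency denominators.

## Windows and the permutation null

Per-SNP statistics are noisy; selection leaves locally extended signals.
`window_scan()` averages $\bar z_s$ in sliding windows of 20 consecutive
SNPs, stepping by 10 SNPs, separately along each scaffold, restricted to
the 1000 longest scaffolds (short scaffolds are repeat-enriched). Only full
20-SNP windows are emitted. SNP-count windows (rather than fixed bp) keep
the sampling variance of the window mean constant across the genome.

How large is a window mean under no selection? `build_null()` answers by
permutation: the lineage's pools are randomly reassigned to the
anadromous/freshwater labels (group sizes preserved), the entire statistic
— pair differences, genome-wide standardization, window averaging — is
recomputed, and the window start offset is drawn uniformly from 1..20 so
all window phasings are represented. All permutations' window statistics
are pooled into one empirical null, and thresholds are nearest-rank
percentiles of that pool: `sort(x)[ceiling(p/100 * n)]`. Window p-values
use the add-one estimator $p = (1 + \#\{\text{null} \ge \text{stat}\}) /
(1 + \#\text{null})$, which is never zero. Outliers are windows at or above
the 99th (suggestive) or 99.9th (stringent) percentile threshold, ties
included.

Each permutation runs on its own pre-allocated L'Ecuyer-CMRG RNG stream, so
the pooled null is byte-identical regardless of the order (or
parallelisation) in which permutations execute, and the session RNG is
left untouched.

With few pools per group, the label-permutation group is small and some
permutations reproduce (or nearly reproduce) the true labelling, pushing
genuine signal into the null. This is inherent to the design, and it makes
the thresholds conservative. With 2 anadromous + 2 freshwater pools, 2 of
the 6 distinct assignments are fully aligned with truth; with 2 + 3 pools
only 2 of 10 are. The synthetic recovery tests in this package therefore
use a 2 + 3 design, mirroring a study with three freshwater populations.

## Outlier regions, parallelism, convergence

Consecutive outlier windows usually reflect one locus. `merge_regions()`
merges outlier windows on a scaffold whose spans are separated by at most
20,000 intervening bases (transitively), and `annotate_genes()` attaches
genes separated from a region by at most the same inclusive 20 kb.

Parallelism is quantified at two levels:

- **Shared outlier regions** (`shared_regions()`): a region is shared when
  it overlaps a region of the other unit by ≥ 1 bp. Because units differ in
  their region counts, the percentage is the mean of the two directional
  fractions: $100 \cdot \tfrac12 (s_A/|A| + s_B/|B|)$.
  `shared_across()` intersects all units' regions for complete parallelism.
- **Shared polymorphism** (`shared_polymorphism()`): same symmetric mean of
  directional fractions over polymorphic *sites* matched by scaffold and
  position. A site is polymorphic when at least one pool segregates or is
  fixed for a non-reference allele.

Convergence between lineages is examined two ways. The heat-map matrix
(`convergence_matrix()`) takes the target lineage's 99.9th-percentile
outlier windows and computes every other lineage's mean $\bar z$ over the
same genomic span; cells with fewer than 2 SNPs are excluded rather than
shown as misleading single-SNP values. The shared nonsynonymous-site test
(`shared_nonsyn_test()`) asks whether sites that are nonsynonymous in both
lineages reach the 95th percentile of each lineage's nonsynonymous $\bar z$
distribution in *both* lineages — reuse of the same functional variants,
the strongest form of molecular parallelism. Sites are matched by position;
effect tables carry no allele phase, so alleles are not compared.

Windowed population genetics (`popgen_windows()`) accompanies the scan:
per-pool nucleotide diversity $\pi$ with the read-depth correction
$\frac{C}{C-1}(1 - \sum_i p_i^2)$, Watterson's $\theta$, Tajima's D, and
per-pair $d_{xy} = p_1(1-p_2) + p_2(1-p_1)$. Values are averages over the
variant sites inside each scan window (per variant site, not per bp — the
windows contain SNPs only, and the output header says so). The effective
sample size is `min(coverage, haploid pool size)`: reads cannot sample more
chromosomes than the pool contains. Undefined values are `NA`, never a
silent zero. `contrast_outliers()` compares any of these statistics between
outlier and background windows with a two-sided Mann–Whitney U test;
elevated $d_{xy}$ and depressed Tajima's D at outlier regions corroborate
the selection interpretation.

## The synthetic generator

`simulate_poolseq()` produces multi-lineage datasets with known truth,
sized and shaped like a real pool-seq experiment. What it emulates:

- A scaffolded genome (default 20 scaffolds, lengths tapering 1 Mb to
  0.5 Mb) — enough structure to exercise per-scaffold windowing.
- SNP positions per lineage with a tunable fraction shared between
  lineages (default 0.5), since real lineages share standing variation.
- An ancestral alternative-allele frequency per position from
  Beta(0.8, 0.8) — a U-shaped site-frequency spectrum, as drift produces.
- Per-pool frequencies as the ancestral value plus Normal(0, 0.5) noise on
  the logit scale: drift that respects the [0, 1] boundary and is larger
  for intermediate frequencies.
- Reads: Poisson coverage (default mean 32×) with binomial allele
  sampling — the standard pool-seq observation model.
- Planted freshwater-selected regions: inside a region, each freshwater
  pool's base frequency is shifted so the expected |dAF| against anadromous
  pools equals the region's `delta` (direction chosen to stay in [0, 1];
  infeasible shifts are clipped with a warning). `min_snps_per_region`
  guarantees enough SNPs per region to fill scan windows; planting can be
  restricted to chosen lineages or freshwater pools for
  partial-parallelism scenarios.
- A toy effect table, gene models spanning each planted region, and
  optional random indel positions, so every annotation path has input.

What it does **not** emulate: linkage disequilibrium between SNPs (drift is
independent per site), mapping or alignment artefacts, reference bias,
variable mappability, or demographic history beyond one drift step. It is
a validation instrument for the statistics, not a population-genetic
simulator of record.

Defaults (pools of 29 diploids, 32× coverage, 2 anadromous + 2 freshwater
pools per lineage, 50,000 SNPs) are chosen to resemble a real pooled
study's per-pool design while keeping a full two-lineage run in seconds.
Everything is deterministic given the config seed, and generation leaves
the caller's RNG state untouched.

## Numerical and reproducibility choices

- **Population-form standard deviation** (divide by $n$, not $n-1$): the
  genome-wide SNP set is treated as the population of interest, and the
  permutation null recomputes the same quantity, so the scan and its null
  are exactly comparable.
- **Nearest-rank percentiles** with a $10^{-9}$ guard inside the ceiling,
  so exact ranks (e.g. 99.9% of 1000 = rank 999) are not pushed up by
  floating-point error in `p/100 * n`.
- **Add-one p-values** bounded away from zero; the smallest attainable
  p-value is $1/(1 + \#\text{null})$.
- **Inclusive 20 kb distance** defined everywhere as intervening bases
  (the `GenomicRanges::distance()` convention): windows or genes separated
  by exactly 20,000 bases merge/attach; 20,001 do not.
- **Reproducibility**: one RNG stream per permutation index; simulation
  under a pinned Mersenne-Twister seed; the pipeline writes a
  `run_manifest.json` with parameters, seed, package version and md5
  checksums of every output, and identical (inputs, config, seed) give
  byte-identical outputs.

## A worked example

```{r example, eval = FALSE}
library(poolscan)

cfg <- sim_config(
  n_lineages = 2,
  n_snps = 20000,
  planted_regions = tibble::tibble(scaffold = "scaf001",
                                   start = 400000L, end = 412000L,
                                   delta = 0.7),
  min_snps_per_region = 40,
  seed = 11
)
sim <- simulate_poolseq(cfg)

snps <- call_snps(sim$counts$L1, sim$manifest, lineage = "L1")
scan <- lineage_scan(snps, n_perm = 200, seed = 11,
                     scaffold_lengths = sim$scaffold_lengths,
                     genes = sim$truth$genes)
scan
scan$regions[["99.9"]]

plot_manhattan(scan)
```

Or, end to end with files on disk:

```{r pipeline, eval = FALSE}
run_pipeline(
  config = list(simulate = list(n_lineages = 2, n_snps = 20000, seed = 11)),
  out_dir = "scan_output"
)
```

The README shows the same example with its printed output.
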