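---
title: "Methods: windowed diversity/divergence sweep scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed diversity/divergence sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkascan)
```

## The model

A selective sweep fixes a beneficial allele and strips linked variation, so
a swept region shows depressed within-species diversity while its divergence
from an outgroup lineage — accumulated over a much longer timescale — is
unaffected. `hkascan` contrasts the two quantities window by window. For a
window with $L$ callable sites,

$$\frac{\theta}{D} \;=\;
\frac{\tfrac{1}{L}\sum_{i=1}^{L} 2 p_i (1-p_i)\,\tfrac{n}{n-1}}
     {\tfrac{1}{L}\sum_{i=1}^{L} \left(X_i + 0.5\,Y_i\right)}$$

where $p_i$ is the alternate-allele frequency among the focal cohort at site
$i$, $n$ is the number of sampled chromosomes ($n = 8$ for four diploids),
and $X_i, Y_i$ indicate that the designated divergence genome is
homozygous-alternate or heterozygous at site $i$ relative to the reference.
The numerator is windowed nucleotide diversity $\hat\pi$ with the
$n/(n-1)$ small-sample correction — per site, exactly the mean pairwise
difference $2k(n-k)/(n(n-1))$ among the $n$ chromosomes, which is what the
test suite verifies by exhaustive enumeration. The denominator is per-site
divergence with heterozygous sites contributing one half.

Because demography (bottlenecks, expansions, structure) moves diversity
genome-wide, no parametric null is attempted. Windows are ranked by their
ratio and assigned *empirical* p-values
$p_i = \#\{j : r_j \le r_i\}/N$; the low tail (conventionally
$p < 0.01$) is the sweep candidate set.

Assumptions worth stating explicitly:

* The reference allele is treated as ancestral for both $p$ (alternate =
  derived) and divergence polarity. This is the usual choice when the
  cohort is mapped to a divergent species' assembly; it is wrong at sites
  where the reference lineage itself carries the derived allele, which
  inflates neither statistic systematically but adds noise.
* $X_i$ is a per-site *indicator* (homozygous-derived site = 1), not an
  allele count, keeping $D$ a per-site probability on the same scale as
  $\theta$. Reading $X_i$ as an allele count (homozygous = 2) is available
  via `filter_config(hom_divergence_weight = 2)`.
* Windows with $D = 0$ have an undefined ratio. They are retained and
  flagged (`zero_divergence`) but excluded from the ranking: the candidate
  set is the *low*-ratio tail, and a zero-divergence window is the opposite
  extreme.

## The filter stack

A position contributes to $L$, $\theta$ and $D$ only if **all** of the
following hold for every relevant sample (focal cohort plus divergence
genome); the first violated rule is recorded, and `scan_windows()` returns
the tally:

| rule | default | notes |
|---|---|---|
| missing genotype | — | any `./.` call fails the site |
| depth floor | 3 reads | inclusive: depth 3 passes |
| depth ceiling | 95th percentile | nearest-rank, per sample, inclusive |
| site QUAL | ≥ 50 | variant records only |
| biallelic | on | multi-allelic records dropped, not decomposed |
| genotype quality | ≥ 20 | Phred-scaled |

Monomorphic records in an all-sites VCF must still clear the depth,
missingness and genotype-quality rules to count toward $L$, but are exempt
from the QUAL rule because all-sites callers give them low or absent QUAL by
construction.

Two window-level rules follow: windows with fewer than `min_callable_bp`
(default 10 kb) callable sites are discarded, and when a reference sequence
is supplied, windows whose GC fraction exceeds the nearest-rank
`max_gc_quantile` (default 0.95) of all window GC values are dropped. GC
filtering is deliberately window-level — there is no defensible per-site GC
rule — and the threshold is a package choice, logged in the run manifest.

The depth ceiling is computed per sample from that sample's full depth
distribution. Per-sample is the conservative generalization of a
per-dataset percentile: it protects against one high-coverage library
dragging the ceiling up for the others. The nearest-rank definition (the
$\lceil qN \rceil$-th order statistic) is used everywhere — it is
deterministic, always an observed value, and free of interpolation
ambiguity.

## Window geometry and numerical conventions

* Default windows are non-overlapping 100 kb (`step_bp = window_bp`).
  Overlapping windows are supported (`step_bp < window_bp`) but inflate the
  effective number of tests in the empirical ranking, so the non-overlapping
  default is recommended; window length is fully configurable (25 kb
  windows are a reasonable choice for gene-scale resolution).
* Partial trailing windows are never emitted: fixed length keeps $L$
  comparable and the callable-length rule meaningful.
* Coordinates are 0-based half-open internally; conversion happens only at
  the VCF (1-based) and GFF3 (1-based inclusive) boundaries. BED input is
  used as-is.
* Empirical p uses denominator $N$ with maximum-rank ties, so at most
  $\lceil \alpha N \rceil$ windows can satisfy $p < \alpha$ and the
  smallest attainable p is $1/N$ — thresholds are exactly reproducible.
* Missing values serialise as `NA` in TSV output; floating point is written
  with 17 significant digits so `write_window_table()` /
  `read_window_table()` round-trip losslessly.
* "Located within a window" for genes means any ≥ 1 bp overlap under
  half-open semantics, not containment — genes are routinely longer than a
  window. Flanking divergent sites are integer homozygous-difference
  counts (no 0.5 weighting), matching how such counts are reported.
* The neutral-locus missingness filter removes loci with *strictly more*
  than the threshold fraction missing (a locus at exactly 10% is kept);
  percentages are reported rounded half-up to one decimal. Posterior
  summaries are equal-tailed 95% intervals; highest-posterior-density
  intervals are not implemented.

## What the generator emulates — and what it does not

`sweep_sim_params()` + `simulate_sites()` produce a cohort of
`n_focal_diploids` genomes plus a divergence contrast with:

* **Neutral polymorphism**: segregating sites planted at per-site density
  $s = \pi_0 H_{n-1}$ with derived-allele counts $k \sim 1/k$ (the standard
  neutral frequency spectrum), derived alleles assigned uniformly to
  chromosomes via a sequential hypergeometric split over the fixed diploid
  pairing. Since $\sum_k \frac{1/k}{H_{n-1}} \cdot
  \frac{2k(n-k)}{n(n-1)} = \frac{1}{H_{n-1}}$, the expected per-site
  unbiased heterozygosity is exactly `pi_background` — the closed-form
  oracle behind the parameter-recovery tests.
* **Divergence**: sites where the divergence sample is homozygous-alternate
  (or heterozygous, with probability `het_fraction_of_divergence`), giving
  $E[D] = d\,(1 - 0.5\,h)$ exactly.
* **Sweeps**: intervals whose polymorphic density is multiplied by
  `diversity_factor`; divergence is untouched, as expected for a recent
  sweep.
* **Artifacts**: per-site injection of low-depth, low-GQ, low-QUAL,
  missing-genotype and multi-allelic records, one class per position, which
  the filter stack must remove; plus an optional high-GC reference tract
  for the window-level GC filter.

The divergence contrast is carried by a dedicated sample (`div1`) rather
than doubling up one focal genome. With a shared sample, neutral
polymorphic sites would leak into $D$ (adding $\pi_0 (n-1)/n$, roughly half
the divergence signal at the defaults) and no clean closed-form expectation
would exist. Real studies *do* reuse a focal genome — the scan accepts any
sample as `divergence_sample` — but the generator keeps the two processes
separable so every test has an exact oracle.

Outside artifacts, depth is constant at 20 reads and genotype quality at
60. Stochastic depth would make the top tail of clean sites exceed any
percentile ceiling by construction, so background depth noise and
filter-triggering artifacts cannot be separated; holding background depth
constant makes "zero artifact rates ⇒ every site passes" an exact
invariant, and the ceiling machinery is exercised by explicit artifacts and
unit tests instead.

Deliberate non-realism, and what that means for the tests: sites are
independent — there is no linkage, no coalescent tree, no recombination
map. The windowed statistics are per-site sums, so independence does not
affect their correctness, and it buys exact expectations; but it understates
the variance correlation structure of real windows (adjacent windows share
genealogies) and makes simulated sweep edges unrealistically sharp. Passing
the parameter-recovery and power tests therefore validates the estimator
and the pipeline plumbing, not the genome-wide false-discovery behaviour on
linked data. Read-level error models, mapping bias and indels are likewise
out of scope (indel records are skipped on input, with a count).

Both representations of a cohort scan identically: the sparse in-memory
`site_set` (explicit records + a callable background interval) and the
expanded all-sites VCF written by `simulate_region()` produce the same
window table, which the suite asserts to 1e-12. File mode writes one record
per position and is capped at 5 Mb; multi-megabase studies use the sparse
path.

## Problem sizes

The test suite and the acceptance script size their simulations so the
whole battery runs in minutes on one core while keeping the statistics
well-powered: 10 Mb (100 windows) for parameter recovery, 100 seeded 10 Mb
replicates for sweep-detection power (the sweep window must reach the
minimum attainable empirical p, 1/100), and 50 Mb in 50 kb windows
(1,000 windows) for the information diagnostic, where the null standard
error of Spearman's $\rho$ is $\approx 1/\sqrt{999} = 0.032$, comfortably
inside the $|\rho| < 0.1$ acceptance band. At these sizes the sparse
generator emits 1.2–1.5 million explicit sites at most, a few tens of MB.

## Known limitations

* Empirical p-values are relative, not absolute: they flag the most extreme
  fraction of the genome regardless of whether any sweep occurred. On truly
  neutral data the `p < 0.01` set is pure noise by construction.
* The ancestral-state convention (reference = ancestral) mispolarises sites
  where the reference lineage is derived.
* The per-sample depth ceiling assumes each sample's depth distribution is
  stationary along the genome; strong mappability variation violates this.
* `D = 0` windows carry real information (extreme conservation) that the
  ranking deliberately ignores.
* The flanking-divergence counter takes an explicit interval; it does not
  choose a flank size for you.
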