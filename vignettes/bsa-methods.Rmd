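---
title: "Mapping a QTL by bulk segregant analysis of pooled RIL sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a QTL by bulk segregant analysis of pooled RIL sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The mapping problem

Two *C. elegans* wild isolates, CB4932 and JU1242, differ strongly in the
final anteroposterior position of the QR.pap neuron, scored on a relative
scale from 0 to 27 defined by the V seam-cell nuclei (parental means 4.16
versus 5.54, with the JU1242 allele acting mostly dominantly). `bsamap`
implements the analysis used to map this difference: 200 recombinant inbred
lines (RILs) are derived from the cross by selfing single descendants to the
F5 generation, 20 animals are phenotyped per line, the 40 most anterior and
40 most posterior lines are pooled and sequenced at roughly 20x coverage,
and the genome is scanned for regions where the pools' allele frequencies
diverge. Because the real raw reads live in a sequence archive and the
upstream alignment/variant-calling pipeline is standard external tooling,
the package's contract starts at per-site allelic depths — and a forward
simulator of the whole design generates statistically faithful inputs so
every stage can be exercised and tested without downloads.

## The cross simulator

`simulate_ril_population()` follows one selfing chain per line: the fully
heterozygous F1 produces two independent gametes per generation, four
generations deep by default (F5). Meiosis uses a Poisson crossover count per
chromosome with mean `length_cM / 100` and breakpoints uniform on the
genetic map — the Haldane model without interference, chosen because it is
the standard default with closed-form checks: the gamete recombinant
fraction between markers separated by *d* Morgans is `(1 - exp(-2d))/2`,
per-marker heterozygosity halves each selfing generation (`1/16` at F5),
and the RIL recombinant fraction converges to the Haldane–Waddington limit
`2r/(1+2r)`. The test suite verifies all three against their closed forms.

The default genome has six chromosomes of C. elegans-like physical size and
50 cM genetic length each, with one marker per 10 kb (configurable). Genetic
position is linear in physical position within a chromosome; the simulator
does not model the recombination-rate structure of real chromosome arms and
centers, which matters for fine-scale interval width but not for the
statistical behavior of the scan.

The QTL model is a single locus: genotype means `mean_AA = 4.16` and
`mean_BB = 5.54` reproduce the parental lines, and the dominance
coefficient default `h = 0.85` places heterozygotes near 5.33, the
F1 value observed in the dominance test. The residual (within-line)
standard deviation is not published numerically — the figures show only
dispersion bars — so `residual_sd = 0.6` is a documented free calibration
parameter of the simulator, of the order suggested by those bars. Phenotypes
are clamped to the bounded 0–27 scale. Lines are phenotyped on the F5
diplotype directly; the one extra selfing of the real F6 scoring (residual
heterozygosity 1/32 rather than 1/16) can be requested via
`n_generations = 5` and has no visible effect on the scan. The QTL genotype
of a line is read at the nearest marker at or to the left of the QTL
position — a deterministic rule that avoids interpolating genotypes.

Pooling assumes equal DNA contribution per line (nothing is published about
pooling bias). Sequencing is Poisson depth around the mean coverage with a
symmetric per-read error rate (default 0.001); a negative-binomial
over-dispersion layer is deliberately omitted as the simplest model
consistent with a stated mean coverage. Variant parental origin alternates
JU1242/CB4932 along the map so both allele-frequency rules are exercised.
The simulator does not model selection, mutation, segregation distortion,
or the exclusion of lines with abnormal migration patterns; passing tests
therefore show that the scan behaves correctly under idealized Mendelian
pooling, not that real libraries are free of such artifacts.

## The scan

For each site the JU1242 allele frequency in a pool is `read_var/read_tot`
when the ascertained variant comes from JU1242 and `1 - read_var/read_tot`
when it comes from CB4932. Sites need coverage *strictly greater than* 10 in
both pools ("higher than ten" read literally; a site at exactly 10 is
dropped, and the boundary is tested). Frequencies are then smoothed in
sliding windows of 200 bp — 1-based, half-open `[anchor, anchor + 200)` —
and the statistic is computed on the smoothed tracks, in that order.

With realistic inter-isolate SNP densities most 200 bp windows are empty
and a 1 bp step makes adjacent windows near-duplicates, so the default
smoothing mode emits one window per *distinct SNP content* (at the leftmost
anchor realizing it, reported at the floored window midpoint). This is
exactly the step-1 scan after deduplication; an `"exhaustive"` mode emits
every anchor for strict fidelity and is compared against a brute-force
windowed mean in the tests. Window means are unweighted; weighting SNPs by
depth is a plausible alternative that the source analysis does not specify.

The statistic converts the smoothed frequencies to line counts
`m_i = f_i * 40` and contrasts the pools as

```
LOR = log( ((m1 + 1e-6) / (40 - m1 + 1e-6)) /
           ((m2 + 1e-6) / (40 - m2 + 1e-6)) )
```

with `m1` the posterior (high) pool and `m2` the anterior pool. The
pseudocount keeps the statistic finite at fixation (`LOR = 2 log(4.0000001e7)
≈ 35.01` at opposite fixation). The log base is natural: the base rescales
the statistic and its simulated threshold identically, so which intervals
are called is base-invariant.

The significance threshold is simulated: one million independent draws of
`m1, m2 ~ Binomial(40, 1/2)` — the null line-count distribution of a
40-line pool at an unlinked locus — and the empirical `alpha/2` and
`1 - alpha/2` quantiles (type-1, so thresholds are attainable statistic
values) give two-sided thresholds at `alpha = 0.001`. The two-sided split
matches the symmetric threshold lines of the original analysis. A
Monte-Carlo threshold at one million draws is indistinguishable in practice
from the exact product-binomial quantile over the 41 x 41 outcome grid; the
tests enumerate that grid and require agreement within one attainable-value
spacing. One genome-wide threshold is used, not a per-site correction,
replicating the published procedure.

Maximal runs of consecutive emitted positions beyond a threshold become
candidate intervals, labeled by which pool carries the elevated JU1242
frequency, with the peak position (largest `|LOR|`, leftmost on ties) and —
mirroring the fixed region observed over a strong QTL — the longest sub-run
where the favored pool's smoothed frequency is within `fixation_eps = 0.02`
of 1.

## What the null does and does not capture

The binomial null models only RIL segregation sampling: which 40 of the
possible RIL genotypes ended up in each pool. At 20x coverage with ~1 SNP
per window, read sampling adds per-site variance of roughly
`f(1-f) E[1/depth] ≈ 0.013` per pool on top of the segregation variance
`0.25/40 ≈ 0.006`, so isolated sites exceed the segregation-only threshold
far more often than `alpha` under a global null (the package's own
calibration experiment measures ~6% per-site exceedance). Single-site
excursions are visually obvious on a scan and a true QTL produces a broad
contiguous run, so the published procedure remains effective for detection,
but the nominal per-site level should not be read as a false-positive rate.
`simulate_threshold(null = "pool_and_reads")` additionally resamples
Poisson depth and binomial reads per pool; under it the measured exceedance
returns to the nominal level. The default remains the segregation-only
null, faithfully reproducing the original analysis.

## Phenotype statistics

Parental contrasts use the Wilcoxon rank-sum test in the
`W = ranksum(x) - n_x(n_x+1)/2` convention (mid-ranks under ties, normal
approximation with tie and continuity correction; exact mode available for
untied samples), delegated to `stats::wilcox.test()`. Cross and
introgression-line comparisons use Kruskal–Wallis followed by Dunn's test
(pooled mid-ranks, tie-corrected standard error) with Bonferroni adjustment
over all pairs, and a compact letter display computed by insert-and-absorb
so that two groups share a letter exactly when their adjusted comparison is
not significant. Dunn's raw p-values are two-sided by default;
`p_type = "one.sided"` reproduces the halved-p convention of the widely
used `dunn.test` R package (an adjusted p of ~0.15 for `|Z| = 1.97` over
six comparisons is only consistent with that convention).

## Numerical and design choices

* Pool membership ties are broken by line id, making pool selection
  deterministic.
* Thresholds are empirical type-1 quantiles; the lower and upper thresholds
  are reported separately rather than symmetrized (they agree to within the
  local spacing of attainable values).
* All simulation entry points take a seed and leave the global RNG state
  untouched; population simulation derives one child seed per line from the
  root seed, so populations are reproducible and lines exchangeable.
  `run_pipeline()` derives its three stage seeds (population, reads,
  threshold) from the single config seed and logs them; rerunning a config
  gives byte-identical outputs.
* Coordinates are 1-based inclusive internally; BED output converts to
  0-based half-open at the boundary only.
* Degenerate inputs fail loudly: zero-coverage sites in the frequency rule,
  empty tables after filtering, empty pools, unknown chromosomes, and
  malformed VCF records (missing `AD`) all raise labeled errors.

## Problem sizes used by the tests

The packaged checks run the full study design where it matters — 200 lines,
40+40 pools, 20x depth — with 50 replicate scans for QTL recovery on the
10 kb marker grid and 20 replicates at ~2,000 sites for null calibration;
closed-form genetics checks use 5,000 replicate lines on small marker maps.
These sizes give Monte-Carlo standard errors comfortably below the margins
being asserted while keeping a desktop run in minutes.

## Limitations

* Linear genetic maps and free-scaling marker grids ignore arm/center
  recombination structure and real SNP ascertainment density.
* The segregation-only null under-covers per site at moderate coverage
  (above); interval calls on sparse single-SNP windows should be read
  accordingly.
* Equal per-line DNA contribution is assumed; a Dirichlet line-weight
  option would be needed to model pooling noise.
* The letter display is validated structurally (clique cover of the
  non-significance graph), not against any published figure lettering,
  whose pairing conventions are not fully recoverable.

## A minimal run

```{r pipeline, eval = FALSE}
cfg <- bsa_config(seed = 1)          # full published design, chrIV QTL at 5.2 Mb
run <- run_pipeline(cfg, "bsa_out")  # writes TSV/VCF/BED/JSON reports
run$result$intervals
plot(run$result)
```
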