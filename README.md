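# bsamap

Bulk segregant analysis (BSA) QTL mapping for selfing crosses, with a
built-in simulator of the whole experimental design.

## The problem and who this is for

Two *C. elegans* wild isolates, CB4932 and JU1242, differ in the final
anteroposterior position of the QR.pap neuron (parental means 4.16 vs 5.54
on the 0–27 V-cell scale). The mapping design behind this package: cross
the isolates, self single descendants to the F5 generation to obtain 200
near-homozygous recombinant inbred lines (RILs), phenotype 20 animals per
line, pool the 40 most anterior and the 40 most posterior lines, sequence
both pools at ~20x, and scan the genome for regions where the pools' allele
frequencies diverge — on chromosome IV the JU1242 allele goes to fixation
in the posterior pool over a ~1.5 Mb region, revealing the QTL.

`bsamap` is for quantitative geneticists running (or teaching) this kind of
pooled-sequencing BSA in selfing species. The pipeline starts from per-site
allelic depths (TSV or a minimal VCF with `AD` fields); read mapping and
variant calling are upstream, standard tools. Because the package also
simulates the cross, the pooling and the sequencing, every stage can be
exercised, calibrated and tested without any external data.

## The statistic

Per site, the JU1242 allele frequency of a pool is `readVar/readTot` for
variants ascertained in JU1242 and `1 − readVar/readTot` for variants from
CB4932. Sites need coverage strictly greater than 10 in both pools;
frequencies are smoothed in sliding 200 bp windows (step 1 bp, deduplicated
to distinct SNP contents) and the pools are contrasted with a pseudocounted
log-odds ratio on the line-count scale (`m_i = f_i · 40` for 40 RILs per
pool):

    LOR = log( ((m1 + ε) / (40 − m1 + ε)) / ((m2 + ε) / (40 − m2 + ε)) ),   ε = 1e-6

with `m1` the posterior pool and `m2` the anterior pool (natural log). The
genome-wide two-sided significance threshold at α = 0.001 is the empirical
quantile of one million null draws `m1, m2 ~ Binomial(40, ½)`; maximal runs
of positions beyond a threshold become candidate QTL intervals, annotated
with their peak and with the sub-region where the favored pool's frequency
is within 0.02 of fixation.

Also included: the forward simulator (Poisson crossovers under the Haldane
map, selfing to near-homozygosity, a one-QTL phenotype model, idealized
chromosome-substitution lines) and the nonparametric phenotype statistics
used around such crosses — Wilcoxon rank-sum, Kruskal–Wallis with Dunn's
post hoc test (Bonferroni), and a compact letter display.

## Worked example

Simulate the full published design (200 F5 RILs, QTL at 5.2 Mb on chrIV,
40+40 pools at 20x) and scan it:

```r
library(bsamap)
cfg <- bsa_config(seed = 1)          # the full design, one root seed
run <- run_pipeline(cfg, "bsa_out")  # writes TSV/VCF/BED/JSON reports
#> simulate: 200 lines, 4 selfing generations, 20 animals/line (seed 1140350788)
#> pool: 2 x 40 extreme lines
#> sequence: mean depth 20, error rate 0.001 (seed 312928385)
#> scan: window 200 bp, min coverage > 10, alpha 0.001, 1000000 null draws (seed 866248189)
#> report: writing bsa_out

iv <- run$result$intervals
iv[iv$n_positions >= 50, ]
#> # A tibble: 4 × 10
#>   chrom   start     end direction n_positions peak_pos peak_lor fixed fixed_start fixed_end
#>   <chr>   <int>   <int> <chr>           <int>    <int>    <dbl> <lgl>       <int>     <int>
#> 1 chrIV  939900 1799900 pool2              85  1759900     19.2 TRUE      1069900   1069900
#> 2 chrIV 1819900 2619900 pool2              78  2429900     35.0 TRUE      2079900   2079900
#> 3 chrIV 2639900 7909900 pool2             517  2969900     35.0 TRUE      5309900   5369900
#> 4 chrIV 7929900 8489900 pool2              57  7969900     20.2 TRUE      7969900   7969900
```

The broad runs sit on chromosome IV only, in the `pool2` direction (JU1242
enriched in the posterior pool). The widest one spans 2.6–7.9 Mb and
contains the simulated QTL at 5.2 Mb with `peak_lor = 35.0` — the value of
the statistic at opposite fixation, `2·log(4.0000001e7)` — and a fixed
sub-region around the QTL. The two pools' mean phenotypes
(`run$summary$pool_means`) are 4.04 and 5.68, bracketing the parental means
4.16 and 5.54 as truncation selection on a mostly-dominant QTL predicts.
Short single-window excursions elsewhere are expected: the binomial null
models segregation sampling only, so isolated sites exceed it more often
than α at 20x coverage (quantified and discussed in the methods vignette;
a read-aware null is available via `simulate_threshold(null =
"pool_and_reads")`).

Phenotype statistics work on plain group/value tables:

```r
d <- read_phenotype_groups("phenotypes.csv")
dunn_test(d$value, d$group)          # Kruskal-Wallis + Dunn (Bonferroni)
compact_letters(dunn_test(d$value, d$group), level = 0.05)
```

A thin command-line wrapper with `run`, `simulate`, `threshold`, `bsa` and
`stats` subcommands ships at `inst/scripts/bsamap.R`.

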