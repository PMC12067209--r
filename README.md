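# aneuploidr

Changing the copy number of a chromosome arm (aneuploidy) perturbs gene
expression far beyond the varied segment. Genes on the varied arm (*cis*)
may scale with their dose (a **dosage effect**, aneuploid/control ratio
`d/2` on a diploid background — 1.5 in trisomy, 0.5 in monosomy) or stay
put (**dosage compensation**, ratio 1); genes on the rest of the genome
(*trans*) are most often modulated *opposite* to the dose change (the
**inverse effect**, ratio `2/d`), sometimes with it (a **direct effect**,
`d/2`). On top of these relative changes, whole-transcriptome output per
genome copy — the **transcriptome size** — can shrink or grow, a shift that
library-normalized RNA-seq ratios cannot see at all.

`aneuploidr` is a tidyverse-style toolkit for studying these effects in
chromosome-arm dosage series (single arms and two-arm combinations such as
monosomy 3L + trisomy 4L), aimed at anyone analyzing or simulating
aneuploid transcriptomes:

* **Simulator with known truth** — a synthetic genome
  (`build_genome()`), per-gene effect-class assignment with expected
  ratios `r_g` (`assign_effect_classes()`, multi-arm trans responses
  composed multiplicatively/additively/dominantly via
  `compose_trans_ratio()`), gamma-Poisson RNA-seq counts whose expected
  value is `L * A_g / sum(A)` with `A_g = mu_g * r_g`
  (`simulate_counts()`; the true size factor `T = sum(A)/sum(mu)` is
  recorded but invisible to the counts), and paired ddPCR panels of 10
  cDNA + 6 gDNA amplicons (`simulate_ddpcr()`).
* **Ratio-distribution pipeline** — RPKM normalization, replicate
  averaging, the "summed mean < 1" low-expression filter,
  aneuploid/control ratios, per-arm cis vs trans partition, 0.05-width
  histogram bins and per-partition medians
  (`normalize_rpkm()` ... `ratio_medians()`, `bin_ratios()`).
* **Distribution statistics** — two-sample Kolmogorov–Smirnov and
  Bartlett tests between labeled ratio sets, a Welch-t
  differential-expression caller on log2 expression with
  Benjamini–Hochberg adjustment, and %unchanged / %SU / %SD modulation
  summaries (`ks_two_sample()`, `bartlett_groups()`, `call_de()`,
  `summarize_modulation()`).
* **Transcriptome-size estimator** — genome-normalized expression: each
  panel gene's cDNA signal is normalized to six gDNA amplicons and
  averaged, the aneuploid/control ratio of that quantity is divided by the
  RNA-seq relative expression, giving ten per-gene estimates of `T`; a
  2-SD outlier rule, the mean ± SE and a test against 1.0 summarize them
  (`per_genome_expression()`, `per_transcriptome_expression()`,
  `size_estimates()`, `filter_outlier_estimates()`, `estimate_size()`).
* **Pipeline** — `run_config()` + `run_simulate()` / `run_analyze()` /
  `run_size()` / `run_report()` write a fully reproducible output tree
  from one seed; `inst/cli/aneuploidr` is a thin command-line front end.

## Worked example

Simulate a monosomy 3L + trisomy 4L combination with the default class
mixtures (40% cis dosage effect, 35% trans inverse), then run the ratio
pipeline and the size estimator:

```r
library(aneuploidr)

genome <- build_genome(2000, seed = 42)
gt <- genotype(c("3L" = 1, "4L" = 3))   # monosomy 3L + trisomy 4L
assignment <- assign_effect_classes(genome, gt, seed = 42)
sim <- simulate_counts(genome, assignment, gt, dispersion = 0.05, seed = 42)
sim
#> <aneuploid_sim> 2000 genes x 6 samples, true size factor T = 1.065

norm <- normalize_rpkm(sim$counts, setNames(genome$length, genome$gene_id))
ratios <- average_replicates(norm, sim$samples) |>
  filter_low_expression() |>
  compute_ratios() |>
  add_partition(genome, gt)
ratio_medians(ratios)
#> # A tibble: 3 × 3
#>   partition     n median
#>   <chr>     <int>  <dbl>
#> 1 cis:3L      100  0.738
#> 2 cis:4L      100  1.16
#> 3 trans      1800  0.997
```

The cis medians sit between full dosage effect and full compensation
(0.5 < 0.74 < 1 for the monosomic arm, 1 < 1.16 < 1.5 for the trisomic
one), exactly the partial-compensation signature seen in real dosage
series. Note the medians are *relative*: each gene's ratio is `r_g / T`,
so the 6.5% true size increase is silently divided out. The ddPCR-based
estimator sees it instead:

```r
panels <- simulate_ddpcr(genome, assignment, gt, cv = 0.1, seed = 42)
means <- average_replicates(norm, sim$samples) |> filter_low_expression()
est <- size_estimates(
  per_genome_expression(panels),
  per_transcriptome_expression(means, panels$panel_genes)
) |>
  filter_outlier_estimates() |>
  estimate_size()
est
#> <size_estimate> mean = 0.9115, SE = 0.0552 (n = 10/10 retained), p vs 1.0 = 0.143
```

`tidy(est)` returns the ten per-gene estimates with their retained flags,
`glance(est)` the one-row summary, and `autoplot(est)` (as for
`bin_ratios()` and `scatter_table()` results) a ggplot display.

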