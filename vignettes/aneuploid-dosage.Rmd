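---
title: "Dosage effects, ratio distributions and transcriptome size: the models behind aneuploidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage effects, ratio distributions and transcriptome size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The dosage-response model

`aneuploidr` treats an aneuploid transcriptome as a set of genes with a
baseline per-cell abundance $\mu_g$ and an expected aneuploid/control
ratio $r_g$ determined by the gene's dosage-response class. On a
background ploidy $p$ (2 throughout), a gene on an arm varied to dose $d$
is *cis*; all other genes are *trans*. The classes and their ratios:

| class            | partition | $r_g$  | meaning |
|------------------|-----------|--------|---------|
| `dosage_effect`  | cis       | $d/p$  | expression proportional to copy number (1.5 in trisomy, 0.5 in monosomy) |
| `compensation`   | cis       | $1$    | expression unchanged despite the dose change |
| `inverse`        | trans     | $p/d$  | modulation opposite to the dose change (2/3 in trisomy, 1/2 in tetrasomy, 2 in monosomy) |
| `direct`         | trans     | $d/p$  | modulation with the dose change |
| `no_change`      | trans     | $1$    | unaffected |

By construction the inverse effect exactly offsets a dosage effect
($r_{\text{dosage}} \times r_{\text{inverse}} = 1$ at every dose), which
is the regulatory intuition behind trans-acting inverse modulation.

When two arms are varied at once, a trans gene responds to both. How the
per-arm responses combine is an empirical question, so
`compose_trans_ratio()` exposes three rules: **multiplicative**
($\prod_a r_a$, the default, chosen because multiplicative responses are
the striking observation in monosomy + trisomy combinations and because
the product rule is the natural model for independently acting
regulators), **additive** ($1 + \sum_a (r_a - 1)$, floored at a small
positive value so a stack of strong reductions cannot drive an abundance
negative), and **dominant** (the per-arm ratio largest in magnitude on
the log scale). The simulator takes no position on which rule real trans
responses follow; it makes each available with known truth.

## What sequencing sees: compositional counts

True abundance is $A_g = \mu_g r_g$; the true transcriptome-size factor
is

$$T = \frac{\sum_g A_g}{\sum_g \mu_g},$$

recorded by `simulate_counts()` to machine precision. Sequencing,
however, is sampled to a fixed depth $L$: the expected count of gene $g$
is $L\,A_g / \sum A$ in an aneuploid sample and $L\,\mu_g / \sum \mu$ in
a control. Two consequences follow and are both asserted bit-exactly in
the test suite:

1. **Scale invariance.** Multiplying every $A_g$ by a constant leaves the
   counts byte-identical. A pure transcriptome-size change is invisible
   to the count matrix and to everything downstream of it.
2. **Compositional ratios.** At zero dispersion every empirical
   aneuploid/control ratio equals $r_g / T$. Pipeline medians are
   therefore $(d/p)/T$ rather than $d/p$: in a trisomy where the varied
   arm carries about 5% of baseline expression and every cis gene shows a
   dosage effect, $T = 1.025$ and the cis median reads
   $1.5/1.025 \approx 1.46$ — the familiar "slightly below 1.5" of real
   dosage series, here arising purely from normalization. The product
   (median $\times\ T$) recovers the class ratio exactly, which is how
   the acceptance tests pin the model down.

Counts are gamma-Poisson: mean as above, variance
$\mu + \phi\mu^2$ via `rnbinom(size = 1/phi)`. A single genome-wide
dispersion is deliberate minimalism — it gives exact oracles at
$\phi = 0$ and realistic replicate scatter at the default
$\phi = 0.05$, a typical bulk RNA-seq value for biological replicates.

## The ratio-distribution procedure

The analysis pipeline mirrors the published display conventions:
normalized counts (RPKM, $x \cdot 10^9 / (L \cdot \text{length})$) are
averaged over biological replicates; genes whose summed aneuploid +
control means fall strictly below 1 are filtered as lowly expressed (the
boundary sum of exactly 1 is retained); ratios are formed aneuploid over
control; genes are partitioned per varied arm (`cis:3L`, `cis:4L`, ...)
against a single trans set that excludes the cis genes of *every* varied
arm; ratios are binned at width 0.05 and summarized by per-partition
medians.

Numerical choices a reader should know:

* **Bins** are half-open and left-closed, $[kw, (k+1)w)$. Because 1.05 is
  not exactly representable in binary, the bin index is computed as
  $\lfloor x/w + 10^{-9}\rfloor$: a ratio printed as sitting on an edge
  lands in the right-hand bin, while genuinely interior values are
  unaffected. Ratios at or above the display cap (default 3.0) pool into
  an overflow bin; medians always use uncapped values.
* **Zero control means** would give infinite ratios; such genes are
  flagged, excluded from medians, and counted in the overflow bin so that
  bin totals still conserve the retained gene count.
* **Medians** use the standard convention (mean of the central pair at
  even $n$).
* The low-expression threshold applies to the same normalized scale the
  ratios are computed on.

## Statistics

Two labeled ratio sets are compared with the two-sample
Kolmogorov–Smirnov test (asymptotic p, effective $n = n_x n_y/(n_x+n_y)$;
tie warnings from discrete data are suppressed because at thousands of
genes the asymptotic p is the right object) and with Bartlett's test for
equal variances. The API accepts any labeled pair and records the labels
rather than hard-coding particular comparisons, since which sets are
pooled is a per-study choice.

Differential expression uses a per-gene Welch $t$ on
$\log_2(x + 0.5)$ with Benjamini–Hochberg adjustment and calls at
$q < 0.05$ signed by the log-fold change. This deliberately simple caller
preserves the decision surface the modulation summaries need
(%unchanged in cis; %SU, %SD, %DE in trans) without any dispersion
shrinkage; genes constant in both groups get $p = 1$ when the means agree
and $p = 0$ otherwise, so a noiseless null yields zero calls.

## Transcriptome size from genome-normalized expression

The estimator compares what ddPCR sees (mRNA per genome copy) with what
RNA-seq sees (mRNA per transcriptome). In a total nucleic acid
preparation the cDNA signal of panel gene $g$ is proportional to $A_g$
and each gDNA amplicon to its arm's copy number. For each of the 10 panel
genes, the cDNA concentration is normalized to each of the 6 gDNA
amplicons and the six ratios averaged *before* the aneuploid/control
ratio is formed (this order matches the stated procedure and cancels
amplicon-specific efficiency). Dividing that per-genome relative
expression by the RNA-seq relative expression gives

$$E_g = \frac{r_g}{r_g / T} = T$$

for every panel gene under zero noise, whatever the gene's own class —
the estimator's identifiability, tested exactly for
$T \in \{0.25, 0.5, 1, 1.5, 2\}$.

Choices and their rationale:

* **gDNA amplicons sit on six unvaried arms** so the genome normalization
  is dose-neutral and the estimator unbiased; the estimates are invariant
  to which unvaried arms are chosen (tested). Placing an amplicon on a
  varied arm is rejected as a configuration error.
* **Measurement noise** is mean-preserving log-normal with a stated CV on
  every measured concentration; droplet-level Poisson statistics are not
  modeled because the analysis consumes concentrations, not droplet
  counts. Three replicate samples per genotype are simulated by default,
  matching the replicated leaf sampling of the RNA-seq arm.
* **Outlier rule**: single pass; sample SD with $n-1$; an estimate is
  removed iff its absolute deviation from the mean is $\ge 2$ SD; the
  boundary case removes; an all-equal panel (SD 0, where the rule is
  undefined) removes nothing, and a spread indistinguishable from
  floating-point noise on the mean is treated as zero. Removing more than
  half the panel triggers a data-quality warning; removing everything is
  an error. The reported mean is the post-removal mean.
* **Significance of a size change** uses a two-sided one-sample $t$
  against 1.0 on the retained estimates — the natural location test for
  "mean of 10 estimates with an SE bar", since no specific test is
  prescribed by the assay itself.

## What the simulator does and does not emulate

The generator reproduces the features the analyses are sensitive to:
per-gene expected ratios by class, multi-arm composition, a global size
factor invisible to normalized counts, overdispersed replicate counts,
and paired cDNA/gDNA signals with multiplicative noise. It deliberately
omits: a silent/low-expression gene fraction (baseline expression is a
single log-normal, so the low-expression filter rarely fires on
simulated data — its boundary behavior is tested on constructed tables),
gene-length and GC biases, batch effects, unequal arm gene counts
(default: 20 equal arms of 5% each, the few-percent share of a typical
translocated arm segment), isoform structure, and droplet quantification.
Passing tests therefore demonstrate the correctness of the *procedures*
under a controlled generative model, not robustness to every artifact of
real RNA-seq.

## Known limitations

* **Correlated size estimates.** All ten per-gene estimates within a
  panel share the same six gDNA measurements, so they carry a common
  error component of roughly $\mathrm{CV}\cdot\sqrt{2/ (6\,n_s)}$ that
  averaging over genes cannot reduce. The SE across the ten estimates —
  and hence the one-sample $t$ — assumes independence and understates
  the true sampling error: at CV = 0.1 the test against 1.0 rejects a
  true null in roughly 20% of simulations rather than 5%. This is a
  property of the estimator's published error model itself, faithfully
  reproduced here; interpret the size-change p-values accordingly, or
  replicate panels with independently measured gDNA if calibrated
  inference is needed.
* **Recovery under combined noise.** With ddPCR CV 0.1 alone the mean
  estimate lands within 10% of the true $T$ in about 97% of simulations;
  adding count dispersion $\phi = 0.05$ (per-replicate CV
  $\ge \sqrt{\phi} \approx 0.22$ on the RNA-seq side) drops this to
  roughly 84% with 3 replicates and 10 panel genes — a noise floor, not
  an implementation artifact.
* Pipeline medians are compositional ($r/T$), as discussed above; they
  quantify relative modulation only.

## Problem sizes and reproducibility

The shipped default configuration simulates 2000 genes, 3 replicates per
group and a monosomy + trisomy combination, which runs end-to-end in a
few seconds; the stochastic calibration checks in the test suite use
1000-gene genomes and 200–500 Monte-Carlo repetitions, sizes at which
the binomial error bands quoted in the tests are meaningful. Every stage
draws its randomness from a fixed sub-seed of the single configuration
seed, so a rerun of `run_simulate()` with the same configuration is
byte-identical, and `scripts/acceptance.R --seed N` is fully determined
by `N`.
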