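---
title: "DMR calling with a quadratic-assignment permutation null"
author: "methperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DMR calling with a quadratic-assignment permutation null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methperm)
```

## The statistical model

`methperm` analyses per-CpG bisulfite counts from a balanced two-group
design with few biological replicates, the situation typical of
whole-genome bisulfite studies in social insects. Three models are
stacked:

**Site level.** A CpG with `m` methylated out of `n` total reads is
tested against the null that it is unmethylated and that methylated reads
are bisulfite conversion failures:

$$p = P[X \ge m], \qquad X \sim \mathrm{Binomial}(n, \varepsilon),$$

where the nonconversion rate $\varepsilon$ is the pooled methylated-read
fraction over all cytosines of an unmethylated lambda-phage spike-in.
The test is one-sided because genuine methylation can only push the
methylated fraction above the error rate. The tail is computed exactly
(`pbinom`), and Benjamini–Hochberg adjustment is applied across all sites
*within a sample*; a site is "methylated" at `q < 0.05`. Conventions:
`m = 0` or `n = 0` give `p = 1`; with $\varepsilon = 0$ any `m > 0`
gives `p = 0`. If no spike-in is available the caller requires an
explicit $\varepsilon$ — there is no silent default.

Strands are merged first: the minus-strand G of a CpG (one bp right of
the plus-strand C) is summed into the C coordinate, because
strand-asymmetric methylation in such data is overwhelmingly a
low-coverage sampling artifact. `hemimethylation_by_coverage()` provides
the diagnostic: mean absolute strand discordance per coverage bin, which
decreases monotonically with coverage when methylation is
strand-symmetric.

**Window level.** Sites that are methylation-significant in at least one
sample, covered (`n >= 1`) in every sample and at `n <= 170` in every
sample (a PCR-duplicate guard) are tiled into fixed, non-overlapping
200 bp windows; windows with fewer than two retained CpGs are dropped.
The 200 bp width approximates the median exon length of the genomes this
design targets (~176 bp), so windows map naturally onto exons. Each
window is tested by a binomial logistic regression of per-sample
`(m, n)` on group membership with a likelihood-ratio test. With a single
binary covariate the maximum-likelihood fits are the group-pooled
proportions, so the deviance difference has the closed form of a 2×2
G-test on pooled group counts; the package computes that closed form
(vectorized over windows) and the test suite asserts equality with
`stats::glm`. No overdispersion correction is applied by default. A
pooled two-sided Fisher exact test is available as an alternative
backend and small-sample oracle. A window is a DMR when the
BH-adjusted `q < 0.01` and the pooled methylation difference is at least
5 percentage points in absolute value (the boundary is inclusive and
configurable). Windows with a whole group uncovered are excluded from
the FDR family rather than assigned `p = 1`. The difference sign is
positive when the *case* group ("care" by default) is higher.

**Genome level (QAM).** The number of DMRs alone does not show that the
grouping matters; the quadratic-assignment permutation answers that. All
balanced relabelings of samples to groups are enumerated, collapsing
complementary label swaps into one partition and excluding the original
assignment — $\binom{2g}{g}/2 - 1$ relabelings, i.e. nine for 3-vs-3.
The *complete* window analysis (test, its own BH family, both
thresholds) is re-run under each relabeling, and each region receives a
probability $k/K$ of being a DMR. The null distribution of the
genome-wide DMR count treats regions as independent Bernoulli draws with
those probabilities: 50,000 Monte-Carlo tallies by default, or the exact
Poisson-binomial pmf by dynamic-programming convolution
(`null_distribution_exact()`), which also serves as the oracle for the
Monte-Carlo path. The summary reports the null mean and maximum, an
add-one empirical p-value $(1 + \#\{draws \ge obs\})/(1 + n)$ — ties
count in the tail, and the estimator can never return zero — and the
per-DMR chance $100 \cdot \text{null mean}/\text{observed}$, the
expected fraction of observed DMRs attributable to chance.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` (site) | 0.05 | per-sample FDR for the methylated call |
| `max_cov` | 170 reads | per-sample coverage ceiling before windowing |
| `window_size` | 200 bp | fixed tiling width |
| `min_cpg` | 2 | minimum CpGs per tested window |
| `q_threshold` | 0.01 | window FDR ceiling for a DMR |
| `min_diff` | 5 pp | minimum absolute pooled difference |
| `n_iter` | 50,000 | Monte-Carlo draws for the QAM null |
| cutoff (gene) | 5% | strict `>` threshold for a methylated gene |

Gene-level methylation is the coverage-weighted level
`sum(m)/sum(n)` over all CpGs in the full gene span (introns included);
a gene is "methylated" when the level exceeds 5% in at least one sample,
and a gene with no covered CpG carries an undefined level (`NA`), never
zero.

## What the generator emulates — and what it does not

`simulate_study()` fixes the study conditions the package is tested
under: a balanced 3-vs-3 design; per-strand negative-binomial coverage
with mean 15 (merged CpG coverage ~30X, inside the 21–37X band typical
of such experiments) and dispersion 0.2; nonconversion 0.005; 25% of
genes methylated at $\pi = 0.7$ on first exons with geometric decay 0.7
per exon rank and introns at half the preceding exon's level (the 5'
mosaic bias); 50 planted 200 bp DMR windows inside methylated genes with
an exact per-CpG group difference of 0.20, 84% of them hypermethylated
in the care group; gene sets whose pairwise overlap follows a
configurable odds ratio via Fisher's noncentral hypergeometric; and
expression rank-correlated with true gene methylation at a target
Spearman $\rho$ (default 0.24) solved by bisection on the realized
coefficient, so heavy ties at zero methylation are accounted for.
Exon length defaults to 176 bp, the median exon length that motivates
the 200 bp windows.

The generator does *not* emulate: within-group biological variance of
methylation (an optional beta jitter of $\pi$ exists but is off by
default, since the emulated design pooled many individuals per
replicate); read-level artifacts (mapping bias, duplicate structure,
M-bias); spatial autocorrelation of methylation beyond gene/exon
structure; or chromosome-scale coverage waves. Passing the recovery
tests therefore shows the inference machinery is correct under the
stated sampling model, not that real libraries meet that model.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere in memory; 1-based
  only in files (cytosine reports, GFF3). Window assignment is
  `floor(pos/200)`, so a site at exactly 200 belongs to `[200, 400)`.
* **Per-sample FDR** for site calls (rather than one joint family over
  all samples): the call feeds a per-sample filter, and the families are
  of equal size, so per-sample control is the interpretable choice.
* **Filter order**: significance filter first, then the coverage
  filters, with the site tally after each step recorded in
  `filter_counts` so the order's effect is auditable.
* **Merged counts** are used for the gene-level 5% cutoff, consistent
  with every other gene-level quantity.
* **Relabeling denominator** is the nine non-original partitions; the
  true labeling is not a null draw and is excluded.
* **Empirical p** uses the add-one, tie-inclusive estimator; with an
  exact pmf the tail probability is used instead.
* **Degenerate inputs**: zero lambda coverage is an error; an empty
  relabeling list is an error; a window family of size one reduces BH to
  the identity; a chi-square table with a degenerate margin returns
  statistic 0 and `p = 1` with a warning; odds ratios use Haldane's 0.5
  correction only when a cell is zero.
* **Problem sizes** in the tests and the acceptance script: the default
  synthetic genome is 5 × 100 kb with 200 genes (~10,000 CpGs), and the
  repeated-seed calibration loops use 4 × 50 kb genomes — large enough
  that the window test operates in its intended regime (hundreds of
  reads per group per window) while keeping simulation loops cheap.

## Limitations

* The window test ignores within-group overdispersion; with strong
  biological replicate variance its p-values are anticonservative. The
  QAM null inherits whatever the window test does, which is precisely
  why it is the final arbiter of genome-wide significance.
* The region-independence assumption of the QAM null ignores
  correlation between neighbouring windows of the same gene; a
  region-dependent null is out of scope.
* Only balanced two-group designs are supported by the relabeling
  scheme, and only CpG context is handled.
* Adjacent significant windows are reported separately; no DMR
  stitching is performed.

## A minimal run

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 42))
lambda <- do.call(rbind, lapply(study$methylomes,
                                function(d) d[d$chrom == "lambda", ]))
merged <- lapply(study$methylomes,
                 function(d) merge_strands(d[d$chrom != "lambda", ]))
res <- run_dmr_analysis(merged, attr(study$methylomes, "groups"),
                        estimate_nonconversion(lambda),
                        genes = study$annotation$genes)
run_qam(res$binned, attr(study$methylomes, "groups"),
        sum(res$dmrs$is_dmr), seed = 43)$summary
```
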