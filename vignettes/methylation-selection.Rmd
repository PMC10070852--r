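---
title: "From methylation classes to balancing selection: the episelect models"
author: "episelect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From methylation classes to balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episelect)
```

# Overview

`episelect` links three pieces of machinery: genotype inference from DNA
methylation at a probe that overlaps a CpG-disrupting SNP, classical
genotype/allele-frequency statistics with a Hardy-Weinberg test, and
Tajima's D on haplotypes extracted from a locus alignment. A
synthetic-data layer generates inputs with the statistical structure
each step assumes, so the whole chain is testable end to end.

# The methylation mixture model

## β and M values

A methylation β-value is the fraction of methylated signal at a probe,
in [0, 1]. Analysis happens on the M scale,
$M = \log_2\big(\beta / (1-\beta)\big)$, which is approximately
variance-stabilized and unbounded. `betaToM()` clips β to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before the
log-ratio so that β ∈ {0, 1} (which real array exports do produce) maps
to a large finite M rather than ±∞; `mToBeta()` inverts the transform
exactly on the open interval, and the round trip is identity to 1e-9
away from the clipped boundary.

## The three-class model and its fit

At a probe whose CpG is destroyed by one allele, the M-value
distribution over a cohort is a three-component mixture: homozygotes for
the CpG-intact allele are hypermethylated, homozygotes for the
CpG-abolishing allele hypomethylated, heterozygotes in between. We model
it as a univariate Gaussian mixture with unequal variances, fitted by
expectation-maximization in `fitMethylationMixture()`.

Numerical choices, all fixed rather than tunable-by-default:

* **Initialization** at the 10th/50th/90th data percentiles (equal
  weights, common starting sd). This is deterministic — repeated fits of
  the same data are bit-identical and permuting the input order changes
  nothing — and lands one component per mode on tripartite data.
* **Convergence** when the log-likelihood improves by less than 1e-8,
  capped at 500 iterations; hitting the cap is reported through the
  `converged` slot, not an error, because a near-converged fit is still
  usable for calling.
* **Variance floor** of 1e-4 on each component, preventing the classic
  EM degeneracy where a component collapses onto a single point with
  unbounded likelihood. Inputs with zero overall variance are rejected
  outright.
* **Model selection**: the three-class model is the default because the
  biology dictates three genotype classes; `selectK = TRUE` compares
  k ∈ {1, 2, 3} by BIC for probes where the assumption is in doubt
  (e.g. a monomorphic cohort).

Genotype calls in `callGenotypes()` are Bayes-rule posteriors under the
fitted mixture; the hard call is the argmax. The component-to-allele
orientation is an argument pair (`lowAllele`, `highAllele`) rather than
a constant because which allele abolishes the CpG is locus-specific; the
default orientation (low methylation = A/A) matches a G→A substitution
destroying the CpG. A `thresholds` override supports forced interval
calls when no three-class fit is available.

## Class-parameter presets

`methylationClassPreset()` ships three named parameter sets for the
class means and sds (M scale): `"cohort96"` (−4.21 ± 1.96, −0.51 ± 2.06,
1.41 ± 0.97), `"cohort45"` (−5.01 ± 0.67, −0.11 ± 0.49, 1.97 ± 0.36) and
`"test"` (the cohort96 means with sd 0.3 throughout). The two cohort
sets describe the same probe in two differently normalized cohorts;
`cohort96` is the default used elsewhere since it reflects the larger,
directly genotyped sample. Note the cohort96 sds overlap the classes
substantially — with those parameters no caller can be near-perfect,
which is why accuracy guarantees (and the ≥ 99% recovery check in the
tests) are stated under the `"test"` preset, where adjacent classes are
at least six generating sds apart. Passing tests under `"test"`
demonstrates the machinery is correct, not that real overlapping cohorts
are called with that accuracy.

# Frequencies and Hardy-Weinberg

For genotype counts $(n_{AA}, n_{AG}, n_{GG})$ with total $n$, the
reference-allele frequency is $p = (2n_{AA} + n_{AG})/2n$
(`alleleFrequencies()`); when only printed proportions are available,
$p = f_{AA} + f_{AG}/2$ (`alleleFreqFromGenotypeFreqs()`) and
`countsFromProportions()` reconstructs integer counts by multiplying by
n and rounding half away from zero.

`hweChisq()` is the df = 1 goodness-of-fit chi-square of the observed
counts against $(np^2, 2npq, nq^2)$, **without** Yates continuity
correction — the correction is inappropriate here because p is estimated
from the same counts, and omitting it is what reproduces the standard
textbook statistic exactly. The inbreeding estimate
$\hat F = 1 - \mathrm{het}_{obs}/\mathrm{het}_{exp}$ is returned with
the test: a positive $\hat F$ reads directly as a heterozygote deficit.
Monomorphic samples are rejected (the test is undefined); an expected
class of zero with nonzero observations yields an infinite statistic
with a warning rather than NaN arithmetic.

# Tajima's D

`tajimasD()` computes, for n haplotypes and S segregating sites,

$$D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}}$$

with the full constant chain ($a_1 = \sum_{i<n} 1/i$, $a_2 = \sum_{i<n}
1/i^2$, $b_1, b_2, c_1, c_2, e_1, e_2$) exposed in the result object so
any downstream consumer can audit the computation. π is the exact mean
pairwise difference over all $\binom{n}{2}$ haplotype pairs
(`pairwisePi()`), computed by the per-site closed form
$\sum_j 2p_j(1-p_j)\,n/(n-1)$ on complete data and by pairwise deletion
when alleles are missing.

Decisions worth knowing:

* **S = 0 gives D = NaN with a warning**, never 0: the statistic's
  denominator is zero and "no polymorphism" is not evidence of
  neutrality.
* **MAF filtering** (`filterByMaf()`) uses a *strict* inequality — a
  site at exactly the threshold is dropped — and runs before D when a
  threshold is supplied. Sites with more than 20% missing alleles are
  removed first, with a logged count.
* **Two diversity modes.** When phase is available (or the data are
  haploid), π is the exact pairwise form. When diploid genotypes are
  unphased, `genotypePi()` treats the 2N allele copies at each site as
  the sample, $\pi_{site} = 2p(1-p)\cdot 2N/(2N-1)$; on phased data
  expanded to haplotypes the two agree by construction. The pipeline
  records which mode produced a report because single-locus Sanger data
  often arrive unphased and the choice affects nothing at HWE sites but
  is not formally identical in general.
* n < 4 triggers a warning: the variance normalization is unreliable at
  such sizes.

The interpretation rule is a threshold flag: D above 1.80 (the
`balancingThreshold` default) is marked as consistent with balancing
selection — an excess of intermediate-frequency variation — while
strongly negative D indicates an excess of rare variants (sweeps,
expansion). The flag is a labeled threshold, not a p-value; users who
need calibrated significance should compare against the neutral
generator below.

# Variant extraction and VCF

`variantsFromAlignment()` scans every column of an aligned FASTA
(1-based coordinates throughout, both for alignment columns and VCF
POS). With `diploidIupac = TRUE` (default) each sequence is a diploid
consensus and two-base IUPAC codes (R, Y, S, W, K, M) expand to
heterozygous genotypes — single-locus Sanger consensus sequences
commonly encode heterozygotes this way; three/four-base codes, N and
gaps are missing data. The reference allele is the **majority** allele
with an alphabetical tie-break: unlike first-sequence conventions this
is invariant under reordering of the input, at the cost of occasionally
differing from external callers on ties (D, π and S are unaffected by
which allele is labeled reference). Columns with more than two alleles
are emitted multi-allelic with a warning and excluded from haplotype
expansion.

The VCF writer emits a deliberately minimal GT-only VCF v4.2 with a
fixed column layout so the write→read round trip is exact; the reader
accepts phased "|" separators (normalizing to "/" and recording that
phase was present) and skips non-SNP records with a count. Unphased
heterozygotes refuse haplotype expansion (`haplotypesFromVariants()`)
and route to the unphased π mode instead.

# The synthetic-data layer

`simulateMethylation()` draws M-values per genotype class from the
preset Gaussians and derives β by the inverse transform.
`simulateGenotypeCounts()` draws one multinomial from
$(p^2 + fpq,\; 2pq(1-f),\; q^2 + fpq)$, the standard
inbreeding-parameterized genotype distribution; f > 0 reproduces the
heterozygote-deficit pattern that a positive HWE test detects.

`simulateNeutralHaplotypes()` is a standard Kingman coalescent with
infinite-sites mutation: exponential coalescence times at rate
$\binom{k}{2}$ (time in units of 2N generations), mutation count Poisson
with mean $\theta/2$ × total branch length, each mutation a unique site.
θ is **per locus**, not per site. The analytic checks E[S] = θa₁,
E[TMRCA(n=2)] = 1 and the 1/i site-frequency spectrum are enforced in
the tests.

`simulateBalancedHaplotypes()` emulates balancing selection
*structurally*: two allelic classes, each an independent neutral
coalescent with within-class θ, plus `kFixed` fixed differences between
the classes. This produces exactly the signature Tajima's D detects — a
block of intermediate-frequency variants inflating π — at a fraction of
the complexity of a forward simulation with overdominance. It is a
surrogate for the detectable signature, not a population-genetic model
of the selective process: it has no selection coefficient, no
recombination, no demography, and its fixed-difference count is chosen
directly rather than arising from allelic age. Consequences for
interpretation: passing tests show the estimator chain correctly flags
a balanced polymorphism of the assumed architecture; they do not
calibrate how old or how strong selection must be for real data to
cross D = 1.80. The default acceptance-scale conditions (12 + 12
haplotypes, kFixed = 16, θ_within = 1, 200 replicates) were fixed in
advance to represent a deeply diverged balanced polymorphism in a
sample comparable to a ~100-chromosome resequencing study; at those
conditions the replicate mean D is ≈ 2.4.

All generators accept a `seed` and are bit-reproducible given one;
`seed = NULL` draws from the ambient RNG stream so a caller can seed
once and run many replicates (this is how the replicate loops in the
tests and the acceptance script are seeded).

# The pipeline

`runPopulationScan()` wires the steps together: methylation CSV →
mixture fit → genotype calls (only when no genotype CSV is supplied) →
per-population frequencies, HWE (skipped with a warning below n = 5,
and for monomorphic populations) → FASTA → variants → MAF filter →
Tajima's D → report. Every number in the report equals the
corresponding module-level call on the same inputs — the pipeline adds
orchestration, logging and serialization, no arithmetic. Reports carry
`schema_version`, the seed and the package version; p-values are
rounded to 3 decimals in the CSV but kept at full precision in the
JSON; no timestamps are written, so reruns under the same seed are
byte-identical. `compareToReference()` places user-supplied reference
population frequencies beside the sample populations, sorted by
ascending reference-allele frequency, with a `flip` flag for tables
oriented to the other allele; deliberately, no test statistic is
attached to that comparison.

Grouping for Tajima's D is currently the whole alignment (`grouping =
"all"`); stratified D by population map is a known limitation, as are:
no recombination or demography in the generators, no exact
(Wigginton-style) HWE test, no multi-allelic handling beyond flag-and-
skip, and no phasing — unphased heterozygous data cap out at the
unphased π mode.

# Problem sizes

The test suite runs the estimator-oracle comparisons on random matrices
up to n = 30, S = 50; the neutral-coalescent calibration at n = 20,
θ = 5 with 1,000 replicates; the site-frequency-spectrum test at n = 8
with 2,000 replicates; and the balanced-model acceptance at 12 + 12
haplotypes with 200 replicates — sizes chosen so each check has clear
statistical power while the whole suite stays interactive.

# Session info

```{r}
sessionInfo()
```
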