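---
title: "Methods: likelihood-based population genomics at ~1x coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-based population genomics at ~1x coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glscan)
```

## The problem

At a mean sequencing depth near 1x per individual, most sites see zero or one
read per diploid, so genotypes cannot be called. All inference in `glscan`
therefore stays on genotype *likelihoods*: for each site and individual, the
relative probability of the read data under 0, 1 or 2 copies of the minor
allele. Population quantities — allele frequencies, site-frequency spectra,
diversity, divergence, differentiation tests — are computed by integrating
over that genotype uncertainty rather than by plugging in hard calls.

## The likelihood model

A read from an individual carrying `g` minor-allele copies supports the minor
allele with probability

\[ P(\text{minor} \mid g) = \frac{g}{2}(1-\varepsilon) +
   \left(1-\frac{g}{2}\right)\frac{\varepsilon}{3}, \]

and the major allele with the mirrored expression. Misreads are split three
ways across the other bases, so \(P(\text{major}\mid g{=}2) = \varepsilon/3\),
not \(\varepsilon\). With `n_minor` and `n_major` reads the genotype
likelihood is the product of per-read emission probabilities, computed in log
space and rescaled so the largest of the triple is exactly 1; an individual
with no reads carries the non-informative triple (1, 1, 1). The synthetic
generator uses exactly this error model, so calibration experiments isolate
estimator error from model mismatch.

**Error rate** \(\varepsilon\): default 0.005 in the generator (post-filter
short-read error rates typically fall between 0.2% and 1%); the genotype
likelihood stage takes \(\varepsilon\) as an argument and must be told the
value the data were generated or filtered at.

## Allele frequencies, SNP calling, site filters

Per-site minor-allele frequencies maximise the marginal likelihood
\(\ell(f) = \sum_i \log \sum_g L_i(g) P(g\mid f)\) under the Hardy–Weinberg
prior by EM (start 0.1, tolerance 1e-8 on the frequency, 200 iterations;
the marginal log-likelihood is non-decreasing and the estimate matches a
1e-5-step grid search to 1e-4 in the test suite). Individuals without reads
sit at the prior mean and do not move the fixed point.

SNP calling is the likelihood-ratio test of \(f = \hat f\) against \(f = 0\)
referred to \(\chi^2_1\). The boundary null makes this conservative; no
half-point-mass correction is applied, matching common practice in
genotype-likelihood pipelines.

Site filters follow the standard low-coverage recipe: total site depth within
0.5–1.5x the mean total depth, `MAF > 0.05` (strict, so a site at exactly
0.05 is excluded), SNP p-value below 1e-6, and at least 10 individuals with
data. Diversity statistics are computed from call sets *without* the MAF
filter, which would otherwise bias the frequency spectrum.

## SAF, SFS, diversity

Per-site sample-allele-frequency (SAF) likelihoods \(P(\text{data} \mid j)\)
for \(j = 0..2N\) come from the standard dynamic program convolving
per-individual genotype likelihoods weighted by \(\binom{2}{g}\), normalised
by \(\binom{2N}{j}\). Folding merges classes \(j\) and \(2N-j\), using the
major allele as the ancestral proxy. The DP equals exhaustive enumeration
over genotype vectors for \(N \le 4\) (property-tested).

The SFS is the maximum-likelihood mixture over allele-count classes, fitted
by EM from a uniform start (tolerance 1e-8 on the class probabilities, cap
500 iterations by default; calibration calls raise the cap to 2000 because
near-boundary spectra converge slowly). Diversity statistics are posterior
expectations under the estimated spectrum (empirical Bayes): per-site
\(\pi_s = \sum_j q_s(j)\, 2j(2N-j)/(2N(2N-1))\), windowed as the sum over
covered sites divided by the number of covered sites (10-kb non-overlapping
windows tiled from position 1). Watterson's \(\theta\) uses the expected
segregating-site count divided by \(a_{2N-1}\) (reported per covered site for
comparability), and Tajima's D plugs expected counts into the classical
constants — it is approximate by construction and flagged `NA` when the
expected segregating count is below 3.

Two numerical notes. First, \(\pi\) is exactly fold-invariant when the
unfolded prior is symmetric and its minor-allele restriction is used as the
folded prior (the weight \(j(2N-j)\) is symmetric); EM-estimated folded
priors differ from folded EM-estimated priors by small amounts, so the two
pipelines agree closely but not bitwise. Second, empirical-Bayes \(\pi\) has
a positive bias at low coverage concentrated in the rare allele-count
classes; the recovery test runs at 8 reads/individual (120 pooled reads per
site), where the estimate lands within 10% of the realized sample
heterozygosity. At lower pooled depth the bias grows, which is worth
remembering when comparing absolute diversity levels between cohorts of
different depth.

## FST and dxy from the 2D SFS

The joint spectrum of two populations is fitted by EM on the outer-product
likelihood \(SAF_1(j)\,SAF_2(k)\), fully vectorised as two matrix products
per iteration. Per-site FST components are posterior expectations of the
Hudson/Bhatia estimator,

\[ \alpha = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{2N_1-1} - \frac{p_2(1-p_2)}{2N_2-1},
   \qquad \beta = p_1(1-p_2) + p_2(1-p_1), \]

aggregated as a ratio of sums per window and genome-wide. Hudson is the
default because it behaves well under unequal sample sizes and recovers the
Balding–Nichols drift parameter without bias (the acceptance suite recovers
c = 0.1 within ±0.02 from 50,000 sites at 4x and 25 individuals per
population). Negative per-site numerators are kept — truncating them would
bias window sums. Reynolds (1983) components are available as an alternative
(`estimator = "reynolds"`), as some established pipelines default to them;
outputs are labelled with the estimator used. "10-kb moving windows" are
non-overlapping (step = length): nothing in the downstream analysis needs
overlapping steps, and non-overlapping windows keep ratio-of-sums additivity
exact. \(d_{xy}\) is the posterior expectation of
\(p_1(1-p_2) + (1-p_1)p_2\), averaged per covered site; it tends to the
within-population heterozygosity as divergence goes to zero (tested).

## The differentiation screen

Super-pools are compared per SNP with the two-group frequency LRT:
\(\Lambda = 2[\ell_A(\hat f_A) + \ell_B(\hat f_B) - \ell_{A\cup B}(\hat
f_{pool})]\) on \(\chi^2_1\). This statistic is fully determined by machinery
the pipeline already has (genotype likelihoods + EM), which is why it is the
primary screen; a dosage score test (`score_test()`) is provided as a
cross-validating variant and agrees with the LRT within a factor of two on
95% of sites at high depth. p-values are floored at 1e-320 so
\(-\log_{10}p\) stays finite.

Calibration caveat, measured by the acceptance suite: the frequency LRT is
*anticonservative* at small sample sizes. With 15+15 diploids the empirical
type-I error at \(\alpha = 0.05\) is around 0.06 even when genotypes are
known with certainty, and rises toward 0.08 at 1x coverage; the null p-value
distribution is correspondingly non-uniform. Genome-wide screens that rank
SNPs by empirical quantile (as here) are unaffected by a monotone
miscalibration, but nominal per-SNP error rates should not be taken at face
value at these sample sizes.

Outlier thresholds: Bonferroni at \(\alpha/m\), and the empirical
top-quantile cutoff at the \(-\log_{10}p\) of ascending rank
\(K = \max(1, \lfloor qm \rfloor)\) with \(q = 10^{-4}\) (top 0.01%) by
default and \(10^{-5}\) as the stricter variant. For *power* evaluation
against planted outliers the quantile cutoff is computed from the background
(null) sites: in a real genome-wide screen true signals are a vanishing
fraction of tested SNPs, so the genome-wide quantile is effectively a null
quantile; computing it on a test set where planted outliers are 0.2% of
sites would cap measurable power at \(K/200\) by construction. Planted
outliers use near-fixation in one super-pool (\(f_A = 0\), \(f_B = 0.5\)),
the pattern of the strongest empirical outliers. Even so, at 1x coverage
with 30+30 individuals the LRT noncentrality is about 26, which bounds power
at the \(10^{-4}\) tail near 0.75–0.80; the acceptance suite reports the
measured value rather than forcing it.

## Signal compilation and gene assignment

Outlier SNPs are merged along each chromosome by single linkage: a gap of
*at least* 500 kb starts a new independent signal (a distance of exactly
500,000 bp splits). Clusters never span sequences; unplaced scaffolds are
ordinary sequences. Merging is order-invariant, idempotent on cluster peaks,
and equals a brute-force gap scan in tests.

Gene assignment extends each gene 5 kb on its 5' side and 3 kb on its 3'
side in *biological* orientation: on the minus strand the 5-kb window sits at
the higher-coordinate end. This choice changes gene counts relative to a
strand-blind rule and is therefore stated prominently. A SNP may hit several
genes; SNPs hitting none are "intergenic"; a gene hit by SNPs of several
clusters counts once in genome-wide totals.

Cross-contrast overlaps are tested one-sided against
\(X \sim \text{Binomial}(n_C, n_D/M)\) in log space; p-values below double
precision are reported as 0 with an underflow flag and a finite
\(\log_{10}p\). At screen-scale counts (1199 and 1237 outliers, 288
shared, 20 million SNPs) the p-value underflows to exactly 0, with
\(\log_{10}p\) near -927.

## LD pruning and PCA

Pruning removes SNPs with variance-inflation factor above 2 within 100-SNP
windows stepped by 5, computed from the window correlation matrix of
posterior expected dosages with a 1e-8 ridge; monomorphic SNPs are dropped
first and VIF ties remove the lower-MAF SNP (preserving informative sites;
established tools' tie rules are version-dependent). A SNP removed in any
window stays removed, and a post-hoc audit over all windows of the kept set
never exceeds the threshold. Note that sample correlation matrices are
singular whenever a window holds more SNPs than there are individuals;
pruning is then more aggressive, which is the conservative direction.

PCA standardises expected dosages by \(\sqrt{2f(1-f)}\) and eigendecomposes
the individual covariance averaged over SNPs. This is a plain dosage PCA:
the iterative individual-allele-frequency refinement used by specialised
low-coverage PCA tools is out of scope, and the plain version is adequate
for the package's validation scope (populations at drift 0.3 separate
perfectly on PC1; a panmictic cohort's leading eigenvalue stays within a
documented 30% band of the Marchenko–Pastur bulk edge).

## Depth QC for collapsed duplications

Mean depth in 50-kb non-overlapping windows, normalised by the genome-wide
*median* of window means (robust to the very regions being flagged); a
sequence whose median normalised depth reaches 1.6 is flagged as a candidate
collapsed tetrasomic region. The 1.6 default sits between the disomic (1x)
and collapsed (2x) expectations and is configurable; the underlying
observation it emulates is a two-fold depth elevation on a few chromosomes.

## The synthetic generator: what it emulates, what it does not

`population_model()` + `draw_population_frequencies()` implement the
Balding–Nichols model: ancestral frequencies from a symmetric Beta (shape
0.8 by default; 0.004 effective-theta shapes are used where realistic
~0.4% diversity is needed), population frequencies from
\(\text{Beta}(p\frac{1-c}{c}, (1-p)\frac{1-c}{c})\). Its virtue is that `c`
*is* the per-population FST, giving closed-form recovery targets.
`simulate_read_counts()` adds Hardy–Weinberg genotypes, Poisson depth
(default 1.08 reads/site/individual, the coverage regime the package
targets) and the three-way error model. Positions sit on at most five named
chromosomes so windowing and merging code paths are exercised.

Deliberately absent: linkage and recombination (sites are independent, so
LD-pruning tests use explicitly constructed correlated dosages), coalescent
genealogies, mapping error, indels, multi-allelic sites, and depth variation
beyond Poisson. Passing calibration therefore demonstrates estimator
correctness under the stated generative model, not robustness to alignment
artefacts or cryptic relatedness in real data.

## Problem sizes and reproducibility

Calibration runs use 50,000 sites (FST recovery), 20,000 sites (SFS, null
calibration, diversity), 100,200 sites (power) and 8,000 sites (end-to-end
scan) — sizes at which every experiment completes in minutes on one CPU
while keeping Monte-Carlo error well below the tolerances tested. One master
seed drives every stage through `derive_seed(seed, stage)`, so reruns are
byte-identical and stages can be re-run independently; all seeds stay within
32-bit integer range.
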