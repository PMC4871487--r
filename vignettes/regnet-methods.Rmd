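---
title: "Methods: per-sample lasso inference of regulator networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-sample lasso inference of regulator networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(regnet)
```

This vignette documents the statistical model behind `regnet`, the choices
made where the design was genuinely open, and what the synthetic validation
does and does not demonstrate about real tumor data.

## The model and its assumptions

For one tumor sample, expression of gene $g$ is modelled linearly in the
gene's regulatory features:

$$y_g = w_0 + w_C C_g + w_M M_g + \sum_{TF} w_{TF} N_g^{TF}
      + \sum_{miR} w_{miR} N_g^{miR} + \sum_{RBP} w_{RBP} N_g^{RBP} + \varepsilon_g$$

with $C_g$ the (GISTIC-style) copy-number level, $M_g$ the methylation
beta-value of the probe most negatively correlated with the gene's
expression, and $N_g$ non-negative binding-site counts per regulator. The
coefficients are shared across genes within a sample — the model explains
*between-gene* expression variation from *cis* features — and a separate
model is fit per sample, so regulator activity may vary across tumors.
Implicit assumptions: effects are additive (no competitive or cooperative
binding terms), counts are a proxy for regulatory input irrespective of
position or affinity, and the error is homoscedastic Gaussian on the log2
expression scale.

Because there are hundreds of features and effects are expected to be
sparse, the fit minimizes the 1/2n-scaled squared error with an L1 penalty,

$$\tfrac{1}{2n}\lVert y - w_0 - Xw\rVert_2^2 + \lambda \lVert w\rVert_1 .$$

Features are standardized to unit variance before penalization (counts,
copy-number levels and beta-values live on incomparable scales; an equal
penalty is only meaningful on a common scale); the intercept is unpenalized,
and coefficients are reported back on the original scale.

## The solver

`fit_lasso()` is cyclic coordinate descent with soft-thresholding on
precomputed covariance moments ($X^\top X/n$, $X^\top y/n$), implemented in
C++ with warm starts along a 100-point log-spaced $\lambda$ path from
$\lambda_{max}$ (the smallest penalty with an all-zero solution) down to
$10^{-3}\lambda_{max}$. Convergence is declared when the largest coefficient
change in a sweep falls below $10^{-8}$ (cap $10^5$ sweeps); KKT residuals
of returned solutions are checked in the tests against $10^{-6}$ and the
objective against an exhaustive sign-pattern quadratic-programming oracle.
Coordinates are visited in the fixed column order of the matrix, making
solutions deterministic. Zero-variance columns are never brought into the
model. The test suite also cross-checks coefficients against an independent
lasso implementation at machine precision.

## Penalty selection and evaluation

$\lambda$ is chosen at the cross-validation *minimum* of the mean K-fold
squared prediction error (K = 10 over genes; ties go to the stronger
penalty). The 1-SE rule is not used, but the full CV path is returned for
callers who want it. `evaluate_cv()` nests the selection: each outer fold
chooses its penalty by an inner CV on the training genes only, so the
held-out Spearman correlation is free of selection leakage;
`nested = FALSE` reproduces the simpler (leaky) variant in which one penalty
is chosen on all genes. Held-out skill is summarized by the Spearman rank
correlation (average ranks for ties); a constant prediction — e.g. an
intercept-only model after ablating every feature — contributes rho = 0 by
convention, with a warning. Fold assignments are seeded and recorded.

## Selective inference

Classical tests are invalid for features chosen adaptively by the lasso.
`selective_pvalues()` implements fixed-$\lambda$ polyhedral post-selection
inference: conditioning on the active set and signs — a polyhedron
$\{y : Ay \le b\}$ assembled from the KKT conditions (sign constraints on
active coefficients, subgradient bounds on inactive ones) — the relaxed
least-squares coefficient of each active feature is a Gaussian truncated to
an interval $[V^-, V^+]$ computable from the polyhedron. Two-sided p-values
come from the truncated-Gaussian distribution function; one-sided tests are
available by flag.

Numerical details that matter: the truncated CDF is evaluated through
log-space survival functions with log-difference arithmetic, so far-tail
statistics do not underflow to 0/0; a degenerate truncation interval returns
p = 1. Because all feature columns are centred, the statistic and every
polyhedron row are orthogonal to the intercept direction, so inference with
an unpenalized intercept is exact. The noise scale is estimated by
df-corrected OLS residuals on the full feature set when $n > p + 1$
(`estimate_sigma()`), else on the active set. Calibration is verified in the
acceptance suite: pooled selective p-values over 500 global-null replicates
pass a KS uniformity check at distance < 0.06.

The per-sample $\lambda$ handed to inference is the CV-selected one. Strictly,
conditioning at a data-dependent $\lambda$ is an approximation (the
theory fixes $\lambda$); the calibration check therefore uses a fixed
penalty, and the cross-sample selection counts should be read as a ranking
statistic rather than a family of exact tests. Regulators are ranked by the
number of samples in which they are active with p < 0.05
(`count_selections()`), with a strict `n_selected > min_samples` cutoff
(`rank_regulators()`).

## Target discovery

For a candidate regulator $r$, removal is defined as zeroing its fitted
contribution: $\hat y^{(-r)} = \hat y - w_r x_r$, so the per-gene error
change is $(y - \hat y + w_r x_r)^2 - (y - \hat y)^2$, exactly zero wherever
the regulator has no site or no coefficient. Changes are summed across
samples and compared against a permutation null in which every feature
column is shuffled independently (a fresh permutation per column per
replicate; one shuffled matrix serves all samples and regulators, which is
also what makes B = 5000 replicates affordable).

Two null schemes are provided, and the choice is consequential:

* **refit** (default): the per-sample lasso is refit on the shuffled matrix
  at the sample's original penalty. Shuffling destroys the feature–response
  association, so refit coefficients — and hence null error changes —
  concentrate near zero, and a genuine target (nonzero count, nonzero
  coefficient, error increase on removal) beats essentially every
  replicate.
* **reuse**: the original coefficients are kept and only the design is
  permuted. This is cheaper, but whenever the permuted regulator column
  lands a nonzero count on a gene (probability equal to the column's
  nonzero rate, per replicate) the null error change reproduces the
  observed one in distribution. Empirical p-values are therefore floored
  near (nonzero rate)/2 — far above any stringent FDR threshold — and the
  scheme cannot separate true targets from the null at realistic
  binding-site sparsity. It is retained for sensitivity analysis, and the
  permutation-oracle checks use it because its arithmetic can be reproduced
  exactly by an independent brute-force loop.

Empirical p-values use the add-one estimator $p = (1 + \#\{null \ge
obs\})/(B+1)$: strictly positive, minimum $1/(B+1)$ — at the production
scale B = 5000 this floor ($\approx 2\times 10^{-4}$) matches the callable
FDR threshold. Benjamini–Hochberg adjustment is applied per regulator
across genes, since the hypotheses of interest form one family per
regulator's target set. Note the interaction between the floor and BH: with
m genes and threshold q, at least $m/(q(B+1))$ genes must reach the floor
before anything is callable; at desk scale (B = 500, q = 0.05, m = 2000)
that is 80 genes, so regulators with fewer true targets than that cannot
have their set called at all. Validation utilities report predicted/reference
set overlaps (`overlap_report()`) and compare log-fold-change distributions
across disjoint gene groups — reference targets, predicted-only targets,
motif-only genes, no-site genes — by ECDFs and pairwise KS statistics
(`ecdf_groups()`).

The permutation engine deliberately mirrors the scalar removal identity
term by term (long-double accumulation in a fixed order), so mathematically
tied observed and null statistics also tie numerically and p-values are
bit-reproducible against an independent loop implementation.

## Feature construction

* Promoters are the strand-independent ±2000 bp window around the TSS,
  clipped at the chromosome start; all coordinates are 0-based half-open
  (BED convention) and interval overlap means ≥ 1 shared base.
* TF sites are motif-scan hits on both strands with exact score p-value
  below $10^{-4}$. The scan scores windows by log2 odds against a 0-order
  background (uniform by default, configurable); p-values are exact tail
  probabilities of the discretized score distribution, computed by dynamic
  programming. Bins are allocated per motif position (bin width = score
  range / (1000 · width)) so the aggregate quantization error stays below
  0.05% of the score range; enumeration checks in the tests bound the
  p-value error under 1%. A pseudocount of $10^{-4}$ on PFM probabilities
  avoids $-\infty$ scores. TF hits are counted only where they intersect
  open-chromatin (DNase) peaks — peak-required mode — because a motif match
  in closed chromatin is unlikely to be bound.
* miRNA sites are exact seed matches in the 3'UTR; RBP sites are exact
  matches of the motif's 10 highest-probability k-mers (product of
  per-position probabilities, ties broken lexicographically so the set is
  deterministic), optionally restricted to CLIP peaks with background-binding
  regions subtracted. 3'UTR scanning is single-stranded: these sites exist
  on the mature transcript only. Overlapping occurrences are all counted; a
  position matching several listed k-mers counts once.
* Feature assembly intersects the gene universes of all sources, drops
  regulator columns with no site in any retained gene, and merges exact
  duplicate columns within a class into a single feature with recorded
  members (duplicates are indistinguishable to the regression and would
  make selection arbitrary).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, with
defaults chosen once to embody the validation study: 2000 genes, 40
samples, 52 features (CNV, METH, 20 TFs, 15 miRNAs, 15 RBPs), 10 planted
regulators all in the RBP class — mirroring a study design in which RBP
features carry the dominant signal — with absolute base weights uniform on
[0.5, 1.5], random signs, expression noise SD 1, and binding-site counts
i.i.d. Poisson with mean 0.05 (≈ 4.9% of genes carry a site, ≈ 100 targets
per regulator). True weights are drawn once per regulator and multiplied per
sample by U(0.8, 1.2): the per-sample models are coherent but not
identical, as the per-sample fitting strategy presumes. The CNV covariate is
a discrete level in $\{-2..2\}$ (centre-heavy) plus N(0, 0.1) jitter; the
methylation covariate is Beta(2, 2) and enters with negative weight by
default, methylation being canonically repressive. A regulator's true
target set is the set of genes where it has at least one site. Matched
tumor/normal log fold changes shift the targets of a chosen regulator by
±`shift` (following the regulator's effect sign) over N(0, `lfc_sd`) noise.

Sequence-level fixtures (`simulate_sequences()`) realize a count matrix in
actual sequence: per gene, a synthetic chromosome carries the promoter and a
3'UTR; motif occurrences are planted at non-overlapping random positions
and the background is rejection-sampled — each gene's region is redrawn
until rebuilding the counts through the scanning/counting code reproduces
the planted values exactly, which removes spurious matches (including
reverse-complement and junction-spanning ones). Motif consensi are drawn
with pairwise Hamming separation (and no reverse-complement collisions for
the double-stranded promoter scan) so that one regulator's occurrences
cannot satisfy another's matcher. TF motifs are 8-mers: under a uniform
background an exact consensus match has p $\approx 1.5\times10^{-5} <
10^{-4}$ while a single mismatch already fails the threshold, so scan hits
and planted occurrences coincide.

What passing these tests shows — and does not. The generator matches the
model's assumptions by construction: linearity, feature-independent noise,
counts that are exactly the planted regulatory input. Recovery results
therefore validate the *inference machinery* (solver, selective p-values,
permutation null, FDR), not the biological adequacy of the linear
binding-site model; on real tumors, held-out correlations are far from 1,
effects are partly non-additive, and binding sites are noisy proxies.
Realistic read-level RNA-seq, copy-number segmentation and array probe
structure are out of scope.

## Problem sizes and numerical conventions

The validation studies run at 2000 genes × 40 samples × 52 features with
B = 500 permutation replicates and 500 calibration replicates — sizes at
which the full acceptance computation completes in a few minutes on one
core while leaving the detection margins wide. Determinism throughout comes
from a single master seed expanded into per-stage/per-sample child seeds by
an integer hash with avalanche mixing (`child_seed()`); nearby labels yield
unrelated streams, which matters because Mersenne-Twister streams from
adjacent seeds are correlated. Other conventions: empirical p-values are
never zero; Spearman of a constant vector is 0 with a warning; filters are
idempotent; `log2(x + 1)` maps zero expression to zero and leaves rank
statistics invariant to the pseudocount on positive data; methylation probe
selection treats zero-variance probes as r = 0 and warns when no probe is
negatively correlated; expression matrices carry an explicit scale tag so a
transform cannot be applied twice.

## Known limitations

* Selective p-values are computed at the CV-chosen penalty, an
  approximation discussed above.
* The refit permutation null concentrates so sharply near zero that the
  empirical p-value becomes nearly binary (floor vs 1) for well-fit
  regulators; the add-one estimator and the BH floor interaction bound what
  is callable at small B.
* Duplicate-feature merging is within-class only; cross-class duplicates
  (which cannot be told apart by the regression either) keep their separate
  labels.
* The promoter window is strand-independent and fixed-width; no
  conservation filtering, RNA secondary structure, or gapped/structured
  motifs.
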