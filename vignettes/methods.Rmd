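---
title: "Methods: joint RNA/RPF analysis of transcription-translation decoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint RNA/RPF analysis of transcription-translation decoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodecouple)
```

# The measurement model

Ribosome profiling yields counts of ribosome-protected fragments (RPFs) per
gene; RNA-seq yields total mRNA counts. We model both as negative-binomial,
`Var(Y) = mu + phi * mu^2`, with a dispersion `phi` shared across genes
within an assay (`phi = 0` is the Poisson limit). A gene's translation
efficiency (TE) is the RPF/mRNA abundance ratio; the quantity of interest
for a two-condition contrast is

```
delta_TE = log2FC(RPF) - log2FC(RNA)
```

which is zero when transcription alone drives the change and non-zero when
translation is independently regulated ("decoupled").

The pipeline assumes: (i) counts are gene-level integers from a fixed
annotation, with no within-gene positional information; (ii) most genes are
not differentially expressed, and up- and down-regulation are roughly
balanced — the assumption TMM normalization needs (see *Known limitations*);
(iii) biological replicates within a condition are exchangeable.

# Stages and their parameters

## Normalization (TMM)

Each sample is compared to a reference sample (the one whose
75th-percentile count rate is closest to the mean such rate) on the M/A
scale; genes zero in either member of a pair are excluded, no pseudocount is
introduced. The most extreme 30% of M values and 5% of A values are trimmed
from each tail (`trim_M = 0.30`, `trim_A = 0.05`, the method's canonical
defaults), and the surviving M values are averaged with inverse
delta-method-variance weights. Factors are rescaled to geometric mean 1
(asserted to 1e-9 in tests). Degenerate case: a pair whose M values are all
below 1e-6 in magnitude (identical composition) returns factor 1 exactly,
so identical or uniformly scaled samples are never perturbed by trimming
noise.

## Expression filters

* `filter_expressed()`: a gene is kept when its CPM is at least
  `threshold_cpm` (default 1) in *all* replicates of *at least one*
  condition (`scope = "any"`). The alternative reading — all replicates of
  *every* condition — is available as `scope = "all"`. We default to "any"
  because a design in which one condition expresses a substantially smaller
  gene set would otherwise discard genes genuinely expressed only there.
* `presence_flags()`: RPKM strictly greater than 1 in all replicates of a
  condition, reported per gene x condition.

## Differential expression (exact conditional NB test)

Counts are first scaled to a common effective library size (geometric mean
of TMM effective sizes) and rounded half-to-even back to integers; this
deterministic equalization replaces quantile-based pseudo-count adjustment
and its adequacy is checked by type-I calibration tests (fraction of
p < 0.05 on null simulations within 0.05 +/- 0.01).

The common dispersion maximizes the per-gene NB log-likelihood conditional
on each gene's within-condition total, summed over genes and over conditions
with at least two replicates, over `phi` in [1e-6, 10] (log-spaced grid
bracketing followed by Brent optimization, tolerance 1e-8). With a single
replicate everywhere the dispersion is declared not estimable.

The test conditions on the total `t` of both groups: a group of `n`
replicates with mean `mu` has sum `NB(n*mu, phi/n)`, `mu` is estimated as
`t / (n_A + n_B)`, and the two-sided p-value sums the probabilities of all
splits `(a, t-a)` whose point probability does not exceed the observed one.
Ties in point probability are compared with a relative tolerance of 1e-8 so
that floating-point noise cannot drop the symmetric twin of the observed
split. `t = 0` returns p = 1 by convention. This "sum of less-probable
outcomes" two-sidedness is well defined for the asymmetric NB-sum
distributions and is what the enumeration oracle in the tests implements
independently.

Fold changes are `log2((mean_B + 0.5) / (mean_A + 0.5))`; the 0.5 prior
keeps all-zero genes at logFC 0 rather than +/-Inf. Significance combines
BH-adjusted p < `fdr_cut` (default 0.01) with |log2FC| > `lfc_cut` (default
1, i.e. fold change beyond 2x); both cutoffs are plain arguments, nothing is
hard-coded.

## Translation efficiency

* **Global slope**: ordinary least squares of log2(RPF RPKM + 0.01) on
  log2(RNA RPKM + 0.01), per condition, on replicate-averaged RPKM of the
  genes detected in that condition (the filtered set; which genes enter the
  fit is configurable via `genes`). The 95% CI is `slope +/- t(0.975, n-2) *
  SE`. The 0.01 pseudocount only protects the log at RPKM = 0 and is an
  order of magnitude below the presence threshold.
* **Per-gene test**: `delta_TE` with a Wald z statistic. The variance of
  each assay's log2 fold change uses the delta method,
  `Var = (1/ln(2)^2) * sum_groups (1/n) * (1/mu + phi)`, group means floored
  at 0.5 (the fold-change prior) so all-zero genes stay finite; the two
  assays are independent experiments, so the variances add. This Wald
  construction was chosen over an interaction GLM because it needs only
  quantities the DE stage already produces, is antisymmetric under swapping
  the assays by construction, and its null calibration and recovery are
  directly testable (KS distance to uniform < 0.05 on coupled simulations;
  planted-effect bias < 0.1 log2 units).

## Decoupling classification

With band `b` (default 1 log2 unit, mirroring the +/-2-fold DE cutoff),
rules apply in order: genes significant in neither assay are UNCHANGED;
`delta > b` with a significant RPF change is TE_UP; `delta < -b` with a
significant change in either assay is TE_DOWN; significant in both assays
with `|delta| <= b` is TRANSCRIPTIONAL; everything else is UNCHANGED. This
is the default `"guarded"` mode: requiring significance in the relevant
assay suppresses band crossings produced by pure counting noise in
low-abundance genes. `"literal"` mode classifies by the band alone, which
matches the purely fold-change-based group definition; the two modes differ
exactly on non-significant band crossings. The decoupled fraction is
computed over classified (regulated) genes only; with no regulated genes it
is reported as undefined (NA) rather than 0.

The high-transcription scatter groups take genes above the 0.90 RNA-RPKM
quantile and split them by their residual from the global regression line at
the 0.05/0.95 residual quantiles (RED = low translation, BLUE = very high,
GREEN = the rest). The quantile defaults are exposed because no principled
values exist; they are display thresholds, not inference.

## Gene-set enrichment

Preranked GSEA uses the weighted running sum (increments `|metric|^p`
normalized over the set, `p = 1`; decrements `1/(N-k)`), ES = signed maximum
deviation. The null permutes *gene-set membership* (random same-size sets),
not phenotypes, because the input is a preranked statistic with no
per-sample structure to permute. `p = (1 + #{|ES_perm| >= |ES|}) /
(n_perm + 1)` (add-one smoothing, so p is never 0), NES divides by the mean
|ES| of same-signed permutations, and the reported direction is the rank
position of the extremum relative to the middle of the list (the
barcode-plot "skew"). A set covering the whole ranking is an error (the
decrement is undefined), as is an empty overlap. Over-representation uses
the upper-tail hypergeometric distribution with BH adjustment across sets.

## Polysome qPCR

Every gradient fraction receives the same exogenous RNA spike before
extraction, so fraction-specific recovery/efficiency offsets appear
identically in gene and spike Cq. Correction subtracts
`spike_Cq - mean(spike_Cq)` within a run; the choice of the *mean* spike Cq
as reference only shifts all corrected Cq of a run by a constant, which the
relative quantity `q = 2^(Cq_min - Cq)` cancels exactly — the tests assert
this invariance directly. TE ratios divide the summed `q` over polysome
fractions by the summed `q` over monosome fractions; the monosome/polysome
boundary within fractions 7-14 is a required parameter (default mono =
{7, 8}, poly = {9,...,14}) because no single split is canonical. Zero
monosome signal yields an undefined (NA) ratio, not an error. The reciprocal
1/Cq sometimes used for display is not proportional to abundance and is
deliberately not used for quantification. Profile shifts are the difference
in profile-weighted mean fraction index, with a replicate-resampling
bootstrap p-value for a right shift (single-replicate groups return the
statistic with p = NA).

# What the simulator emulates — and what it does not

`generate_joint_counts()` reproduces the target study design: 3 conditions x
3 biological replicates x 2 assays, NB counts, log-normal baseline
abundances (meanlog `log(400)`, sdlog 0.5 — so virtually all genes sit above
100 expected counts, the regime in which the planted effects are
recoverable), per-gene baseline TE (log2 SD 0.5), library sizes uniform in
2-4 million, and planted classes in proportions 60% null / 20%
transcriptional (|log2FC| = 2, random sign) / 10% TE-up / 10% TE-down
(delta_TE = +/-2). Effects are applied as -lfc/2 and +lfc/2 around baseline,
so the planted contrast is exact in the expected counts, and expected counts
are *not* renormalized after effects are applied — planted fold changes
remain visible and the symmetric class mix keeps total library drift within
about 10%.

The simulator does **not** emulate: positional read structure (UTR vs CDS),
gene-length-dependent counting biases beyond the uniform 300-5000 nt lengths
used for RPKM arithmetic, gene-gene correlation, outlier samples or batch
effects, tagwise dispersion heterogeneity, or GC/mappability artifacts.
Passing recovery tests therefore demonstrates correctness of the statistics
under the stated model, not robustness to every artifact of real libraries.

# Numerical and reproducibility choices

* All stochastic stages take an explicit integer seed (`set.seed` at entry);
  the pipeline derives stage seeds deterministically from the master seed,
  and rerunning a config yields byte-identical output files (no timestamps
  in the manifest).
* Library equalization rounds half-to-even (R's `round`), making the
  adjusted counts integer and deterministic.
* BH adjustment is the standard step-up with enforced monotonicity, capped
  at 1; NaN p-values are rejected rather than silently dropped.
* Exact-test probabilities are computed in log space and normalized before
  summation to avoid underflow at large totals.
* Problem sizes used by the validation suite (2000-5000 genes, 200-1000
  Monte-Carlo replicates) were chosen so that each Monte-Carlo check's own
  sampling error is several times smaller than the tolerance it asserts —
  e.g. the planted delta-TE bias bound of 0.1 is checked with 500 planted
  genes (standard error about 0.016).

# Known limitations

* TMM assumes roughly balanced up/down regulation. Under strongly one-sided
  composition change (e.g. 20% of genes all shifted upward in one assay) the
  trimmed mean is pulled toward the contaminated side and fold changes
  shrink accordingly. This is a property of the normalization itself; the
  package exposes it rather than hiding it, and the validation suite plants
  symmetric classes, as the method assumes.
* The common-dispersion NB model has no tagwise shrinkage; genes with
  atypical dispersion will be mis-calibrated in proportion.
* The Wald delta-TE test relies on the delta-method normal approximation,
  which degrades for group means below ~10 counts; the expression filter is
  the intended guard.
* The bootstrap profile-shift p-value is granular with 3 replicates per
  group (10 distinct multisets per group) and should be read as evidence of
  consistency across replicates, not as a finely resolved significance
  level.
* GSEA p-values are permutation-based with add-one smoothing; resolution is
  bounded by `1/(n_perm + 1)`.
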