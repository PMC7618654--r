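---
title: "Discriminating failure modes of piRNA-directed LINE1 methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating failure modes of piRNA-directed LINE1 methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methfid)
```

## The scientific question

In the foetal male mouse germline, the piRNA pathway directs de novo DNA
methylation of young LINE1 retrotransposon copies. When a component of this
machinery is partially disabled, family-average methylation drops — but an
average hides *how* the system fails. Three qualitatively different defects
produce the same mean loss:

1. **Uniform inefficiency** — every young LINE1 copy is methylated, but to a
   lower level (`m = f * mu_hi` for all eligible loci).
2. **Deterministic subset failure** — a *fixed* subset of copies absolutely
   requires the disabled function and is unmethylated in every animal; the
   rest are normal.
3. **Stochastic misfunction** — in each animal, a random, different subset of
   copies escapes methylation.

`methfid` implements the quantitative machinery that separates these three
hypotheses from whole-genome methylation data (per-cytosine CpG reports,
Bismark layout), together with the image-analysis statistics (masked Pearson
colocalisation with Costes auto-thresholding and block-shuffle
randomisation, DAPI-dense heterochromatin overlap of FISH spots) used to
localise the failing copies in the nucleus, and an IP-MS enrichment filter.
Every statistic is exercisable on synthetic data with known ground truth.

## The discriminating statistics

Let $m_{ij}$ be the methylation percentage of locus $i$ in biological
replicate $j$ (a pooled-count percentage, see below), within one LINE1
family and genotype.

**Per-replicate family median.** The median over loci is robust to a failed
minority: under stochastic failure with per-replicate failure probability
$p < 0.5$, the median stays at the unaffected level $100\,\mu_{hi}$, while
under uniform inefficiency it moves to $100\,f\,\mu_{hi}$. Equal medians
between two hypomorphic genotypes therefore argue against mere
inefficiency. Medians are compared with unpaired two-tailed Student's
(pooled-variance) t-tests on the per-replicate medians.

**Summed across-replicate variance.** For each locus with a complete set of
replicate values, the unbiased sample variance across replicates
($n-1$ divisor) is summed over the family:
$$ V = \sum_i \mathrm{Var}_j(m_{ij}). $$
Only replicate-*inconsistent* failure inflates $V$. Under the stochastic
model a locus's values follow a two-point mixture
($100\,\mu_{hi}$ with probability $1-p$, $100\,\mu_{lo}$ with $p$), whose
sample variance has expectation $p(1-p)\,\Delta^2$ with
$\Delta = 100(\mu_{hi}-\mu_{lo})$; summed over $N$ eligible loci the
statistic separates from the deterministic/uniform alternatives by
$\Theta(N\,p(1-p)\,\Delta^2)$, while those alternatives leave only binomial
coverage noise $\approx 100^2\, m(1-m) / C$ per locus at total locus
coverage $C$. The tests verify the mixture expectation to within 10% at
$N = 500$, $p = 0.3$, $\Delta = 85$, and that the deterministic statistic is
below 5% of it.

Because variance sums over unequal replicate numbers are not comparable,
comparisons refuse unbalanced genotypes unless explicitly overridden —
mirroring the practice of dropping surplus replicates for consistency.

**Variance comparison test.** The test for elevated $V$ in genotype A over
genotype B permutes genotype labels across the pooled replicate columns
independently within each complete-case locus, using the difference of
summed variances as the statistic and the add-one convention
$p = (k+1)/(B+1)$ with $B \ge 999$ label permutations. A permutation scheme
was chosen over an F-test because, with three replicates per genotype,
normality of per-locus variances is indefensible. Internally the
permutation null is computed by enumerating the $\binom{2R}{R}$ column
subsets once per locus and sampling subset indices, which is exactly
equivalent to uniform label permutation and keeps the 200-cohort power
study fast.

**Classifier.** `classify_failure_mode()` applies the hypotheses in
sequence: (1) no significant loss of per-replicate family means versus wild
type → *wildtype-like*; (2) per-replicate medians significantly reduced
*and* the across-locus spread of the test genotype within a factor
(`spread_ratio_max`, default 3) of wild type (a whole-distribution shift,
not a failed subset) → *uniform_inefficiency*; (3) summed variance
significantly elevated versus every reference genotype → *stochastic*;
(4) otherwise → *deterministic*. Component p-values are Benjamini–Hochberg
adjusted together and compared against `alpha = 0.05`. The spread-ratio
guard matters in practice: with high coverage, a stochastic genotype's
medians can differ from wild type by a statistically significant but
scientifically trivial amount; its grossly widened locus distribution is
what keeps it out of the uniform branch.

## Per-locus quantification

Cytosine reports are strand-merged (a `+` cytosine at position $i$ and a
`-` cytosine at $i+1$ form one CpG dyad with summed counts), assigned to
0-based half-open locus intervals, and pooled: the locus percentage is
$100 \sum \text{meth} / \sum (\text{meth}+\text{unmeth})$, a
coverage-weighted ratio rather than a mean of per-CpG ratios. The pooled
convention matches Bismark-style aggregation; whether the original analyses
pooled or averaged is not documented, so the choice is exposed and tested.
Loci with pooled coverage below `min_total_coverage` (default 5) or fewer
than `min_cpg_units` (default 3) covered dyads are missing, and downstream
statistics are pairwise-complete (the variance statistic, stricter, is
complete-case). Feature-class percentages follow interval subtraction:
genic/promoter/CpG-island classes exclude transposable elements, the
intergenic class excludes both transposable elements and genes, and the
transposon class excludes genes.

Metaplots map each dyad to a consensus coordinate by proportional scaling —
the fraction of the way through the locus on its strand, times the number
of body bins (default 100), with minus-strand loci orientation-flipped so
bin 1 is the 5′ end — plus 2 kb flanks at 100 bp per bin. Per-locus
alignment to the consensus would be more faithful for 5′-truncated copies
but requires sequence; proportional scaling is deterministic, testable, and
exact for the synthetic cohorts. The promoter test averages the first 25
body bins per replicate and compares genotypes with Student's t-tests,
BH-corrected across families.

## The synthetic methylome

`simulate_annotation()` / `simulate_cohort()` generate the study
conditions: families of non-overlapping full-length loci on a synthetic
chromosome, per-locus divergence drawn from a folded normal per family (a
proxy for element age), per-CpG coverage Poisson(`coverage_lambda`) split
across the two strands, and methylated calls Binomial at the locus's true
level. The failure models set true levels exactly as in the three
hypotheses; only loci with divergence ≤ `divergence_max` are eligible
(old elements are immune under every model, emulating the near-wildtype
behaviour of old LINE1 families). Deterministic failed subsets depend on
the master seed and genotype but never the replicate; stochastic fates are
drawn per (locus, replicate). Defaults used throughout the tests are the
discrimination conditions: $\mu_{hi} = 0.85$, $\mu_{lo} = 0$, $p = q = 0.3$,
$f = 0.6$, three replicates, 500 eligible loci, per-CpG coverage 500-1000.
No bisulfite/enzymatic conversion error is modelled — conversion failure is
absorbed into $\mu$ — and no read-level structure exists, so the simulator
validates the statistics, not aligner or extraction behaviour. Real repeat
annotations also contain truncated and nested copies; overlapping loci are
merely tolerated (with a warning), not emulated.

`simulate_locus_matrix()` is a locus-level shortcut: pooled locus coverage
is Poisson(`coverage_lambda * cpgs_per_locus`) — the exact distribution of
the summed per-CpG depths — with Binomial calls at the true level, giving a
matrix distribution identical to running the full per-cytosine pipeline.
The power study (`power_simulation()`, 200 cohorts per model) runs on this
sampler; a test cross-checks it against the full pipeline.

## Image statistics

`simulate_scene()` builds 16-bit, single-plane scenes of round nuclei with
DAPI-dense heterochromatin at the nuclear periphery and around an offset
nucleolus — the geometry of gonocyte constitutive heterochromatin — plus
two factor channels whose pixelwise textures are shared (`colocalised`,
with an exact target Pearson via a common latent field), independent, or
heterochromatin-suppressed (`excluded`), optional factor foci inside
heterochromatin, and FISH spots placed inside or outside the
heterochromatin mask with exact geometric ground-truth flags. Noise is
Poisson shot noise plus Gaussian read noise. Pixels are independent within
a cell's texture; real euchromatin has spatial autocorrelation, which is
exactly what the block-shuffle null is designed to respect, so calibration
results here demonstrate correctness of the machinery, not robustness to
arbitrary texture scales.

**Costes auto-threshold.** Channel 2 is regressed on channel 1 (ordinary
least squares over the masked pixels; a non-positive slope leaves
thresholds undefined with a warning), and the threshold pair
$(T_1, a T_1 + b)$ is lowered until the Pearson correlation of pixels below
*both* thresholds is ≤ 0, or the below-set becomes too small or constant.
The search bisects over intensity steps and then settles the boundary
locally. Bisection provably agrees with a top-down exhaustive scan when the
below-threshold correlation is monotone in the threshold; with pixel noise
the correlation wiggles in a band around its zero crossing and *any*
bisection may settle one crossing below the scan. The oracle-equivalence
tests therefore use random piecewise-linear image pairs (anti-correlated
below a knee, correlated above), where the crossing is well-posed —
agreement is then exact in 50/50 random cases — and a separate test bounds
the discrepancy on noisy pairs.

**Randomisation.** The significance test shuffles channel-1 tiles of
`block_px` (the point-spread-function width, default 4) that lie fully
inside the mask — partial edge tiles stay fixed rather than wrapping, so no
intensities are fabricated outside the mask — and recomputes the full
thresholded-Pearson statistic each round (thresholds re-derived on the
shuffled pair; when undefined the plain masked Pearson is the fallback).
Recomputing per round makes the statistic a pure function of the
arrangement, so under the null the observed and shuffled statistics are
exchangeable and $p = (k+1)/(\text{rounds}+1)$ is exactly calibrated:
with 20 rounds the smallest attainable p is $1/21 \approx 0.048$, attained
on truly independent channels at rate $1/21$ (verified on 500 synthetic
cells) and essentially always on colocalised cells at target $R = 0.8$.

**Heterochromatin overlap.** `dapi_dense_mask()` operationalises "set DAPI
brightness to saturate chromocenters": pixels at or above a reference
quantile (per cell, or pooled as the somatic-reference analogue) are dense.
A FISH locus is heterochromatic iff its disc shares at least one pixel with
the dense mask — partial overlap suffices. For quantitative recovery the
quantile should sit slightly *above* the complement of the expected
heterochromatin area fraction (0.75 for the default geometry, whose
heterochromatin occupies ~28% of the nucleus): the estimated mask is then
nested inside the true dense region, and scattered threshold noise cannot
flip euchromatic spots. Foci detection (a threshold of per-cell median +
5 robust SDs, grown to connected regions of at least a
`min_radius_px`-disc's area) stands in for what was a manual assignment in
the original workflow; the detector is deliberately simple and is validated
on planted Gaussian foci.

## IP-MS filter

`enrichment_stats()` reports the log2 ratio of arm means with zero
intensities imputed at half the smallest nonzero intensity in the table (a
deterministic stand-in for the undocumented imputation of the original
processing) and a two-sided Student's t-test on log2 intensities;
`filter_hits()` keeps proteins with $P < 0.05$ and fold enrichment
strictly > 4. Both thresholds are strict inequalities, as printed.

## Numerical and degenerate-input conventions

Zero-coverage loci are missing, never division errors. Two-sample t-tests
on zero-variance, equal-mean inputs return $t = 0, p = 1$ (and $p = 0$ for
the unequal-mean degenerate limit). Spearman correlations use average
ranks for ties and are missing when either margin is constant. BH
adjustment validates $p \in [0,1]$ and delegates to the standard step-up
implementation. All simulations derive independent substream seeds from a
single master seed via a stable string hash (kept below $2^{31}$), so
cohorts are reproducible and replicates independent.

## Problem sizes used by the checks

The test suite and the acceptance script run the variance analytics on 500
loci at per-CpG coverage 1000 with 3 replicates; the classifier power study
on 200 cohorts per model at 500 loci and coverage 500; threshold-oracle
agreement on 50 random 64×64 8-bit pairs; randomisation calibration on 500
independent and 100 colocalised cells; and overlap recovery on 3 images ×
40 cells per simulated fraction. These sizes keep every Monte Carlo
tolerance (10% on the variance ratio, 3 binomial SEs on rates, ±2
percentage points on medians) comfortably above the residual sampling
noise. No result is stated in this vignette that the tests or
`scripts/acceptance.R` do not themselves compute.

## Known limitations

- No read-level simulation (conversion errors, mapping bias, PCR
  duplicates are out of scope); the simulators validate statistics
  downstream of methylation extraction.
- Proportional consensus scaling ignores internal deletions; metaplot bins
  are comparable across genotypes but not alignable to real consensus
  positions for truncated elements.
- The classifier assumes the four generating models are exhaustive; mixed
  failure modes will be assigned to the dominant signature.
- 2-D image scenes only; the colocalisation statistics operate per plane,
  as the processed-image quantification did.
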