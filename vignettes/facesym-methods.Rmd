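---
title: "Methods: facial asymmetry, heterozygosity and genotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial asymmetry, heterozygosity and genotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesym)
```

## The scientific problem

Small, random departures of a bilaterally symmetric structure from perfect
symmetry — *fluctuating asymmetry* (FA) — are widely used as a proxy for
developmental imprecision: an organism under genetic or environmental stress
is assumed to buffer its development less well, and to end up less
symmetric. One long-standing genetic hypothesis is that individual
heterozygosity improves buffering, so that more homozygous individuals
should be more asymmetric. `facesym` implements the full analysis needed to
test that hypothesis on 3D facial landmark data and SNP genotype panels:

1. per-individual asymmetry scores from landmarks (object-symmetry
   Procrustes decomposition into total, directional and fluctuating
   asymmetry);
2. a per-individual homozygosity index weighted by locus variability
   (homozygosity by loci, HL);
3. association models: ordinary least-squares regressions of the scores on
   demographics, HL and reference-coded genotypes with stepwise interaction
   pruning, and an ANOVA regression tree over a whole SNP panel;
4. a synthetic cohort generator that plants every quantity the pipeline is
   supposed to recover, so the implementation is testable against a known
   truth.

## Asymmetry scores: object symmetry

A configuration of $k$ landmarks in 3D is a $k \times 3$ matrix $X$. The
structure's symmetry is described by a scheme: bilateral pairs (here Zygion,
Alare and the eyeball centers, left/right) and midline landmarks (Nasion,
Pronasale, Subnasale), with the midsagittal plane taken as $x = 0$. The
*reflected-relabeled* copy $X^\ast$ negates the $x$ coordinate of every
landmark and swaps the labels within each pair. A configuration is
symmetric exactly when $X^\ast$ and $X$ coincide after superimposition.

All $2n$ configurations (originals plus reflected copies) enter one joint
generalized Procrustes analysis (GPA): each configuration is centered,
scaled to unit centroid size, and iteratively rotated to the evolving
consensus until the root-mean-square change of the consensus falls below
$10^{-10}$ (at most 100 iterations). Rotations solve the orthogonal
Procrustes problem by SVD with the usual determinant correction, so
reflections are never introduced and handedness is preserved. Including the
reflected copies in the consensus is standard object-symmetry practice and
makes the consensus itself symmetric.

The individual asymmetry vector is the flattened difference between the
aligned original and the aligned reflected copy,
$a_i = \mathrm{vec}(X_i^{\mathrm{al}} - X_i^{\ast\,\mathrm{al}})$, and the
scores are Euclidean norms in the aligned coordinate space:

* total asymmetry $\mathrm{TA}_i = \lVert a_i \rVert$ — the Procrustes-space
  distance between face and reflection;
* directional asymmetry $\mathrm{DA} = \bar a$, the population mean
  asymmetry pattern (reported as a vector and as its magnitude, not
  significance-tested);
* fluctuating asymmetry $\mathrm{FA}_i = \lVert a_i - \bar a \rVert$, the
  individual deviation from the population pattern.

Conventions chosen (the literature varies): full-Procrustes unit-size
scaling (shape only, no size); no tangent-space projection beyond the
alignment itself; no factor-½ halving of the face–reflection difference.
These choices are monotone-equivalent to other published object-symmetry
scores and make every number reproducible from this document. Scores in the
small-deviation regime are first-order identical to formal Procrustes
distances; the test suite checks the agreement against an exhaustive
rotation-search oracle at tolerance $10^{-4}$.

## Homozygosity by loci

For a biallelic locus with ALT allele frequency $p$, the expected
heterozygosity is $E = 2p(1-p)$. The HL index of an individual is

$$ \mathrm{HL} \;=\; \frac{\sum_h E_h}{\sum_h E_h + \sum_j E_j}, $$

where $h$ runs over the loci the individual carries in homozygosis and $j$
over those in heterozygosis. HL is 0 when every locus is heterozygous and 1
when every locus is homozygous, and weighs variable loci more than
near-monomorphic ones. Implementation conventions: $E$ uses the plug-in
estimator $2\hat p(1-\hat p)$ with $\hat p$ from the analyzed cohort itself
(a `2n/(2n-1)` small-sample correction is available as a flag); allele
frequencies are estimated jointly across cohorts by default (per-group
estimation is possible by subsetting); missing calls contribute to neither
sum and `n_loci_used` is reported so callers can filter; an individual
whose usable loci are all monomorphic has undefined HL (returned missing,
with a warning). Population summaries report per-group mean, standard
error, and decile percentiles computed by linear interpolation between
closest order statistics (R's type-7 rule) — percentile conventions differ
between packages, so the rule is fixed and tested against a hand
computation.

## Association models

The OLS design encodes sex as a male indicator (female reference), age and
HL as numeric covariates, cohort as an indicator against the first label,
and each SNP as two treatment-coded indicators (genotype 1 vs 0 and 2 vs 0,
with 0/1/2 counting ALT alleles). Interactions among sex, age and HL can be
requested; `prune_interactions()` starts from all three, refits repeatedly,
and removes the least significant interaction while its p value exceeds
`alpha` (default 0.05) — largest p first, one at a time, base terms always
retained. Inference is the standard t machinery on the unbiased residual
variance (the fit itself is delegated to `lm()`); p values are reported
unadjusted, and genome-wide claims are made only through
`genomewide_flag()` at the conventional $p \le 10^{-8}$.

The ANOVA tree (`anova_tree()`) is grown by exhaustive search: at each node
every locus contributes the nonredundant binary partitions of its observed
genotype classes (each single class against the rest — for three classes
these are exactly the three possible binary splits), and the split
maximizing the within-node sum-of-squares reduction is taken. A split is
accepted only if its improvement reaches `cp` (default 0.01) times the root
sum of squares and both children hold at least `minsplit / 3` individuals
(`minsplit` defaults to 20, `max_depth` to 30). There is no
cross-validation pruning: growth is gated by `cp` alone, which is the
behavior the null/planted-signal validation targets; `cp` is exposed so
sensitivity can be explored. Missing calls follow the majority branch (no
surrogate splits), both in fitting and in prediction, and the number routed
this way is recorded per node. Ties in the split search are broken
deterministically (first locus in column order, lowest genotype class).
A root-only tree is a valid result and is how "no SNP identified" is
expressed.

## The synthetic cohort generator

The generator's defaults emulate the data structure of a large two-cohort
adult imaging-genetics study: $n = 3215$ individuals aged 45–92 years
(truncated normal, mean 59.5, SD 8.0, exact rejection sampling — clipping
would distort the moments), two cohort labels RS1/RS2 in proportion
2470:745, an even sex split (the emulated study does not publish one), and
102 independent biallelic SNPs. Genotypes follow the inbreeding-deformed
Hardy–Weinberg law: with ALT frequency $p$ and inbreeding coefficient $F$,
$P(\mathrm{het}) = 2p(1-p)(1-F)$ with the matching homozygote excess;
$F = 0$ by default (the emulated cohort is explicitly non-inbred). Allele
frequencies not supplied are drawn Uniform(0.1, 0.9), avoiding
near-monomorphic loci where HL is ill-conditioned.

Faces are built additively from a symmetric template (unit centroid size):

* a symmetric individual deviation, Gaussian with scale `sym_sigma` (default
  0.013 per degree of freedom, i.e. total symmetric shape variation of
  about 0.05 Procrustes units — the realistic magnitude of adult facial
  shape variation);
* half of a planted antisymmetric asymmetry field $a_i = d + e_i$, so that
  the face-minus-reflection difference recovers $a_i$ exactly to first
  order; $d$ is the planted DA (default norm $0.05\,\sigma_0$) and $e_i$ is
  isotropic Gaussian with scale
  $\sigma_i = \sigma_0 + \beta_{\mathrm{HL}} \mathrm{HL}_i$ (plus optional
  per-genotype, sex and age shifts, all zero by default);
* an arbitrary random rotation, translation and positive scale (removed
  exactly by the downstream GPA — verified to $10^{-8}$);
* i.i.d. Gaussian coordinate noise `noise_sigma` (default $\sigma_0 / 10$).

Two scales were fixed once, on magnitude grounds: $\sigma_0 = 5 \times
10^{-4}$ puts the FA scores in the $10^{-3}$ range that unit-size Procrustes
facial asymmetry studies report, and the default DA norm of 5% of
$\sigma_0$ reproduces the published regime in which DA is negligible and TA
and FA are nearly collinear.

**The antisymmetric subspace projection.** For 9 landmarks, antisymmetric
deviations have 12 degrees of freedom (3 per bilateral pair, 1 per midline
landmark — midline points can move only off the midplane). Three of these
are pure similarity motions: translation along the reflection axis and the
two rotations about the in-plane axes. Procrustes alignment removes exactly
those three, so only a 9-dimensional *asymmetric shape subspace* survives
the pipeline. The generator therefore projects every planted field (DA and
the $e_i$) onto that subspace before use; without the projection, part of
any planted signal would be silently absorbed by the superimposition and no
object-symmetry pipeline could recover it. `asym_basis()` exposes the
bases.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: linkage disequilibrium (loci are independent),
ancestry structure, landmark-localization error that is spatially
correlated or landmark-specific (noise is i.i.d. and isotropic), real
facial shape distributions (symmetric deviations are Gaussian in an
orthonormal basis), and any environmental covariance between asymmetry and
the covariates. Sex and age effects on the FA scale exist as optional
knobs (`beta_male`, `beta_age`) but are off by default, so the default
cohort is a genuine null for every association term.

## Numerical choices and degenerate inputs

* GPA: tolerance $10^{-10}$ on the RMS consensus change, `max_iter = 100`;
  non-convergence returns a flagged result with a warning. The objective
  (summed squared deviation from the consensus) is non-increasing by
  construction and tested.
* Rotations: SVD of the $3\times3$ cross-covariance; determinant
  correction flips the smallest singular direction; configurations of rank
  < 2 yield an identity rotation with a warning. Ties in degenerate SVDs
  are resolved by base R's deterministic SVD sign convention.
* Scores: exact zeros are reported as numerically tiny values bounded by
  the GPA tolerance; FA for a single individual is undefined (hard error,
  with a `ta_only` escape hatch).
* Genotype I/O: half-calls and `./.` become missing; multi-allelic VCF
  records are skipped with a warning; non-diploid genotypes are a hard
  error naming the record. Values outside {0, 1, 2, NA} never enter a
  `genotype_matrix`.
* Measurement-noise attenuation: adding i.i.d. coordinate noise inflates
  every asymmetry norm through a concave
  $\sqrt{\sigma_i^2 + \mathrm{const}}$ response, which attenuates the
  fitted FA-on-HL slope by roughly 3% at the default noise level. This is
  a property of norm-based scores, not of the estimator; recovery tests
  therefore run on the noise-free signal path, and analysts should expect
  the same mild attenuation on real data.
* A norm-based score of a $d$-dof Gaussian field of scale $\sigma$ has
  expectation $\sigma$ times the mean of a $\chi_d$ distribution
  ($\approx 2.9$ for $d = 9$), so regression slopes of FA on a covariate
  estimate that multiple of the planted scale effect. Validation compares
  the pipeline's slope against the same regression run on the planted
  fields, which is the well-defined notion of recovery for such scores.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: a
random-search-plus-refinement rotation minimizer, the closed-form two-shape
superimposition, an exhaustive split enumerator, an SVD pseudo-inverse for
OLS, a formula-based reimplementation of the stepwise pruning, and direct
Monte-Carlo sampling for HL. Parameter-recovery and error-rate experiments
use: 20 seeds at $n = 2000$ (DA vector), 200 cohorts at $n = 1000$ (HL
slope), 1000 null fits at $n = 1000$ (type-I error of the HL term,
expected within [0.03, 0.07] at $\alpha = 0.05$), and 100 null tree
replicates at $n = 3000$ with the full 102-locus panel (root-only
expected in the large majority). These sizes give Monte-Carlo standard
errors comfortably below the effects being checked while keeping the whole
suite fast enough to run routinely.

## Known limitations

* Scores are norms, hence biased upward for small true asymmetry (a
  $\chi$-distribution mean effect); comparisons between groups of similar
  size are unaffected, but absolute score levels should not be
  over-interpreted.
* The tree is grow-only with a `cp` gate; it is intended as a screening
  device ("is any locus associated?"), not as a calibrated predictor.
* HL from a ~100-SNP panel is a noisy proxy for genome-wide heterozygosity;
  the package reports it as defined, and the generator lets users explore
  how much signal such a panel can carry at a given $F$.
* No measurement-error decomposition from replicate digitizations is
  implemented (the emulated study has no replicates), so FA here includes
  device noise.
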