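---
title: "Models and methods behind shellpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shellpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

shellpop compares the ability of a small multiallelic marker panel
(microsatellites) and a large biallelic panel (ddRAD SNPs) to resolve
fine-scale population structure in a benthic invertebrate, and couples
that comparison with outline morphometrics and pigmentation analysis of
the same shells. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## The synthetic study

Every analysis in the package can be exercised on generated data with
known structure. The generator builds:

* **Genotypes.** A base allele-frequency spectrum per panel —
  microsatellite loci draw their allele number from `2 + Poisson(9)`
  (mean ≈ 11 alleles/locus, matching a typical moderately polymorphic
  panel) with symmetric Dirichlet(1) frequencies; SNP loci are biallelic
  with minor-allele frequency Uniform(0.05, 0.5). Subpopulations diverge
  from the base by Wright–Fisher drift: `t` successive multinomial
  resamplings of `2 Ne` gene copies, independently per locus and
  subpopulation, with no mutation or migration. After `t` generations the
  expected standardized divergence is `1 - (1 - 1/(2 Ne))^t`, which
  doubles as the analytic check on the simulator. Individuals are sampled
  under Hardy–Weinberg proportions (two independent allele draws).
* **ddRAD call sets.** Per-genotype stack depths (shifted negative
  binomial, mean 20), independent per-genotype missingness, and a
  grouping of SNPs into tags, so the published filtering rules have
  something to act on.
* **Shells.** Outlines are inverse elliptic-Fourier reconstructions of
  population mean coefficient sets plus independent Gaussian coefficient
  noise. The default model is a fan-shaped valve whose harmonic-2/3
  coefficients vary smoothly across populations (hinge angle and hinge
  height), with within-population coefficient SD 0.01 against
  between-population steps of about 0.06/9 per coefficient — enough for a
  MANOVA at 9 × 20 shells to detect structure essentially always while
  leaving visible within-population scatter.
* **Pigmentation images.** An elliptical shell mask whose pigmented
  subset (a blob-shaped region chosen by a low-frequency random field)
  covers a target fraction of the shell at a target mean grey in the
  0–110 window; unpigmented shell pixels sit at grey 150–230.

A single integer seed drives everything; each stage derives a child seed
deterministically from the stage name, so stages are reproducible and
statistically decoupled. What the generator does **not** emulate: linked
loci, genotyping error, null alleles, allele dropout, mutation,
migration, photographic artefacts (shadows, reflections), or
size–shape allometry. Tests passing on these data show the estimators
and the pipeline work as specified; they do not validate robustness to
those real-data complications.

## Population genetics

**Diversity.** Expected heterozygosity uses the small-sample unbiased
estimator `He = 2n/(2n-1) (1 - sum p^2)`; observed heterozygosity is the
fraction of non-missing genotypes that are heterozygous. Missing
genotypes are excluded pairwise per locus, never by deleting whole
individuals.

**Hardy–Weinberg exact test.** The probability-test p-value (the summed
conditional probability of all genotype tables no more probable than the
observed one, given allele counts) is estimated by a Markov chain on the
pairing of gene copies: each step proposes swapping two uniformly chosen
copies. Uniform-over-pairings is stationary for this symmetric walk and
induces exactly `P(table) ∝ 2^H / prod n_ij!`, so every proposal is
accepted — the switch chain in its always-accept form, implemented in
C++. Defaults are 10,000 dememorization steps and 1,000 batches of
10,000 iterations; the Monte-Carlo standard error is the between-batch
standard deviation over `sqrt(batches)`. Table probabilities are compared
on the log scale with an absolute tolerance of 1e-9 so tied tables are
counted, and the running log-probability is refreshed from the counts at
every batch boundary to stop floating-point drift.

**F_ST.** The Weir–Cockerham variance-components estimator: per allele
per locus, components `a` (among populations), `b` (among individuals
within populations) and `c` (within individuals) are computed with
per-locus sample sizes honouring missing data; the multilocus estimate is
the ratio of summed components and may legitimately be negative.
Pairwise significance permutes whole individuals (both alleles together)
between the two populations of a pair — the permutation unit used by
standard F-statistics software — with the add-one estimator
`p = (1 + #{theta_perm >= theta_obs})/(n_perm + 1)`, one-sided, so
permutation p-values are never zero. Permutations are vectorized: all
membership indicators are assembled into one matrix and the components
obtained by a single cross-product per pair.

**FDR.** Storey q-values at a single `lambda = 0.5`:
`pi0 = min(1, mean(p > lambda)/(1 - lambda))`, then the step-up
minimization on sorted p-values. The single-lambda estimate (rather than
a spline over a lambda grid) is deliberate: with only 36 pairwise tests a
spline fit of pi0 is noisy, and the single-lambda form has the useful
exact property that forcing `pi0 = 1` reproduces Benjamini–Hochberg,
which the tests assert. The estimate can be unstable when many p-values
are genuinely small (pi0 collapses towards 0 and q-values can undercut
p-values); the package exposes `pi0` as an override for that situation.

**Filters.** The ddRAD filter applies, in order: (1) keep biallelic SNPs
genotyped in at least 40 individuals; (2) keep the best-called SNP per
tag; (3) set genotypes with stack depth below 5 to missing. Because
step 3 can push a SNP back below the call-count threshold, the
call-count/biallelic predicate is re-applied once after masking; this
makes the filter idempotent (re-running it on its own output is a
no-op), which is the property the tests check. The microsatellite rule
excludes loci that deviate from HWE (after FDR) in more than 4 of the
populations — the threshold separating the published keep/drop pattern
(loci deviating in 5 and 7 populations dropped, in ≤ 2 kept); the 3–4
range is untested in the source material, so the threshold is exposed as
a parameter.

**Power simulation.** Per replicate: drift all subpopulations, sample
genotypes, and test allele-frequency homogeneity across subpopulations
per locus with a Pearson chi-square on the subpopulation × allele count
table, summing statistics and degrees of freedom over loci. Two
numerical guards matter. First, alleles whose minimum per-subpopulation
expected count falls below 1 are merged into the next-rarest class
before the test. Second, each locus statistic is rescaled by
`(N-1)/N` — its exact conditional mean under fixed margins is
`df · N/(N-1)` — which is negligible for one table but decisive when
thousands of sparse per-locus tables are summed: without it the summed
statistic's mean exceeds its degrees of freedom by several null standard
deviations and the type-I error at `t = 0` reaches ~0.26 instead of
0.05 for a 2,000-locus SNP panel at five diploids per subpopulation. A
per-locus exact-test variant (Monte-Carlo Fisher combined over loci by
Fisher's method) is available behind `method = "fisher"`; the chi-square
default is deterministic and much faster, and both calibrate correctly
at `t = 0`.

**Mantel test.** Pearson correlation over upper-triangle entries with
simultaneous row/column permutation of one matrix, one-sided, add-one
estimator. Whether the original pairwise-F_ST significance was one- or
two-sided is not documented; one-sided (greater) is used throughout.

**Genotype PCA.** Individuals are encoded as per-allele dosage vectors
(0/1/2), missing entries mean-imputed per column, columns centered (not
scaled), decomposition by SVD. Components carry a deterministic sign
(largest-magnitude loading positive). PCA plus pairwise F_ST act as the
in-package detector of genetic clusters; Bayesian admixture clustering
is deliberately out of scope.

## Morphometrics

Outlines are traced from binary masks by Moore-neighbour (8-connected)
boundary following with Jacob's stopping criterion, normalized to
counterclockwise orientation with the start point rotated to maximal x
after centering. Smoothing is the cyclic three-point moving average
(default 10 iterations — the iteration count used upstream is
unreported, so it is a visible parameter). Resampling places k = 1000
pseudo-landmarks at equal arc length. Generalized Procrustes
superimposition is full GPA: center, scale to unit centroid size, rotate
(no reflection) against an iteratively re-estimated mean, converging
when the mean moves < 1e-8.

Elliptic Fourier analysis uses the standard closed-polygon formulas with
no first-ellipse normalization (alignment is GPA's job). The curve
parameter is cumulative chord length by default; a uniform per-point
parameterization is available (`param = "uniform"`) and is the mode in
which the analytic identities hold exactly — an ellipse sampled
uniformly in angle has pure harmonic-1 content under the uniform
parameter, but genuine higher harmonics under arc-length
parameterization, which is a property of the parameterization, not an
implementation artefact. Reconstruction evaluates the truncated series
at equally spaced parameter values; a useful exactness check used in the
tests is that linear interpolation attenuates harmonic n by exactly
`sinc^2(pi n / N)` at N sample points.

The harmonic-count calibration returns the smallest N whose mean
cumulative power fraction reaches the threshold (default 0.98). By
default harmonic 1 is excluded from the baseline: for Procrustes-aligned,
ellipse-like shells harmonic 1 alone holds > 99% of raw power, so a "15
harmonics for 98%" style criterion is only informative on the residual
spectrum. `exclude_first = FALSE` restores the raw-spectrum convention.

Shape statistics: PCA of the 4-per-harmonic descriptor matrix (centered,
unscaled, SVD); component retention at 95% cumulative variance; one-way
MANOVA with Wilks' Λ = det(E)/det(E+H) and Rao's F approximation (which
reduces exactly to the one-way ANOVA F at one response; Bartlett's
chi-square is available). The originally reported MANOVA df layout
(F with 8 numerator df for 15 responses) does not match any standard
Wilks approximation for 15 response variables; the package reports the
standard Rao degrees of freedom. Thin-plate splines use the kernel
`U(r) = r^2 log r^2`, solving the interpolation system directly;
bending energy is the kernel quadratic form (exactly zero for affine
maps). TPS between group mean shapes uses every 25th pseudo-landmark by
default — 40 landmarks keep the linear system well conditioned at 1000
pseudo-landmarks.

## Colour

Images are converted to grey as the per-pixel channel mean, rounded
half-up. Pigmented pixels are shell pixels with grey at or below 110;
the boundary is included by default (the window is described as "0–110"
without stating inclusivity) and exposed as a flag. The colour index is
`sqrt(mean pigment grey × pigmented fraction)`, implemented literally as
the formula states even though darker pigment means *lower* grey — an
inverted-intensity mode (`110 - mean grey`) would rank shells by
darkness instead; the literal form is the default because it is the
printed definition. Population differences are tested by classical
model-I one-way ANOVA.

## Association models

Phenotypes (colour index, shape PC1) are regressed on the first two
genetic principal components with population as a random intercept,
fitted by maximum likelihood (lme4; the deviance is profiled over the
between/within variance ratio, so the boundary fit `var_between = 0`
reduces exactly to OLS). Per-coefficient tests are Wald chi-square
`(estimate/se)^2` on 1 df by default, with a likelihood-ratio variant
behind a flag; ML rather than REML is the default to match the stated
estimation approach, REML being available. A named outlier population
can be excluded before fitting, which is how the workflow asks whether
phenotype tracks the residual (non-outlier) genetic background.

## Problem sizes and determinism

The packaged analysis scripts and tests run at desk scale by choice: 300
SNP loci (the study's full panel was 10,539), 13 microsatellites, nine
populations of 20, 1000 pseudo-landmarks in the drivers and 300 in the
repeated-battery tests, 500 power replicates for microsatellite panels
and 200 at 2,000 loci for SNPs. Power at the full SNP panel size is
strictly higher than at the scaled panel (the summed-chi-square
noncentrality grows linearly in locus count), so scaled results are
conservative for the panel-comparison conclusion. Every stochastic step
takes an explicit seed, all seeds derive from one global seed by stage
name, and re-running any script or the whole pipeline with the same seed
reproduces identical output files.
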