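---
title: "Deep phenotypic profiling of synaptic puncta: models and methods"
author: "synProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep phenotypic profiling of synaptic puncta: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synProfiler)
```

## The problem

Fluorescent reporters of presynaptic material render the synapses of a single
neuron as a row of micron-scale puncta along its axon. Mutations that
grossly disrupt this pattern are easy to score by eye; most interesting
alleles are not. Two obstacles stand in the way of scoring subtle alleles:
isogenic populations are phenotypically heterogeneous (distributions of
puncta number, size, intensity and spacing overlap heavily between genotypes
even under controlled culture), and many informative traits are statistical
in nature (variability, distributional shape, regional redistribution) and
thus invisible to qualitative inspection. No single feature threshold
separates such populations.

synProfiler addresses this with population-level, multidimensional
phenotyping: each animal's puncta pattern is condensed into a fixed
76-feature profile, and a genotype is characterized not by any single
metric but by the direction in this 76-dimensional phenospace that best
separates its population from wild type.

## Pipeline overview

1. **Detection** (`detectCandidates`, `classifyCandidates`,
   `segmentPuncta`): multi-scale Laplacian-of-Gaussian blob candidates,
   pruned by a support vector machine on six descriptors, then segmented
   into per-punctum records (position, size, intensities).
2. **Profiling** (`extractProfile`, `qcFilter`): 76 descriptive metrics per
   animal; animals with fewer than five puncta are excluded.
3. **Pairwise models** (`fitSWLR`, `fitBestFeature`, `crossValidate`):
   stepwise logistic regression of mutant vs. wild type on standardized
   features; evaluation by cross-validated ROC/AUC and by
   sensitivity/specificity at a 50% probability threshold, against the
   best-single-feature baseline.
4. **Population relations** (`crossModelMatrix`, `bestPairNetwork`,
   `zscorePopulationProfiles`, `weightedDistanceMatrix`,
   `hierarchicalCluster`): cross-scoring of every population under every
   model, and correlation-weighted phenotype distances feeding hierarchical
   clustering.
5. **Reporting** (`buildAverageWorm`, `renderAverageWorm`): per-genotype
   "average worm" schematics.

Everything is testable without external data because the synthetic-data
module (`simulateAxonImage`, `simulateAnimalPuncta`,
`simulatePopulationProfiles`, and the benchmark constructors) generates
ground-truthed images and populations with planted genotype effects.

## The synthetic generative model

An axon image is a horizontal, straightened segment: puncta are isotropic
2-D Gaussians whose width combines the punctum's intrinsic half-max radius
$r$ with the optical PSF, $\sigma_\mathrm{eff}^2 = (r/\sqrt{2\ln 2})^2 +
\sigma_\mathrm{psf}^2$ (in pixels), over a flat background with additive
Gaussian read noise and optional Poisson shot noise. The ground-truth
integrated intensity of a punctum is the full Gaussian integral
$2\pi A \sigma_\mathrm{eff}^2$; with zero background and noise the rendered
image conserves this total to better than $10^{-3}$ relative (puncta are
kept $\ge 4\sigma$ from the image edges).

A population is generated hierarchically. Each animal draws latent means —
puncta count $\lambda$, interpunctal spacing, punctum radius, peak
intensity — from between-animal lognormal distributions around the
genotype baseline; puncta are then drawn within the animal (truncated
Poisson count $\ge 1$, Gamma gaps, lognormal radii and intensities). The
between-animal layer is what makes isogenic populations heterogeneous, and
is the reason single-feature thresholds fail. Defaults (chosen once as
realistic for a motor-neuron axon segment imaged at 40x):

| parameter | default | between-animal CV | within-animal CV |
|---|---|---|---|
| puncta count | Poisson mean 18 | 0.15 | (Poisson) |
| interpunctal gap | 1.5 um | 0.12 | 0.45 |
| half-max radius | 0.5 um | 0.10 | 0.25 |
| peak intensity | 600 a.u. | 0.18 | 0.35 |

Genotype effects are planted as shifts of a baseline mean in units of its
between-animal SD, and/or multipliers on a within-animal CV
(`plantedEffect`). Randomness is organized as one master seed with
per-animal substreams derived by hashing (seed, genotype, animal index), so
populations can be extended without reshuffling existing animals.

What the generator does *not* emulate: axon curvature and tracing,
two-channel imaging, body autofluorescence, dendritic (ventral) puncta, or
any specific real strain's parameter values. Passing tests therefore
demonstrate the correctness and statistical soundness of the pipeline on
images with known truth — not that any particular real dataset would yield
particular AUCs.

## The 76-feature registry

`featureRegistry()` documents every feature: id, name, category (count,
size, intensity, spatial, regional, variability), units, and two
behavioural flags (whether the feature moves under axial translation, and
whether it scales linearly under a global intensity rescaling — both
enforced by property tests). Six ids have fixed, externally meaningful
names: 1 *number of puncta*, 21 *puncta intensity homogeneity*, 33
*intensity of posterior puncta*, 52 *interpunctal intensity*, 55 *10th
percentile of integrated intensity*, 75 *number of puncta in the top 75% of
size range*. The remaining ids are category-structured summary statistics
of the same quantities (per-animal moments, percentiles, range-band counts,
anterior/posterior sub-domain statistics, spacing statistics,
autocorrelations). Conventions that matter:

* percentiles interpolate linearly between order statistics;
* "homogeneity"/"variability" features are coefficients of variation
  (SD/mean), defined as 0 for degenerate input;
* anterior/posterior halves split the synaptic domain at its axial
  midpoint;
* "top p% of range" bands are relative to the per-animal min-max span, with
  a zero span placing every punctum in the band;
* interpunctal intensity is the background-subtracted fluorescence at gap
  midpoints — measured from the image during segmentation, or computed from
  the flanking Gaussians' tails in the simulator.

The registry is data: a different 76-entry list can be substituted without
touching extraction code, and the profile container (`PhenotypeProfiles`, a
`SummarizedExperiment`) carries it as `rowData`.

Animals with fewer than five puncta are excluded (`qcFilter`) because
several features (percentile spreads, spacing dispersion, autocorrelations)
are not computable; such animals are also typically mis-expressing the
reporter. An animal with exactly five puncta is retained.

## Detection and segmentation choices

The candidate stage is deliberately high-recall: scale-normalized LoG
responses at several sigmas, strict 8-neighbour local maxima above a
permissive threshold (3x the background noise propagated through the
kernel, estimated by MAD), merged across scales by response-ordered
non-maximum suppression. Precision is delegated to the classifier — a
linear-kernel SVM (radial optional) on six standardized descriptors: peak
intensity, local contrast, blob response, half-max area, eccentricity,
local background. On synthetic data, training labels come from matching
candidates to ground truth within 2-3 px; in an experimental setting,
manual curation would play this role. The trained machine is stored as
plain numbers and serialized to JSON with 17 significant digits, so a
reloaded model makes bit-identical decisions.

Segmentation measures, per accepted candidate: size as the area of the
half-max connected region (half-max radius also stored); integrated
intensity as the background-subtracted sum over a circular aperture of
3.5x the detection scale (capturing ~99% of a Gaussian's mass, which is why
a noiseless Gaussian's measurement matches $2\pi A s^2$ to a few percent);
peak as the candidate pixel above local background. Local background is the
median of the window's border ring (window half-width 5x scale, so the ring
sits in background); this makes intensity features invariant to constant
offsets. Pixels closer to another accepted peak are excluded from both
region and aperture, splitting overlapping puncta by nearest-peak
assignment. Axial positions are intensity-weighted centroids in
micrometres from the left image edge, anterior by convention; records are
sorted anterior to posterior.

## The stepwise logistic phenotype model

For a mutant/wild-type pair, features are z-scored on the pooled training
animals (so coefficients are comparable across features) and a logistic
regression is built by forward-backward selection: at each forward step the
candidate giving the largest deviance drop enters if its 1-df
likelihood-ratio p-value is below `pEnter` (default 0.05); any included
feature whose removal p-value exceeds `pRemove` (default 0.10) is dropped;
iteration continues to a fixed point, with a cap (`maxSteps`, default 20)
guarding runaway selection and cycling. Exact ties break to the lowest
feature id, making fits fully deterministic. The number of features a
mutant needs is itself informative — obvious alleles separate with one or
two, subtle ones recruit many weak descriptors.

Numerical choices: fits use an in-package IRLS engine (cross-checked
against `stats::glm` in the tests) because selection refits thousands of
small models inside cross-validation; complete or quasi-complete separation
is detected (divergent coefficients, non-convergence, or essentially zero
deviance) and handled by refitting with a small ridge stabiliser (1e-6) on
the non-intercept coefficients, recorded on the model object. The stored
deviance trace is the nested sequence — null deviance, then the deviance as
each finally selected feature is added in entry order — which is
non-increasing by construction.

The best-feature (BF) baseline fits all 76 single-feature models and keeps
the highest training AUC (ties to the lower id): the best-case scenario for
characterizing a mutant with one metric. Model quality is measured by:

* `rocAuc`: AUC as the probability that a random mutant outscores a random
  wild-type animal, ties counted one half (midrank identity; verified
  against exhaustive pair counting);
* `crossValidate`: stratified k-fold (default 5) with the full selection
  re-run inside each training fold, so reported AUCs carry no selection
  leakage; mean and SD across folds are reported;
* `sensitivitySpecificity`: true-positive and true-negative rates at a
  probability threshold of 50%.

## Benchmark design

Model-level benchmarks plant "+2 SD shifts in 3 of 76 features". Planting
additive shifts directly in *extracted* profiles turns out to be ill-posed
for selection-recovery checks, because extracted features obey exact
algebraic identities (puncta number equals anterior plus posterior counts;
domain length equals last minus first position; density and
length-per-punctum are ratios of these). A constant shift on one side of an
identity creates an artificial noise-free contrast, and stepwise selection
- correctly - exploits the redundant partners rather than the planted id.
The model benchmarks (`profileBenchmark`, via
`simulateCorrelatedProfiles`) therefore draw features from a factor-model
Gaussian with realistic redundancy but no exact identities: correlation 0.5
within a registry category, 0.1 across categories, unit marginal variance.
There a planted shift is identifiable, and the planted features are the
only columns with a systematic group difference. Null calibration,
clustering and severity benchmarks use the full puncta-level generative
pipeline (`nullPairBenchmark`, `clusterBenchmark`, `severityBenchmark`).

Benchmark sizes used by the test suite and the acceptance script — 200
animals per group for model benchmarks, 100 per population for clustering,
100 synthetic images for detection, 10-20 seed replicates — were chosen as
the smallest sizes at which the measured quantities are stable, and are
stated alongside every reported number.

## Relating genotypes

Populations are compared on their **mean z-scored profiles**: each feature
is z-scored over the pooled set of all QC-passing animals (a common scale;
a wild-type-only reference is available behind a flag) and averaged within
genotype. Constant features are dropped with a log. Distance between two
genotypes is a standardized Euclidean distance with per-feature weights
$w_j = 1/\sum_k |r_{jk}|$ (normalized to sum to the feature count), where
$r$ is the feature correlation over pooled animals. The phrase "weighted by
the inverse of the correlation coefficient" admits several readings; this
one was chosen because it directly implements the stated intent — counting
every phenotype aspect once rather than once per redundant feature: a block
of m perfectly correlated features receives total weight ~1 instead of m. A
Mahalanobis variant (inverse correlation matrix) and plain Euclidean are
available behind the `method` flag. Clustering is agglomerative with
average linkage by default (complete/single/Ward selectable); dendrograms
export as Newick, networks as GraphML.

Cross-model analysis scores every population under every model
(`crossModelMatrix`: mean probability per cell, self pairs flagged) and
links each model to the non-self population it scores highest
(`bestPairNetwork`; exact ties yield all tied edges, flagged). On planted
benchmarks, two genotypes sharing a generative effect pick each other as
best pairs — the synthetic analogue of re-isolates and outcrosses finding
one another.

## Average-worm schematics

`buildAverageWorm` condenses a population into n = round(mean count)
glyphs; the i-th glyph takes the (n-i+1/2)/n quantile of the population's
punctum size and intensity distributions (quantile functions interpolated
from the averaged per-animal percentile features), so glyphs run largest to
smallest and brightest to dimmest. Glyphs are drawn at mean-spacing
intervals; the ordering is display-only and never feeds back into analysis.
Rendering is a pure function of the spec (byte-stable SVG); glyph radius is
proportional to the square root of size, fill colour maps intensity on a
fixed dark-blue-to-yellow ramp, and a degenerate intensity range renders in
a single colour. `categoryZSummary` provides the companion per-category
mean |z| table for hypothesis generation.

## Known limitations

* The 76-feature list reproduces the documented taxonomy and the six pinned
  descriptors, not a feature-by-feature identity with any external list.
* The SVM descriptor set, kernel and training labels are this package's
  choices; on real images the classifier must be retrained on curated
  labels.
* Stepwise entry/removal thresholds (0.05/0.10) are explicit, configurable
  stand-ins; with 76 candidate features and liberal thresholds, null models
  can select noise features — cross-validated AUC, not training fit, is the
  honest performance measure (and is what the null-calibration benchmark
  checks).
* Generative defaults are plausible, not fitted to any real strain;
  absolute feature values are not comparable to any particular dataset.
* No statistical testing of cluster assignments and no bootstrap support
  values; the dendrogram is descriptive.

## A small worked example

```{r example, eval = FALSE}
wt <- simulatePopulationProfiles(populationSpec("wild type", 100, seed = 1))
mut <- simulatePopulationProfiles(populationSpec(
  "mutantA", 100, effects = plantedEffect("intensity", var_mult = 0.4),
  seed = 2))
both <- qcFilter(combineProfiles(wt, mut))

fit <- fitSWLR(both, "mutantA", "wild type")
fit
crossValidate(both, "mutantA", "wild type", k = 5, seed = 1)
sensitivitySpecificity(fit, both)
```

The fitted model typically selects intensity-variability features first
(the planted effect reduces within-animal intensity CV), and scores each
animal with the probability of exhibiting the mutant phenotype — the
animal's position along this mutant's phenotypic dimension.
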