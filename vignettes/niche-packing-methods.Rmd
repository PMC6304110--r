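---
title: "Methods: morphospace packing and isotopic niche metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphospace packing and isotopic niche metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichepack)
```

This vignette documents the models behind `nichepack`, the choices made
where the procedure was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real field data.

## The question

When one community holds more species than another, the extra richness can
be accommodated in two ways: species can *pack* more tightly into the same
functional space, or the community can occupy a *larger* space. The
package measures both sides on two complementary spaces — an
ecomorphological trait space and the bivariate stable-isotope plane — for
two communities sampled at species level.

## Morphospace construction

**Analysis unit.** Specimens are averaged to species means per site before
any modelling (`aggregate_to_species()`), because packing metrics are
inter-specific. A `residual_level = "specimen"` option instead regresses
at specimen level and averages the residuals; the default matches the
species-count framing of the metrics.

**Size correction.** Each of the ten linear measurements (four external,
six craniodental, all in mm) is regressed on body mass by OLS,
`trait = a + b·mass`, and the residuals are retained. Mass is the
predictor only, never a response. The regression is linear on the raw
scale by default (a `log_transform` flag applies log10 to traits and mass
for users who prefer classical allometry); residuals are exactly
mean-zero and mass-orthogonal, which the unit tests assert to 1e-9.
Missing measurement cells are excluded pairwise from each trait's fit; a
species missing any trait after aggregation cannot enter the PCA and is
dropped with a named warning. Each fit requires at least three complete
species and non-degenerate mass variance.

**PCA.** The morphospace is the eigendecomposition of the *covariance*
matrix of residuals — all residuals share mm units, so rescaling to a
correlation matrix would discard real magnitude differences
(`use_correlation` switches this). PCA is run per community by default,
reproducing the per-community procedure; hull areas from separate PCAs
live in different coordinate frames and are not strictly commensurable,
so a `joint_pca` option builds one shared space when comparable areas are
wanted. Signs of components are fixed deterministically (the
largest-magnitude loading of each component is made positive) so repeated
runs are bit-identical. Rank-deficient inputs succeed with zero-variance
trailing components and a warning.

**Packing metrics.** Nearest-neighbour and centroid distances are
Euclidean in the full retained component space (default k = 10, i.e. all
of it — the full-space distances equal the residual-space distances up to
rotation). The minimum convex polygon area is computed on the first two
components only, via convex hull plus the shoelace formula; fewer than
three distinct or collinear points give area 0 with a `degenerate` flag.
Nearest-neighbour summaries are mean ± s.d. (n−1); centroid distance is
summarized by mean and median (the median is what the rarefied bootstrap
reports).

## Between-community inference

**Rank-sum test.** Per-species nearest-neighbour and centroid distance
vectors are compared across communities with a two-sided
Wilcoxon/Mann–Whitney test: exact enumeration when the pooled sample is
at most 20 and tie-free, otherwise the normal approximation with
mid-ranks, tie correction and continuity correction.

**Rarefied bootstrap.** Unequal richness inflates hulls and deflates
nearest-neighbour distances, so communities are compared at equal
richness: in each of B = 500 replicates, k = 22 species are drawn from
each community *without replacement* (rarefaction semantics — with
replacement, duplicated species produce spurious zero nearest-neighbour
distances; a `replace` flag restores the classical bootstrap), the
statistic is recomputed within the subsample, and the two per-species
vectors are tested by rank-sum. Because the replicates multiply tests, no
single adjusted p-value is reported; the p-value distribution is
summarized by its median and the proportion of replicates at or below
0.05. Each community's replicate stream is derived deterministically from
the master seed and the community label, which makes results independent
of argument order and bit-reproducible.

Two properties of this design deserve note. First, when the per-replicate
test compares subsample *vectors* (our default; comparing only medians
would discard within-replicate information), overlap between the two
subsamples makes the null conservative when the parent community is not
much larger than k — the calibration test therefore uses a parent of 200
species for k = 22, where replicates are nearly independent and the
proportion of p ≤ 0.05 sits at its nominal 0.05 within binomial error.
Second, with k equal to the community richness the "subsample" is the
whole community and the replicate median equals the observed one exactly,
a degenerate case the tests pin down.

## Isotopic niche metrics

Species-mean (δ13C, δ15N) points, with 1‰ of either isotope treated as
the same distance (the standard convention; the axes are plotted
isometrically in this literature). The six Layman metrics are NR and CR
(axis-aligned ranges), CD (mean — not median, deliberately differing from
the morphospace stage's median centroid summary), MNND and SDNND
(nearest-neighbour mean and s.d.), and TA (convex hull area, reusing the
same hull kernel as the morphospace). Degenerate sizes are flagged rather
than erroring: MNND/SDNND need two species, TA three.

The standard ellipse has semi-axes √λ₁, √λ₂ from the sample covariance
(n−1), so SEA = π√(λ₁λ₂) and SEAc = SEA·(n−1)/(n−2) corrects small-sample
bias; n < 3 is an error and a zero-variance axis yields SEA = 0 with a
degenerate flag. Per-foraging-group metrics use a minimum group richness
(default 3) below which ellipses are flagged `insufficient_n` instead of
reported — with two points an ellipse is a line segment.

**Bayesian SEA.** The covariance posterior uses a conjugate
normal–inverse-Wishart prior chosen vague but proper: prior mean set to
the sample mean, κ₀ = 1e−3, ν₀ = 3 (dimension + 1, the smallest proper
value), scale 1e−3·I. Conjugacy makes the posterior inverse-Wishart and
sampling direct — no MCMC, no convergence diagnostics, exact
reproducibility from a seed. Each covariance draw maps to
SEA = π√det(Σ). The posterior is summarized by the mode of a
Freedman–Diaconis histogram of draws and central quantile intervals at
50/75/95%, the nested-boxes convention of isotope niche density plots.
At large n the posterior concentrates at the SEAc scale (tested: the
posterior median is within 5% of SEAc at n = 500), which is the only
defensible calibration given that prior details vary across
implementations in this literature.

**Trophic span.** NR/TEF with TEF = 3.4‰ per trophic level by default;
the continuous value is returned and its interpretation (e.g. "at least
two levels") is left to the caller.

## The synthetic generator

`generate_morpho_community()` draws species body masses log-normally per
foraging group (bat masses span roughly 3 g to above 200 g; a normal
model would produce negative masses), builds species trait means as
`intercept + slope·mass + group offset + N(0, resid_sd)`, and adds
specimen-level mass jitter and measurement noise *proportional to the
species-level scatter* — so a zero residual s.d. collapses the entire
hierarchy onto the allometric line exactly, which the tests exploit.
`generate_isotope_community()` draws species means from per-group
bivariate normals and specimens around them with a scaled-down copy of
the group covariance.

The bundled fixture (`synthetic_communities()`, fixed seed, also
committed as CSV under `inst/extdata/` at realistic measurement
precision) mirrors the richness structure of the motivating field study:
48 vs 23 morphometric and 39 vs 17 isotope species, a single savannah
fruitbat species, forest isotope parameters spanning roughly twice the
savannah δ13C range with similar δ15N ranges, and a tighter species-level
trait scatter in the forest so the richer community packs more densely in
morphospace. All values are openly synthetic: the fixture reproduces the
*qualitative* contrasts (forest hull larger, forest packing tighter,
CR roughly doubled) and no attempt is made to match any published
numbers.

What passing on synthetic data shows — and does not. The generator
matches the analysis model by construction (linear allometry, Gaussian
group ellipses, exchangeable species). Real communities add phylogenetic
non-independence, non-Gaussian and skewed isotope distributions,
detection and sampling bias, and intra-species structure the generator
omits; passing tests demonstrate the estimators are correct under the
stated model, not that the model is adequate for any particular field
dataset.

## Numerical and scale choices

* Problem sizes in the test suite (subsample enumeration at n ≤ 5,
  brute-force geometry at ≤ 12 points, consistency at n = 400–500,
  bootstrap calibration at B = 2000) were chosen as the smallest sizes at
  which each property is sharp; the full suite runs in under a minute.
* Stochastic recovery tests state their tolerance in sampling-theory
  terms: the s.d. of log SEA-hat is ≈ √(trigamma((n−1)/2) +
  trigamma((n−2)/2))/2, so a 15% margin is a >3σ bound at n = 400 (at
  n = 50 it would be ~1σ and the check would fail on a third of honest
  draws).
* The insectivores-only variant refits the regression and PCA on the
  subset, as the per-variant procedure dictates; consequently the hull
  subset property (insectivore MCP ≤ all-bats MCP) is guaranteed only in
  a fixed coordinate frame, where the tests assert it exactly.
* Report CSVs and JSON serialize at full precision with no timestamps, so
  fixed-seed runs are byte-identical.
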