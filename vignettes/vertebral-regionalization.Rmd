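---
title: "Quantifying vertebral regionalization: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertebral regionalization: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertregions)
```

## The problem

A vertebral column is a serially homologous structure: every vertebra
carries the same set of anatomical elements, varying gradually along the
cranio-caudal axis. A *region* is a stretch of vertebrae sharing one linear
gradient per morphometric axis; a *breakpoint* is where the gradient's
slope changes. In strongly modified axial skeletons — secondarily aquatic
mammals are the canonical case — regional boundaries are not visible to the
eye, vertebral counts vary enormously across species (33 to 90
post-cervical vertebrae in our target data structure), and the questions
become statistical: how many regions does a column support, where are the
breaks, which regions are homologous across species, and do these
quantities covary with ecology?

`vertregions` answers these with four connected analyses: segmented-
regression region fitting with information-criterion model averaging,
spectral-clustering module homology, serial disparity, and phylogenetic
comparative statistics, plus a synthetic-data generator that plants known
truth through every stage.

## Measurement cleaning

Each vertebra carries 14 linear and 2 angular measurements (the default
schema names centrum height `Hc`, centrum width `Wc`, metapophysis height
`Hm`, and the neural-spine and transverse-process inclinations `Inp` and
`Itp`; the other eleven linear slots are placeholders the user can rename —
downstream computation depends only on the count and the linear/angular
kind). Serial structures gain and lose elements along the column, and the
cleaning rules avoid fabricating morphological jumps:

* linear measurements of a naturally **absent** apophysis are zero — except
  metapophysis height on a run of lumbar vertebrae flanked by
  metapophysis-bearing neighbours, which takes the mean of the flanking
  values (lumbar metapophyses are normally well developed, so zero would be
  an artefact);
* angular measurements are never zeroed (a present apophysis always has a
  positive inclination): terminal runs copy the nearest bearing vertebra,
  interior runs take the mean of the two flanking bearing vertebrae;
* **broken** measurements are imputed as the mean of the nearest non-broken
  value on each side (a single-sided copy at the column ends). Absence
  rules run first so neighbour values are always defined; both passes are
  idempotent and statuses are preserved for audit.

Measurements are then z-transformed per specimen with the sample (n − 1)
standard deviation. Segments follow the flags: thoracic = rib-bearing,
caudal = chevron-bearing plus the terminal fluke vertebrae, lumbar = the
remainder; precaudal = thoracic + lumbar.

## Ordination

Each specimen's scaled measurements are converted to Gower dissimilarities
(range-normalized mean absolute difference; variables with zero range
contribute zero but stay in the denominator) and ordinated by classical
principal coordinates analysis. Negative eigenvalues, which a Gower matrix
can produce, are dropped, and variance fractions are computed over the
positive eigenvalues only — the standard PCO practice. Eigenvector signs
are fixed deterministically so repeated runs are bit-comparable. Axes with
more than 5% of the variance (typically two or three) enter the segmented
regressions; axis 1 is always retained so a fit is never empty.

The *common morphospace* pools every vertebra of every specimen into one
Gower + PCO ordination, with provenance kept per row; its first three axes
are the coordinates for module homology and serial disparity.

## Region fitting

For breakpoints $t_1 < \dots < t_{r-1}$ (a breakpoint value $t$ means "the
region ends at vertebra $t$"), each retained axis is regressed on the
continuous linear-spline basis $\{1, x, (x - t_j)_+\}$. Successive segments
are forced to be continuous: serial variation is gradational, and
continuity is what lets a slope change — rather than a level jump — define
a boundary. The spline knot sits at the breakpoint vertebra itself, so a
slope change occurring exactly at a vertebra is representable and noiseless
kinked data are fitted exactly; region membership for the minimum-segment
rule still assigns vertebra $t$ to the region it ends.

Models are scored by
$$\mathrm{BIC} = n \ln(s/n) + k \ln(n), \qquad k = rp + p + r - 1,$$
with $n$ = observations × axes and $s$ the total residual sum of squares
across axes. The parameters counted are one slope per region per axis, the
first-segment intercept per axis, and one position per breakpoint — which
is also why candidate breakpoints are integer vertebral positions. When a
fit is exact, $s$ is floored at $10^{-12} n$ and the model flagged
saturated, so the BIC stays finite.

Region counts from 1 to 11 are compared through BIC weights
$w_i \propto e^{-\Delta\mathrm{BIC}_i/2}$; the optimum is the highest
weight, and the **region score** $RS = \sum_i i\, w_i$ carries the model
uncertainty as a continuous regionalization level (weights 0.4 at seven
and 0.6 at eight regions give $RS = 7.6$).

**Search.** Admissible breakpoint configurations keep at least three
observations per region. Their number has the closed form
$\binom{n - 3r + r - 1}{r - 1}$; the search enumerates exhaustively
whenever this count is at most 50,000 (which covers every region count at
the fixed 33-vertebra stage, at most 18,564 configurations at $r = 7$) and
otherwise switches to a seeded heuristic: starting configurations extend
the best model with one fewer region by each admissible extra breakpoint,
plus random draws; coordinate-wise 1-D scans run to convergence from the
best ten starts, followed by "kick" restarts that re-randomize one
breakpoint of the incumbent at a time. All evaluated models are archived.
On every instance small enough to verify (20 observations, up to four
regions), the heuristic attains the exhaustive optimum — this is asserted
in the test suite.

**Two-stage protocol.** Because the recovered region number grows with the
number of observations offered to the model, the region count is first
chosen on 33 equidistant vertebrae (positions on the rounded arithmetic
progression, ends included; the per-specimen PCO and its >5% axis rule are
applied to those 33 vertebrae). Breakpoint *positions* are then estimated
on the full column — with the PCO recomputed on all vertebrae, so the
retained axis count may differ between stages; both are recorded — keeping
only models with the predefined optimal region count. Each breakpoint is
summarized by its weighted mean and weighted standard deviation across the
top 5% of archived models by residual sum of squares (at least one model;
"top 5%" is a ceiling). Weights are likelihood-proportional,
$w \propto e^{-\frac{n}{2}\ln(s/n)}$, renormalized within the retained set.

**Species aggregation.** The mean BIC-weight vector across a species'
specimens (renormalized defensively) chooses the species-level region
count, which is then imposed on every specimen's stage-2 fit; specimens
preferring a different count are reported with a warning. Breakpoints
combine across specimens by the law of total variance (mean within-specimen
variance plus the population variance of specimen means). A region spanning
the precaudal/caudal boundary contributes the fraction of its vertebrae
falling in each segment — two complete precaudal regions plus five eighths
of an eight-vertebra spanning region give 2.625 precaudal regions — and the
per-segment counts average across specimens.

## Module homology

Regions are species-specific; *modules* are the cross-species homology
units. All vertebrae of all specimens are clustered in the common
morphospace (axes 1–3) by spectral clustering: a self-tuning Gaussian
affinity with local scales at the 7th neighbour (robust to unequal cluster
densities), the normalized Laplacian, the cluster number chosen by the
largest eigengap within 2–15, and k-means on the row-normalized leading
eigenvectors with a deterministic farthest-point initialization. Serial
coherence is then enforced per specimen: isolated single-vertebra label
runs are absorbed into the flanking module with the longer adjacent run
(ties anterior). Modules present in at least half of a species' specimens
are retained; boundaries (the last vertebra of the anterior module) are
averaged across specimens on the relative scale — specimens of one species
may differ in count — and rescaled to the species' retained count. Each
fitted region maps to the module holding the majority of its vertebrae
(ties anterior, with a warning). Module boundaries can be compared to
anatomical landmarks: the double- to single-headed rib transition, the last
rib, the first chevron, and the centrum height/width ratio profile that
separates laterally compressed peduncle vertebrae (ratio > 1) from
dorso-ventrally flattened fluke vertebrae (ratio < 1).

## Serial disparity

Disparity is the mean Euclidean distance between successive vertebrae on
common-morphospace axes 1–3 — exactly three axes, even when more pass the
5% rule, keeping the measure comparable across analyses. Segment means use
only pairs whose two vertebrae share a segment; the single pair straddling
the precaudal/caudal boundary enters the whole-column mean only, keeping
segment means pure. Species values average specimens.

## Comparative statistics

All regressions are generalized least squares with residual covariance
proportional to the lambda-scaled Brownian correlation of a time-calibrated
phylogeny (off-diagonal elements multiplied by $\lambda \in [0,1]$).
Lambda is estimated by maximum likelihood — a 21-point grid with
golden-section refinement between the bracketing grid points, ties toward
the smaller lambda — chosen over REML as a single reproducible criterion.
At $\lambda = 0$ the fit equals ordinary least squares, which the tests
assert to $10^{-8}$. Goodness of fit is the predictive partial $R^2$: one
minus the ratio of summed squared phylogeny-aware prediction errors (each
tip predicted from its expectation plus the covariance-weighted residuals
of all other tips) of the full model over the intercept-only phylogenetic
null, following Ives (2018, Syst. Biol. 67:509–517). Phylogenetic ANOVA
uses the generalized extra-sum-of-squares F test with lambda estimated
under the full model and held fixed for the null, so both residual sums of
squares live under the same covariance. Ancestral states under Brownian
motion are the closed-form GLS conditional expectations (an independent
implementation is cross-checked against ML ancestral states from
`phytools` in the tests). Trees are pruned to the analysis taxa with
branch-length-preserving tip removal; species with missing speed data are
dropped per analysis, never imputed. Swimming speeds are divided by body
size (total length) before analysis.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its design choices matter and are stated here.

**Latent gradient structure.** Vertebral measurements covary strongly, so
the planted signal lives in a few latent cranio-caudal profiles, each
piecewise-linear with the same breakpoints, mixed into the 16 measurements
and then carrying noise. Three properties were chosen to mirror real
morphometric suites, and each has a measurable consequence for the
ordination the fitter sees:

* *A monotone dominant gradient.* The first latent's slope never changes
  sign; it alternates between a low and a high band at each breakpoint.
  Overall vertebral size and process development change their rate, not
  their direction, along real columns — and when every measurement is
  monotone, range-normalized L1 dissimilarities are additive along the
  column, so the ordination embeds the column without distortion.
* *Decorrelated minor latents.* Randomly drawn piecewise profiles share
  low-frequency trends and are strongly correlated; the generator projects
  each minor profile off the earlier latents (linear combinations keep the
  same knots) and redraws any profile whose independent part is less than
  half its size — rescaling a near-collinear residual would plant steep
  slopes the truth record does not own. The planted gradients then occupy
  distinct morphospace axes with controlled amplitudes, as real
  morphospaces do.
* *Evenly spread loadings.* Measurement suites are designed to cover
  distinct aspects of shape; loadings are a randomly rotated
  Fibonacci-sphere set of directions, which keeps the pooled dissimilarity
  close to isotropic in the latent space.

**Noise.** Noise is Gaussian at two levels: a serial deviation of each
latent profile, independent per vertebra and per latent (anatomical
irregularity that ordination cannot average away), and independent
per-measurement noise (measurement error, which the 16-variable Gower mean
largely averages out). The effect of each planted breakpoint is
parameterized as the *deflection* its slope change accumulates over one
mean region length, in noise-SD units; the default effect size is 8, twice
the detectability floor of about 4 below which the information criterion
can no longer separate adjacent region counts reliably at 33 observations.
Default planted breakpoints are evenly spaced and then snapped to the
33-vertebra subsample grid, so the planted region count is representable at
the resolution of the region-number search — a breakpoint falling between
two candidate knots leaves a kink no model of the true size can absorb.

**What passing recovery tests do and do not show.** The generator produces
columns whose ordination axes are close to piecewise-linear with additive
noise — the regime the segmented-regression model assumes. Real columns
add features the generator deliberately omits: non-monotone dominant
gradients in aberrant taxa, heteroscedastic measurement error, missing
data beyond the absence/breakage rules, and ordination curvature from
strongly folded morphospace paths. Recovery rates measured here are
therefore an upper bound on what identical settings would achieve on real
data, and the known failure modes are one region too many (fitting
residual ordination curvature, typically near the column ends) or one too
few (merging a gently contrasting terminal region).

**The comparative layer** plants a complete study: a unit-depth Yule tree;
habitat frequencies 7:11:8:36 (rivers-bays, coastal, mixed, offshore)
matching the imbalance of the target dataset; vertebral counts drawn from
habitat-specific windows within 33–90 (riverine species low); region score
rising linearly with count (6 to 9 across the count range) with
Brownian-motion deviations of known lambda; disparity falling linearly
with count; and size-corrected burst speed following a planted linear
model on region score, with sustained speed unrelated. Availability of
speed data mirrors the 34/62 sustained and 26/62 burst pattern. Specimen
columns (1–3 per species, equal counts within a species so planted
breakpoints are shared) carry the species' planted region structure.

## Numerical choices and degenerate inputs

* Exact fits floor $s$ at $10^{-12} n$ and flag the model saturated.
* Constant measurement variables z-score to zero with a warning; constant
  responses in PGLS are flagged degenerate with zero slopes.
* Eigenvector signs in PCO and spectral embeddings are fixed by making the
  largest-magnitude loading positive.
* Ties break anterior throughout (module smoothing, majority mapping) and
  toward smaller lambda in the PGLS grid, for determinism.
* All stochastic steps (heuristic search, clustering, simulation) take
  explicit integer seeds and restore the caller's RNG state.

## Problem sizes used in the validation suite

The packaged tests run at deliberately modest sizes chosen to exercise
every code path at interactive speed: recovery experiments use 20
replicate species, each with two specimens drawn from a planted
40-vertebra blueprint, with the region number selected from the mean BIC
weights across specimens — the protocol's unit of inference; the oracle
suite uses instances of up
to 20 observations and four regions where exhaustive enumeration is exact;
PGLS recovery uses 50 replicates on a 100-tip tree; the end-to-end
pipeline check runs a scaled-down synthetic study. The pipeline itself
handles full-size inputs (tens of specimens, up to 90 vertebrae, a pooled
morphospace of thousands of vertebrae) through the same functions.

## Known limitations

* The heuristic search is exact on all verified small instances but
  carries no global guarantee at full-column sizes; the archived model set
  it returns is only a subset of the model space, so top-5% breakpoint
  uncertainties under the heuristic are conditional on the archive.
* Gower-PCO ordination of strongly non-monotone columns bends gradients
  (the classic horseshoe), which the segmented model reads as extra
  regions; this is a property of the method, not of an implementation.
* Lambda is bounded to [0, 1]; values above 1, which some empirical
  datasets prefer, are truncated.
* No Cailliez/Lingoes correction for negative eigenvalues; no AICc
  selection; region counts beyond 11 are out of scope.
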