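---
title: "Delimiting skeletal morphotypes from incomplete measurement tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting skeletal morphotypes from incomplete measurement tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aepymorph)
```

## The problem

Museum collections of extinct taxa preserve far more broken bones than intact
ones. For the elephant birds (Aepyornithidae) of Madagascar — femora,
tibiotarsi and tarsometatarsi measured with fixed series of 20, 21 and 44
linear measurements — only about a quarter of available adult specimens are
complete. Multivariate taxonomy nevertheless needs complete data frames, and
discarding broken specimens risks discarding exactly the rare morphotypes a
revision is meant to find. `aepymorph` implements the full analysis chain
that resolves this tension: impute what is missing, cluster what results,
name the clusters by nomenclatural priority, and translate femoral
circumference into body mass.

## The model and its stages

**Scaling.** Every measurement column is centred and scaled to unit variance
using observed cells only. Without this, overall size (total lengths in the
hundreds of mm against widths in the tens) dominates every downstream
distance.

**Imputation by iterative PCA.** Missing cells start at the column means
(zero in scaled space). The matrix is then alternately approximated by a
rank-`ncp` truncated SVD and re-completed with the fitted values — observed
cells are restored after every pass — until imputed cells move less than
`tol` (default `1e-6` in scaled units, capped at 500 iterations; hitting the
cap flags the result rather than failing). This is an EM algorithm for a
fixed-rank signal-plus-noise model. The default `"regularized"` mode shrinks
each retained singular value by `(d^2 - sigma2)/d^2`, with `sigma2` the mean
of the discarded eigenvalues, pulling the reconstruction toward the column
means when a component is weak; this curbs the overfitting EM is prone to
when much data are missing. The rank is chosen by fivefold cross-validation:
observed cells are randomly partitioned, each fold is masked and re-imputed
at every candidate rank, and the rank minimizing the mean squared error of
prediction wins (ties to the smaller rank). Candidate ranks default to
`1:min(8, p - 2, n - 2)`. CV-internal imputations run at a looser tolerance
(`1e-4`, 100 iterations) since they only rank candidates.

**PCA and mixture clustering.** The completed matrix is re-scaled and
decomposed by centred SVD (deterministic sign: the largest-magnitude loading
of each component is positive). Clusters are sought with finite Gaussian
mixtures fitted by EM under six covariance families — spherical, diagonal or
ellipsoidal shape, with equal or varying volume (EII, VII, EEI, VVI, EEE,
VVV) — and compared by BIC in the form `2*loglik - n_params*log(n)`
(maximized). A clustering is *stable* when its BIC exceeds the best model at
any other number of clusters by more than 2. Principal components enter the
model one at a time; the first count at which a stable multi-cluster pattern
appears is kept (a stable single-component fit is no pattern, so stepping
continues past it). EM is initialized from a Ward tree cut at K. Two
numerical details matter here:

* the Ward tree is built on *standardized* scores. Plain Euclidean Ward is
  dominated by the first component's scale, and a single EM start from such a
  tree cannot recover clusters separated only along a lower-variance axis;
  standardizing the init (EM itself runs on raw scores) makes the start
  scale-adaptive, matching the behaviour of the field's reference
  implementation, which we reproduce to four decimals of log-likelihood on
  shared fits.
* a single hierarchical start is the default (`n_restarts = 1`). Extra random
  restarts occasionally locate higher-likelihood optima at large K that tip
  BIC toward spurious splits; the single-start behaviour matches standard
  model-based clustering practice. Restarts remain available, and EM runs
  that empty a component are automatically retried from perturbed starts.

Specimens are assigned by maximum posterior responsibility; classification
uncertainty is one minus that maximum, and specimens at or above 0.05 are
excluded from taxonomic output. Components are relabelled in increasing order
of mean first-component score, so cluster 1 is always the smallest
morphotype.

**Two rounds.** Round 1 uses only specimens missing strictly less than 25%
of their element's measurements (a specimen at exactly 25% waits for round
2). After unsupervised selection, elements whose stable K falls below the
maximum K found across elements in the same run are re-fitted supervised at
that maximum — the re-fit sees at least the first two principal components,
because the substructure it hunts for is by construction invisible on the
primary size axis. Round 2 re-imputes and re-clusters *every* specimen
(broken ones beyond the gate, round-1 uncertainty exclusions, type specimens,
localized specimens) at the K and dimensionality fixed by round 1; scaling
parameters are recomputed for the round-2 matrix and recorded in the run
report. Round-2 labels for heavily incomplete specimens are delivered with
their uncertainty so users can subset; both rounds are tagged apart in every
output.

**Naming clusters.** Each cluster is named by the senior available species
name among its *well-predicted* type-specimen members: smallest publication
year, ties broken by month (an unknown month sorts after any known month of
the same year), then alphabetically for determinism. Types placed by
published measurements rather than clustering enter through discrete
diagnostic intervals — per-cluster min–max intervals of a single measurement
— and compete for seniority on equal terms. Interval assignment is refused
for codes not flagged discrete; queries in gaps return `"unassigned"` and
queries touching two intervals return `"ambiguous"`. The shipped femoral
circumference interval set is flagged discrete explicitly: its two largest
intervals touch (253–254 mm), but the set separates the small-bodied range
where the published placements use it.

**Mass.** Body mass follows the Campbell–Marcus regression
`log10(M_g) = 2.411 * log10(LCF_mm) - 0.065` on femoral least-shaft
circumference (code F3). The formula returns grams; summaries are in kg,
rounded only at presentation. Per-cluster summaries use observed — never
imputed — circumferences; a single-specimen cluster reports sd 0 flagged by
n = 1.

**ANOVA diagnostics.** Per measurement, a one-way ANOVA across cluster labels
on observed values only, Bonferroni-corrected with denominator equal to the
number of measurements actually tested for that element. Published analyses
of this kind print slightly different corrected thresholds (0.0026 for
femora, 0.001 and 0.0012 for tarsometatarsi) whose family sizes are not
derivable from the measurement counts alone; we report our own denominator
alongside rather than reverse-engineering theirs.

## What the synthetic generator emulates — and what it does not

The generator draws each specimen as its cluster's mean profile plus a
per-specimen latent size factor times per-measurement loadings plus
independent residual noise, truncated positive by resampling (clipping would
pile mass at zero). Defaults are calibrated to the published per-taxon
range tables: cluster profiles are range midpoints (gaps filled by a linear
fit across the four-taxon size series; the one code missing everywhere is
averaged from its neighbours and marked synthetic); the total within-cluster
sd is a quarter of the printed range width, putting ±2 sd at the printed
extremes. That total is split 70% onto the shared size factor and 30%
residual, which reproduces the strongly size-dominated correlation structure
of real aepyornithid measurements (first principal component above 85% of
variance, as in the real analyses). Tibiotarsal ranges are single
type-specimen values, so those sds fall back to 6% of the mean, the typical
width/4-to-midpoint ratio of the other elements.

Breakage missingness is anatomically structured: a broken specimen loses one
whole region (proximal end, distal end, or shaft) *plus* every whole-bone
length measurement. Region blocks are defined from the measurement scheme's
anatomy. The defaults (18 specimens per cluster, 15% breakage) are the
conditions under which the package's validation studies run.

The femoral study plants a species-level subcluster: the middle of three
primary groups is generated as two subgroups offset by ±1 within-cluster sd
per code with alternating sign. The alternating pattern makes the offset a
*shape* contrast, nearly orthogonal to the all-positive size direction: the
primary axis still shows three groups (unsupervised selection stabilizes at
K = 3), while the contrast owns the second component, where a supervised
4-component fit separates the subgroups. Weaker offsets (0.25–0.5 sd) scatter
across later components and are unrecoverable even supervised; a pure size
offset large enough to split reliably also breaks the 3-group primary
structure. The chosen construction is the regime the published femoral
analysis describes: substructure invisible to unsupervised BIC yet recovered
at a fixed higher K.

The generator does not simulate sexual dimorphism, temporal size drift,
spatial autocorrelation, measurement error correlated with size, or
non-Gaussian within-taxon variation. Passing the package's recovery studies
therefore shows the pipeline is correct under its own model, not that real
aepyornithid data satisfy that model.

## Numerical choices and degenerate inputs

* Covariances whose condition number exceeds `1e10` (or that lose positive
  definiteness) receive a ridge of `1e-6` times their mean diagonal.
* BIC ties in model selection go to the smaller K, then the family with
  fewer parameters.
* Measurement columns observed fewer than twice, or with zero observed
  variance, are rejected before imputation (the pipeline drops them with a
  record in the run report; calling the imputer directly errors, naming the
  code).
* CV fold assignments that would empty a column's observed set are resampled
  (bounded at 100 attempts).
* Rows with no observed measurement are rejected at read time; observed
  values must be strictly positive.
* All randomness flows from explicit integer seeds; generation and analysis
  are bit-reproducible given the seed.

## Problem sizes

The validation studies use 72 specimens per element (4 × 18, or 4 × 18 with
the femoral middle group split 18/18), 20 seeded replicates per study, and
model grids K = 1…6 over six families with up to 4 principal components.
These sizes resolve the cluster structure the studies plant while keeping a
full replicate around three seconds; larger grids change nothing about the
method and can be requested through `pipeline_config()`.

## Known limitations

* The stepped rule stops at the first stable multi-cluster pattern; with a
  single EM start, BIC occasionally prefers an extra split of a
  large-variance group (1 of 20 tarsometatarsal replicates; such cases were
  cross-checked against the reference implementation and reflect genuinely
  higher-likelihood optima, not fitting errors).
* Single imputation only: the completed matrix carries no imputation
  variance, so downstream uncertainties are conditional on the imputed
  values (the published method makes the same choice).
* Genus-level nomenclature (availability of genus names, designation of new
  genera) is reported as metadata only; the resolver implements species-level
  seniority.
* Tibiotarsal defaults rest on single type specimens rather than ranges and
  are correspondingly cruder.
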