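---
title: "Ensemble SDM methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDM methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdm)
```

`ensdm` implements the skill-gated, weighted-average ensemble protocol that
has become standard for mapping habitat suitability of poorly surveyed
species from presence-only records, together with the range-change
accounting used to express how a projected (e.g. future-climate) suitability
surface differs from the current one. This vignette is the package's own
account of the underlying models, the defaults, and the choices made where
the protocol leaves room.

## The modelling problem

The data are presence-only occurrence records of a species and a stack of
co-registered environmental raster layers on a regular longitude/latitude
grid. Because true absences are unavailable, *pseudo-absences* (random
background cells) stand in for non-detections, and single models are fitted
to discriminate presence cells from background cells. A single learner's
output in a cell is a suitability score in $[0,1]$; it estimates a quantity
monotone in, but not equal to, the probability of presence — pseudo-absence
designs cannot identify prevalence, which is why everything downstream
(gating, weighting, binarisation) works with rank- and threshold-based
statistics.

The pipeline is:

1. **Thinning** — at most one record per analysis cell, first record in
   input order kept. This removes the weight that duplicated or clustered
   opportunistic sightings would otherwise carry. Thinning is idempotent
   and the thinning grid is the analysis grid itself (10 arc-minute cells
   by default); we do not maintain a second, coarser thinning grid, since
   a single resolution is the only reconstructable convention and the cell
   size is configurable anyway.
2. **Predictor screening** — pairwise Pearson correlation and variance
   inflation factors, dropped to a fixed point (below).
3. **Pseudo-absence sampling** — `n = 1200` cells drawn uniformly without
   replacement from cells with complete predictor data and no presence.
   The draw is made once and shared across repetitions; redrawing per
   repetition would conflate background uncertainty with split
   uncertainty. (A per-repetition redraw can be emulated by looping over
   seeds.)
4. **Repeated splits** — 70/30 train/test, 10 repetitions. Splits are
   stratified by class even though small-sample protocols often leave this
   implicit: with ~200 presences against 1200 background cells, an
   unstratified 30% test draw can end up with too few presences to
   evaluate against.
5. **Single models** — every registered learner fitted on every training
   split and scored on its held-out rows.
6. **Gating and ensembling** — runs with held-out TSS > 0.7 *and*
   AUC > 0.8 (strict inequalities) are combined as a weighted average.
7. **Classing and change accounting** — the ensemble map is binarised at
   its TSS-maximising cutoff, the suitable range split into three
   equal-width bands, and projected ranges compared cell-wise against the
   current range.

## Native learners

Two learners are implemented natively; anything else attaches through the
learner registry (`register_learner()`) without changes to the pipeline.

**Logistic regression (GLM).** Binomial GLM with logit link, fitted by
iteratively reweighted least squares on internally standardized predictors.
Step-halving enforces a monotone non-increasing deviance trace, which the
test suite asserts. Complete or quasi-complete separation — likely with
small presence samples and a sharp niche — is detected (diverging
standardized coefficients or a singular step) and resolved by refitting
with a tiny ridge penalty ($\lambda = 10^{-6}$, intercept unpenalised), so
the returned estimate is always finite; such fits carry a `separation`
flag. Convergence is declared when the relative deviance change falls
below `1e-8` (default cap 100 iterations).

**Surface range envelope (SRE).** The classic BIOCLIM-style envelope: per
predictor, the interval between the $q$ and $1-q$ empirical quantiles of
the *presence* values (default $q = 0.025$, the central 95% envelope); a
cell is suitable only if it lies inside every interval. Its output is
inherently binary, so an SRE run can only contribute its 0/1 membership to
the ensemble; in practice its held-out TSS rarely clears the 0.7 gate and
the ensemble is GLM-dominated, which mirrors how envelope methods fare in
multi-model comparisons.

## Skill metrics and the cutoff

All metrics are computed from first principles and checked against
independent oracles (exhaustive enumeration of confusion tables; the
trapezoidal ROC integral):

* sensitivity, specificity, and **TSS** $= se + sp - 1$;
* **Cohen's kappa** $\kappa = (p_o - p_e)/(1 - p_e)$;
* **AUC** in its rank (Mann–Whitney) form, ties counted $\tfrac12$.

Thresholding is *inclusive*: a score exactly at the cutoff predicts
presence. The binarisation cutoff is chosen by sweeping candidate
thresholds at midpoints between consecutive distinct scores (plus 0 and 1)
and maximising TSS, ties resolved toward the smaller threshold — the
conventional default when no external prevalence information exists.
Fixed-value and maximum-kappa alternatives can be had by calling
`evaluate_predictions()` with an explicit cutoff.

## Predictor screening

Screening alternates two greedy rules until neither fires:

1. if any pair of remaining predictors has $|r| \ge 0.8$, drop — from the
   worst-offending pair — the member with the larger mean absolute
   correlation to everything else;
2. if any remaining predictor has VIF $\ge 10$, drop the largest.

Boundary values are dropped (strictly *less than* 0.8 / 10 is required to
stay). Running the two rules to a joint fixed point makes the result
insensitive to which rule is described "first"; the final report always
satisfies both thresholds, which is asserted on every run. The tie-break
(mean absolute correlation) is deterministic; ecological knowledge can
always override by pre-selecting columns. In the pipeline, screening runs
on all complete grid cells, i.e. on the layers themselves rather than on
values at occurrence cells, matching how candidate variable sets are
usually screened before modelling.

Variable importance is permutation-based at the ensemble level: importance
of a column is $1 - r$ between ensemble predictions on intact data and on
data with that column permuted, averaged over 5 shuffles, clipped to
$[0,1]$, and reported both raw and normalised to percentages summing
to 100. Five shuffles is enough because the statistic is a correlation over
all table rows, not a refit.

## Ensemble weighting and evaluation

Weights are proportional to each retained run's held-out skill — by
default the mean of its AUC and TSS, so that a higher average of the two
yields a larger weight; pure-AUC and pure-TSS modes are available. Scores
are shifted to be non-negative before normalising (TSS can in principle be
negative); a degenerate all-zero score vector falls back to equal weights.
Member grids are min–max normalised to $[0,1]$ *after* gating — gating
should reflect each model's own skill, untouched by rescaling — and the
ensemble cell value is the weighted mean, hence bounded by the member
envelope cell-wise.

The ensemble itself is re-scored on the full labelled table (ensemble grid
values extracted at presence and pseudo-absence cells). Held-out scores
are not available at ensemble level because members from different
repetitions have different test sets; scoring on the pooled table is the
transparent alternative and is labelled as such in the score table
(`learner = "ENSEMBLE"`).

**Projection.** When the fitted ensemble is projected onto a scenario
stack, each member model re-predicts the new stack and each member's
*current-grid* min–max affine is re-applied (clipped to $[0,1]$), rather
than re-normalising on the future grid. This keeps current and future
suitability on one scale so that a single cutoff is meaningful in both
periods; re-normalising per projection would silently re-define
"suitable" in every scenario. The current cutoff and band boundaries are
transferred unchanged, standard practice for model transfer.

## Habitat classes, areas and range change

Cells below the cutoff are unsuitable; $[cutoff, 1]$ is divided into three
*equal-width* bands (minimally/moderately/highly suitable). Equal
probability-width — not equal-area terciles — is the contracted reading of
"three equal parts"; intervals are left-closed/right-open with the top
band closed at 1, so classes partition the non-missing cells.

Cell areas use the spherical closed form
$A = R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)$ with
$R = 6371.0088$ km, which conserves the sphere's area to $10^{-6}$
relative on a full global grid. An ellipsoid would change 2-decimal
$10^4\,$km² totals negligibly relative to the modelling uncertainty, and
area *ratios* (the percentages) even less. Areas are kept at full
precision internally; half-up rounding to 2 decimals is applied only at
presentation.

Range change compares binary ranges (moderate + high by default)
cell-wise: loss (1→0), stable (1→1), gain (0→1), never (0→0). The summary
row derives future area $= stable + gain$, species range change
$\% = 100\,(gain - loss)/current$, and separate %loss and %gain — kept
separate deliberately, because a net change figure and a loss percentage
are easily conflated. The identities $stable + loss = current$ and
$stable + gain = future$ hold exactly at full precision and are asserted
in every pipeline run. Percentages are always computed from unrounded
areas, then rounded: this is what makes independently rounded published
tables reproduce to the printed 2 decimals.

## The synthetic-data generator

The generator exists so that every stage can be tested against a known
truth without external rasters. It emulates:

* **smooth, partially collinear environmental fields** — each layer is a
  random-orientation linear lon/lat gradient mixed (weight 0.5) with
  Gaussian-smoothed white noise (bandwidth 3 cells), z-scored to mean 0,
  sd 1. Standardizing removes the unit ambiguity real variable sets carry;
  it also means niche coefficients and scenario deltas are in sd units.
* **controlled collinearity** — a requested pair correlation $r$ is
  induced by empirically orthogonalising the target field against the
  source and remixing as $r\,s + \sqrt{1-r^2}\,e$, so the *realised*
  correlation equals $r$ up to floating point and the screening stage has
  a known correct answer.
* **a known logistic niche** — presence probability
  $p(x) = \operatorname{logit}^{-1}(\beta_0 + \sum_i \beta_i x_i)$. The
  default demo niche is $\beta_0 = -8$, $\beta = (7, -5)$ on two of six
  layers: a steep, spatially restricted niche occupying roughly 15–20% of
  the grid. The steepness is deliberate. With fixed publication-style
  retention gates (TSS > 0.7, AUC > 0.8), the best achievable TSS of *any*
  presence-vs-background classifier is roughly one minus the suitable
  fraction of the background; a weak, diffuse niche therefore caps every
  learner below the gates and no ensemble can legitimately form. The gates
  presuppose a discriminable specialist, so the default truth is one.
* **presence-only sampling** — a Bernoulli draw per cell with probability
  $p(x)$, subsampled (or topped up by weighted sampling without
  replacement) to the target count; coordinates are cell centres.
* **scenario stacks** — additive shifts of named layers. A uniform
  adverse shift of a niche-driving layer shrinks the suitable set
  (projected range change is negative), which the tests assert. Because
  the shift is spatially uniform and the GLM is monotone in the linear
  predictor, synthetic scenarios produce little or no *gain*; real
  scenario layers shift heterogeneously and produce both.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatial sampling bias, observation error in
coordinates, non-linear or interacting niche responses, spatial
autocorrelation beyond the smoothing bandwidth, missing-data structure in
predictors, and prevalence identification. Results on synthetic data
demonstrate that the machinery is correct, not that any particular real
species is well modelled.

## Problem sizes and numerical choices

The bundled demo and the test suite run on a 60×60-cell grid (10
arc-minutes, so roughly a 10°×10° window) with 6 layers, 200 presences,
1200 pseudo-absences and 10 split repetitions — large enough that
parameter recovery is stable (truth-map correlation typically 0.85–0.97
across seeds) and small enough that a full pipeline run takes a couple of
seconds, so properties can be asserted across many seeds.

Numerical conventions collected in one place: IRLS tolerance `1e-8` on the
relative deviance change with step-halving; ridge `1e-6` only under
detected separation; envelope quantiles use the default empirical quantile
definition (type 7); min–max normalisation maps a constant grid to 0.5
with a warning; threshold comparisons are inclusive (`>=`); gating
inequalities are strict (`>`); class intervals are left-closed/right-open,
top-closed; ties in the cutoff sweep resolve to the smallest threshold;
all stage seeds derive deterministically from the single configured seed,
and identical configurations reproduce byte-identical output tables.

## Known limitations

* Only GLM and SRE ship natively; the registry contract is how GBM, RF,
  MARS, CTA, ANN, FDA or Maxent implementations would attach, and
  hyperparameter tuning is out of scope.
* Pseudo-absences are sampled uniformly over the complete-data extent;
  target-group or environmentally stratified background designs are not
  provided.
* Evaluation is random-split only; spatially blocked cross-validation —
  preferable under strong spatial autocorrelation — is not implemented.
* Raster I/O is plain-text ESRI ASCII grids plus a JSON manifest, chosen
  for portability and inspectability; very large grids would want a
  binary-format backend.
* The ensemble's own scores are computed on the pooled labelled table
  (see above) and are therefore optimistic relative to held-out member
  scores; compare like with like when reading the score table.
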