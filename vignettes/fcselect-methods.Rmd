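---
title: "Sparse functional-connectivity biomarkers: models and methods"
author: "fcselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse functional-connectivity biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcselect)
```

## The problem

Resting-state functional connectivity (FC) — the Pearson correlation between
the spontaneous BOLD time courses of two brain regions — is a candidate
biomarker substrate for psychiatric diagnoses. With a whole-brain parcellation
of $R = 140$ regions there are $R(R-1)/2 = 9{,}730$ region pairs per subject,
while realistic multi-site cohorts contain only a couple of hundred subjects.
Two failure modes dominate naive classifiers built on such data: overfitting
($p \gg N$), and nuisance-variable (NV) contamination — connections that track
scanner site, age, sex, eye condition, or medication rather than the
diagnosis, which destroy generalization to data from new sites.

`fcselect` implements a two-stage sparse pipeline against both failure modes:

1. **L1-regularized sparse canonical correlation analysis (L1-SCCA)** between
   a 10-column attribute block $X_1$ (diagnosis, three one-hot site flags,
   age, sex, eye condition, three medication flags) and the FC block $X_2$,
   with a *diagnostic canonical constraint* that keeps only canonical
   variables whose attribute-side loading is confined to the diagnosis
   column;
2. **sparse logistic regression (SLR)** with automatic relevance
   determination, which classifies from the selected subspace while pruning
   all but a handful of connections to exactly zero.

Selection and classification are wrapped in a $9 \times 9$ nested
feature-selection + leave-one-out cross-validation (LOOCV) protocol in which
the held-out subject never influences standardization, selection, or
training for its own prediction.

## Connectivity preprocessing

`fc_pipeline()` fixes the stage order: zero-phase band-pass filtering of the
full series, nuisance regression, then correlation restricted to the frames
surviving motion scrubbing. Filtering always sees the complete series;
frames are excluded only at the correlation stage, because recursive filters
propagate information across frames and excising frames before filtering
would smear motion artifacts.

* **Band-pass (0.008–0.1 Hz).** An order-2 Butterworth applied forward and
  backward (`signal::filtfilt`), after removing the column mean. The
  zero-phase composition avoids shifting temporal correlations; the squared
  magnitude response keeps mid-band gain above 0.99 at a repetition time of
  2 s and attenuates a 0.2 Hz probe below 0.01. Only the transmission range
  is part of the scientific contract; the filter family and order are
  implementation choices and are stated here so results are reproducible.
* **Frame displacement.** The sum of absolute frame-to-frame changes over
  the six rigid-body parameters. Rotations are converted to millimetres as
  arc length on a 50 mm sphere — the convention of the scrubbing
  literature — and `rotation_radius = NULL` switches to raw-radian
  summation for data that arrive pre-converted.
* **Scrubbing.** A frame with FD > 0.5 mm is removed together with one
  frame before and two after. Lowering the threshold can only shrink the
  retained set (a property the test suite asserts).
* **Nuisance regression.** Ten regressors — white matter, CSF, whole-brain
  (global) mean, and the six motion parameters — are band-passed with the
  same filter, augmented with an intercept, and regressed out of every
  regional course by least squares. The global signal *is* included by
  default; drop that column of the tissue matrix to change this.
* **Degenerate pairs.** A region with zero variance within the retained
  frames has undefined correlations; these entries are stored as 0 with a
  warning so the vector length never changes.
* **Index map.** Position $k$ of the FC vector is the pair $(i, j)$,
  $i > j$, in row-major lower-triangle order $(2,1), (3,1), (3,2), \dots$
  (1-based); `fc_index_map()` materializes the bijection.

## L1-regularized sparse CCA

With standardized blocks, the method maximizes $v_1^\top X_1^\top X_2 v_2$
subject to $\lVert v_a \rVert_2 \le 1$ and $\lVert v_a \rVert_1 \le c_a$. The
elementary step is the projection of a vector $a$ onto that constraint set:
soft-threshold, then L2-normalize, with the smallest threshold (found by 60
bisection steps) that meets the L1 bound. At $c = 1$ the solution degenerates
to a single $\pm 1$ coordinate; entries surviving only at relative magnitude
$10^{-12}$ of the largest are set to zero, since support at machine-noise
level is an artifact of rounding order, not sparsity structure.

Choices the objective itself does not fix:

* **Bound parameterization.** $c_a = \max(1, \lambda_a \sqrt{p_a})$, so the
  sparseness parameter $\lambda \in (0, 1]$ interpolates from maximally
  sparse to unconstrained. A consequence worth knowing: a Gaussian-like
  loading vector has $\lVert a\rVert_1/\lVert a\rVert_2 \approx
  0.8\sqrt{p}$, so the feature-side constraint is inactive for
  $\lambda_2 \gtrsim 0.7$ and those grid points return dense loadings. The
  protocol tolerates this — dense compliant fits inflate the union, and the
  classifier stage re-sparsifies — but it is why the *union* of selected
  features is large while the final connection set is small.
* **Components and deflation.** All $q = \min(p_1, p_2) = 10$ components are
  extracted; after each, the rank-1 term $d_k v_1 v_2^\top$ is subtracted
  from the cross-product matrix. At $\lambda = 1$ this reproduces the
  leading singular vectors and exhausts the matrix after $q$ components
  (asserted against `svd()` in the tests).
* **Initialization.** $v_2$ starts at the column-norm profile of the working
  matrix and is refined by 20 plain power steps; the sign is fixed so the
  largest-magnitude entry is positive.
* **Convergence.** Alternation stops when the objective changes by less than
  $10^{-6}$ (relative) or after 200 iterations.
* **Determinism.** The solver's inner arithmetic uses fixed-order scalar
  loops rather than optimized BLAS kernels: selection outcomes ride on
  exact-zero patterns and argmax decisions at near-tied bifurcations, and
  BLAS kernels may legally change their reduction order with buffer
  alignment, which was observed to flip selections between identical runs.
  The matrices are small ($p_1 = 10$ rows), so this costs nothing.

**Diagnostic canonical constraint.** A component is *diagnostic* when its
attribute-side loading is nonzero on the diagnosis row and exactly zero
elsewhere ("nonzero" means exactly nonzero — the projection produces exact
zeros, no epsilon is involved). For every fit, the absolute feature-side
loadings of the diagnostic components are summed into an accumulation vector
$\xi$; fits without a diagnostic component contribute nothing. Across
inner folds and the $\lambda$ grid the $\xi$ vectors are summed, and the
selected index set is the support of the total. Support drives the
downstream projection; the magnitudes are kept for reporting and ranking.

On planted-effect synthetic cohorts the constraint behaves as designed but
not as a hard filter: diagnosis-linked connections receive dominant $\xi$
weight and are fully recovered, site-linked connections are mostly routed
into site components, yet dense compliant fits leak some site support into
the union. Full exclusion of nuisance-linked connections is delivered by the
classifier stage — on the study-scale synthetic cohort, 0–2 % of site-linked
connections survive into the final model against 100 % recall of planted
diagnosis connections in the union.

## Sparse logistic regression with ARD

The classifier is logistic regression on the selected subspace (augmented
with a constant input), with an independent Gaussian prior
$\mathcal N(0, \alpha_i^{-1})$ on each weight and prior precisions learned by
marginal-likelihood (evidence) maximization under the Laplace approximation.

The search is *constructive*. Starting from the bias-only model, each
iteration Gaussianizes the likelihood at the current posterior mode (IRLS
working responses), computes for every feature the sparsity statistics
$s_i$ (leave-one-out prior-free variance) and $q_i$ (leave-one-out
correlation with the working residual), and then:

* re-estimates in-model precisions, $\alpha_i = s_i^2 / (q_i^2 - s_i)$;
* deletes in-model features with $q_i^2 \le s_i$ — their evidence-optimal
  precision is infinite, the prior peaks at zero, and the weight is set to
  exactly 0 (also triggered when $\alpha_i$ exceeds $10^8$);
* adds the out-of-model feature with the largest positive evidence gain,
  provided the gain exceeds $\log m$.

The $\log m$ admission threshold is the Occam penalty of a $1/m$ prior
inclusion probability per candidate: under a pure-noise pool, roughly a
third of candidates show $q^2 > s$ by chance, and a flat threshold would
admit dozens of them; with the multiplicity penalty the expected number of
spurious inclusions stays of order one regardless of pool size. The
constructive direction matters for the same reason: initializing *all*
precisions broad lets the model latch onto training noise and converge to a
local evidence optimum that retains many irrelevant features (measured:
9–21 of 50 pure-noise features at $N = 100$); grown from the empty model,
the same evidence criterion ends with 0–2.

Remaining conventions: the bias rides on a fixed broad prior
($\alpha = 10^{-6}$) and is never pruned; features are standardized with
training statistics stored in the model and re-applied to any test input;
convergence is declared when no addition or deletion fires and the largest
relative precision change is below $10^{-4}$, with a cap of 500 iterations;
each Laplace refit takes up to 25 damped Newton steps. At convergence the
active-set weights solve the reduced penalized-logistic problem, which the
tests verify against a direct Newton solver to $10^{-3}$ relative.

A consequence of evidence maximization worth stating: when many connections
carry *redundant* diagnostic signal, the learner keeps a parsimonious subset
(the rest add no conditional evidence), so exact support recovery of a
planted set is not identifiable — precision of the final set is high while
its recall saturates well below one even when the selection union contains
every planted connection.

The decision rule is the sign of the weighted linear summation
$\mathrm{WLS} = w^\top \hat z$: positive classifies as case, non-positive as
control; $P(y = 1) = \mathrm{logistic}(\mathrm{WLS})$.

## The nested protocol

Subjects are split into nine outer folds, stratified by (diagnosis, sex,
site): each cell is shuffled under the seed and dealt round-robin onto the
folds with a rotating starting fold, so per-cell counts differ by at most
one even for cells smaller than the fold count (the remainder rule is this
package's choice). Each outer fold serves as a testing pool. Its feature
set comes from a nine-fold *inner* re-partition of the remaining eight
folds: drop one inner fold, standardize on the rest, fit sparse CCA at all
45 $(\lambda_1 \le \lambda_2)$ pairs over $\{0.1, \dots, 0.9\}$, and
accumulate diagnostic-component loadings; the testing pool's feature set is
the union over the $9 \times 45$ fits. During LOOCV every subject is scored
by an SLR model trained on all other $N - 1$ subjects restricted to its
pool's feature set — subjects of one pool share features, which is what
makes nested selection computationally feasible. The final classifier is
trained on all subjects restricted to the union of the nine per-fold
feature sets, and can be serialized (`slr_save()`) and applied to external
cohorts without any refitting.

The compliance rate — the share of fits that produce at least one
diagnostic canonical variable — is an emergent quantity, not a parameter;
on study-scale synthetic cohorts it comes out near 20 %.

## The synthetic cohort generator

No public accession exists for the cohorts this class of classifier is
built on, so the generator is a first-class module: every downstream stage
is exercised on seeded cohorts with known ground truth.

* **Attributes.** Age uniform on 20–45 years (adult cohorts), sex
  Bernoulli with 30 % female, eye condition Bernoulli(0.5), three
  medication flags assigned only to diagnosed subjects (rates 0.25, 0.2,
  0.2) — medication is thereby *confounded* with diagnosis, as in real
  clinical cohorts. Site membership is categorical with configurable
  proportions, and a site can be declared control-only, mirroring
  multi-site studies in which one site recruits no patients. All defaults
  are overridable.
* **Connectivity.** Each value is built on a latent Gaussian scale —
  per-connection baseline $\mathcal N(0, 0.25^2)$, plus
  $d \cdot \sigma$ for planted diagnosis connections of diagnosed
  subjects, plus per-unit nuisance contributions, plus
  $\mathcal N(0, \sigma^2)$ noise with $\sigma = 0.1$ — then squashed
  through $\tanh$, a monotone bounded map into $(-1, 1)$ that preserves
  rank order and, with these scales, attenuates a planted standardized
  difference by only a few percent. Baselines are a property of the
  *population*: the truth object records them, so held-out cohorts drawn
  from the same truth share them, which is what makes external-validation
  experiments meaningful. The default site effect is twice the noise SD
  per unit — site effects at least as strong as the diagnosis effect per
  connection, a deliberately hard setting for nuisance robustness.
* **Time series.** Multivariate Gaussian frames with a prescribed
  population correlation (via symmetric eigen square root), random-walk
  motion with transient spikes specified in mm-equivalents (rotations
  scaled on the 50 mm sphere), and tissue signals as low-pass-filtered
  noise — plausible nuisance regressors, not physiological simulations.

What the generator does **not** emulate: spatial correlation structure
among FC features (noise is independent across connections), heavy-tailed
or non-Gaussian noise, scanner drift, hemodynamics, or image-space
artifacts. Passing recovery tests therefore demonstrates the selection and
classification machinery under controlled confounding — not performance on
real fMRI, where inter-feature correlation makes both selection and
nuisance leakage harder.

## Null behaviour of leave-one-out protocols

Two artifacts of LOOCV on signal-free data are worth knowing when reading
the calibration results. With near-empty models the score reduces to the
training-set bias $\log(n_1/n_0)$, which *anti-correlates* with the
left-out label: removing a case tilts the training majority toward
controls. Rank-based measures (AUC) of such scores sit below 0.5, and if
the cohort is exactly class-balanced the majority vote is wrong for every
subject. Conversely, when the cohort's own label draw is imbalanced, the
majority vote is *right* at the majority share, so null accuracy
concentrates at $\max(n_1, n_0)/N$ rather than at one half — a 181-subject
cohort drawn at rate one half can put that baseline above 0.6 in the tail
of the label draw with no information extracted at all. The calibration
experiments therefore use an odd cohort size (181, matching the
discovery-cohort convention, so leave-one-out training sets never tie) and
assess the null against the majority-share baseline: leakage would show up
as accuracy *above* that baseline's binomial band, while the fitted null
models themselves stay essentially empty.

## Evaluation and characterization statistics

Standard steps are delegated to base R — `pbinom` (exact one-sided binomial
tails), `chisq.test` (under/over balance, df = 1), `ks.test` (two-sample
WLS comparisons, exact null below 25 per group), `p.adjust` (Benjamini–
Hochberg across datasets) — with dual-route tests against direct summation
and counting oracles. Conventions:

* diagnostic odds ratio $(TP \cdot TN)/(FN \cdot FP)$, with the
  Haldane–Anscombe $+0.5$ correction and a flag when a cell is zero;
* AUC as the Mann–Whitney pair-ordering probability, ties half credit;
* the permutation test permutes diagnosis labels and reruns the *entire*
  nested selection per replicate (the conservative scheme), with an
  add-one p-value estimator; freezing the observed selection is available
  but labelled anticonservative, since that selection has seen the true
  labels;
* laterality classification: both terminals left → left-intra, both
  right → right-intra, anything else — including medial terminals (vermis)
  → inter-hemispheric, the only rule consistent with the published
  31 %/69 %/0 split;
* network enrichment counts terminal regions with duplicates (two per
  connection) against the anatomically expected fraction;
* the absence test for left-intra-hemispheric connections needs a null
  selection probability that the data do not fix; the package defaults to
  the share of same-hemisphere pairs among all pairs,
  $\binom{70}{2}/\binom{140}{2} \approx 0.248$ — the only candidate that
  reproduces the published $P = 0.01$ for zero of sixteen — and also
  accepts the stricter symmetric-category null of $1/3$;
* the summary-statistic distance test uses pooled variance
  (df $= n_1 + n_2 - 2$, matching the printed $t_{14}$), not Welch;
* clinical-score prediction uses leave-one-out OLS computed exactly through
  the hat-matrix identity $e_{(-i)} = e_i / (1 - h_{ii})$ (verified against
  explicit refits), with age and sex as additional covariates and listwise
  deletion per score domain;
* the score-prediction null redraws 16 connections from the never-selected
  pool, refits all domains, and pools the per-replicate maximum across the
  eight domains — the multiplicity-honest null for "the best of eight
  correlations".

## Problem sizes

The test suite and the acceptance script run the full protocol on cohorts
of 360 subjects with 2,000 connections (15 planted diagnosis effects at
$d = 1$, 50 site-linked connections) and a 181-subject null cohort; unit
tests use 45–400 subjects and 60–800 connections. These sizes keep every
property measurable at comfortable margins while the whole suite completes
in minutes; the machinery itself is the same at 9,730 connections, with
cost scaling linearly in the number of connections for selection and with
the active dimension for classification.

## Known limitations

* Raw image processing (slice timing, realignment, normalization,
  segmentation, smoothing) is out of scope; the pipeline starts from
  region-averaged time series.
* The generator's independence of noise across connections makes synthetic
  selection easier than on real data (see above).
* Only two-block, linear sparse CCA is provided — no kernels, no more than
  two views, no permutation-based sparseness selection.
* The classifier is strictly binary; multiclass extension would need a
  different likelihood and relevance bookkeeping.
* Exact-zero bookkeeping in the selection stage assumes the provided FC
  matrices are column-complete (no missing values); subjects with
  incomplete coverage must be imputed or dropped upstream.
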