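---
title: "Methods: from paired omics to a points-based diagnostic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from paired omics to a points-based diagnostic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`seromarker` implements an inference chain for identifying a tumour-derived
serum biomarker from paired tissue-transcriptome / serum-proteome data and
turning it into a preoperative diagnostic model. This vignette explains the
statistical machinery, the choices that were genuinely open, and what the
synthetic-data generators do and do not emulate.

## The discovery model

A serum protein that is merely *different* between cases and controls may be
a systemic reaction; a protein that is **tumour-derived** should additionally
track its own transcript in tumour tissue. The selection criterion in
`select_tumour_derived()` therefore intersects three pieces of evidence per
gene:

1. **Proteomic dysregulation** — |log2 FC| ≥ log2(1.2) with
   Benjamini–Hochberg q < 0.05 in the serum layer,
2. **Transcriptomic dysregulation** — |log2 FC| ≥ log2(1.5) with q < 0.05 in
   the tissue layer,
3. **Cross-layer coupling** — Spearman ρ > 0 with p < 0.05 across the
   subjects measured in both layers,

with concordant fold-change direction required by default. Fold changes are
the difference of group means of `log2(x + pseudocount)` on library-size
normalized abundances. The pseudocount defaults to half the smallest nonzero
abundance of the layer, the standard zero-guard when the acquisition floor is
unknown.

Per-feature significance uses the two-sided Wilcoxon rank-sum test. No test
is named by the design this mirrors, so a distribution-free choice is safest
for skewed abundance data; the large-sample form (tie-corrected normal
approximation with continuity correction, identical to
`stats::wilcox.test(exact = FALSE)`) is vectorized across features, and an
exact permutation-enumeration path (`exact = TRUE`) exists for small groups —
unlike the classical exact distribution it remains valid under ties.
Correlation significance deliberately uses the *unadjusted* p-value by
default (`adjust_corr = FALSE`): single-pair correlations in this design are
conventionally reported raw, and the dual-layer q-thresholds already control
the discovery error; BH adjustment of the correlation axis is available as an
option. A pair needs at least `min_n = 5` complete observations — the
Spearman t-approximation is unstable below that — otherwise it is emitted
flagged with ρ undefined rather than dropped.

## The monoclonality score

Monoclonal B-cell populations express a single immunoglobulin light chain,
skewing the κ/λ output ratio in either direction. The absolute κ/λ score

$$s(\kappa, \lambda) = \left|\log_2\frac{\kappa + \varepsilon}{\lambda + \varepsilon}\right|$$

quantifies that skew symmetrically: zero for balanced output, equal for
κ-restricted and λ-restricted clones, strictly increasing in log-scale
imbalance. The exact published form of such scores varies; since every
reasonable variant (absolute log10 ratio, max/min ratio) is a monotone
transform of the others, all rank-based downstream comparisons are invariant
to the choice, and the package exposes the variants while defaulting to the
absolute log2 ratio. The implementation computes
`|log2(κ+ε) − log2(λ+ε)|` so swap symmetry holds *exactly in floating
point*, not only analytically. On the transcript side the intended usage is
IGKC against the summed IGLC paralogs; summing the λ constant-region
paralogs is a deliberate aggregation decision.

## Biomarker evaluation

**ROC.** `roc_curve()` builds the empirical curve over the unique observed
values (with ∓∞ sentinels; positive call at value ≥ threshold) and computes
the AUC by the tie-corrected rank formula — exactly pair counting with ties
worth ½. The confidence interval is a stratified percentile bootstrap (2000
resamples by default, seeded); a bootstrap was preferred over an asymptotic
variance formula because it needs no tie-pattern assumptions and the chain
is seeded end to end anyway.

**Cutoffs.** Two complementary cutoffs are produced. The ROC cutoff
maximizes Youden's J (ties broken toward higher specificity, then the lower
value, making the result deterministic); "closest to (0,1)" is available as
an alternative strategy. The AIC cutoff is found by a dichotomization scan:
for every candidate `c` in the grid (observed unique values between the 5th
and 95th percentiles by default) the logistic model `y ~ 1[x ≥ c]` is fitted
and the AIC-minimizing `c` returned, ties toward the smaller value. A scan
producing a cutoff in marker units is the only reading of "a cutoff chosen
by minimal AIC" whose output *is* a concentration; AIC-guided knot selection
is a different operation and is not part of the default chain. Perfect
splits on the grid are handled with a tiny ridge (1e-6) on the slope so the
scan cannot diverge on separable grid points.

**Linearity.** `rcs_basis()` implements the restricted cubic spline
(natural spline) basis in the truncated-power parameterization: k knots give
k−1 columns including the linear term, with continuous second derivatives
and exact linearity beyond the boundary knots (checked numerically in the
tests). Knots default to 4 at the (5, 35, 65, 95)% quantiles — the standard
placement — configurable from 3 to 5. `nonlinearity_test()` compares the
spline logistic model against the linear one with a likelihood-ratio χ² on
k−2 degrees of freedom; under a true linear logit its size is nominal
(verified by simulation in the acceptance suite).

**Ordinalization.** `ordinalize()` codes low/mid/high with boundary values
assigned upward (a value exactly at a cut belongs to the upper level); the
coding is emitted both as an ordered level and as the two dummy indicators
used by the model. Coarsening can only lose information, and the test suite
asserts the ordinal AUC never exceeds the continuous AUC on the same data.

## Cohort modelling

**Propensity matching.** The propensity of case status is fitted by
logistic regression on the clinical covariates (calendar dates enter as days
since the earliest date — the simplest faithful encoding), and cases are
matched 1:1 to controls greedily, nearest-neighbour on the propensity logit,
processing cases in descending propensity order without replacement. Greedy
rather than optimal matching is the standard deterministic reading of a
plain "1:1 nearest neighbour" description. Balance is reported as the
standardized mean difference of every expanded covariate column before and
after (pooled-SD form; proportion form for binaries). An optional caliper in
SD units of the logit is exposed and **off by default**; be aware that when
case and control covariate supports only partly overlap, plain 1:1 matching
of *all* cases provably cannot balance the tails — the conventional 0.2-SD
caliper (at the cost of dropping off-support cases) is what the package's
own balance simulations use to reach the usual |SMD| < 0.1 standard.

**Logistic machinery.** `fit_logistic()` is a design-matrix
maximum-likelihood fit (via IRLS with a tight convergence tolerance) with
Wald inference, an explicit rank check that names collinear columns, and
(quasi-)separation detection with a small-ridge refit that is always
flagged, never silent. Model building in `select_model()` starts from the
ordinal-marker dummies plus the age indicator and admits each candidate term
in listed order iff it lowers the AIC — note that under a null candidate
ΔAIC < 0 still happens with probability ≈ 0.16, so inclusion of a noise
term is expected occasionally and the report records the AIC trace. The age
cutoff itself comes from a Youden analysis with younger-is-case-like
orientation; the reported cutoff is placed midway between the selected
threshold and the next observed age so the strict `age < cutoff` indicator
reproduces the selected dichotomy exactly.

**Nomogram.** `build_nomogram()` re-expresses the fitted model on a 0–100
points scale: each term's contribution β·x is anchored at its observed
minimum, the widest contribution range spans 100 points, and total points
map to probability through the inverse logit. This is an affine re-coding,
so nomogram probabilities equal model probabilities to numerical precision
(asserted at 1e-9 in the tests) — the nomogram is presentation, never a
second model.

**Split and calibration.** The derivation/validation split is stratified by
diagnosis class with largest-remainder allocation and a seeded shuffle, so
class proportions are preserved within one subject and the split is
reproducible. The model is fitted on the derivation set and compared with
the continuous and ordinal marker by ROC on both sets. Calibration bins
subjects into equal-count bins of predicted probability and compares
observed frequency with mean prediction; an optimism-corrected curve is
available through Harrell's bootstrap (refit on resamples, evaluate on the
original, subtract the mean optimism bin-wise).

## The synthetic-data generators

The generators make the whole chain testable without patient data. They
emulate the *statistical structure* the analysis assumes — not the biology:

* `generate_paired_omics()` draws log2-normal abundances around
  feature-specific baselines. Default cohort sizes are 28+30 (proteome) and
  38+31 (transcriptome) with 76% of the smaller layer shared — the overlap
  implied by 83 unique subjects filling 58+69 slots. Planted tumour-derived
  markers carry configured per-layer fold changes (defaults 2.64 / 2.0 log2
  units) and a per-subject latent factor shared between layers. The latent
  model is a **variance decomposition**: every feature keeps marginal log2
  noise `noise_sd` (default 0.8), and planted features split theirs into a
  shared component sized so the within-class cross-layer Pearson correlation
  equals `2 sin(πρ/6)` — the bivariate-normal map to a Spearman target ρ
  (default 0.6). Two consequences worth knowing: the *pooled* cross-layer
  correlation over shared subjects is higher than ρ because the concordant
  case shift adds association, and finite-sample Spearman estimates are
  slightly attenuated; the tests therefore check the within-class
  correlation against the target.
* `generate_cohort()` produces the four-class case-control table (default
  sizes 68/33/26/78, totalling 205). Serum IgM is log-normal; the default
  case/control shift (log-means 0.45 vs −0.163, SD 0.5) was sized once to
  give case-vs-control discrimination near AUC 0.81, the regime this design
  operates in. The negative IgM–age slope (−0.01 per year on log IgM)
  applies to all three control classes and is centred at the control age
  mean so class means are unaffected; cases' IgM is age-independent. Cases
  are younger on average (52 vs 60, SD 15, truncated to [18, 90]) and have
  higher lacrimal-gland involvement (0.4 vs 0.15), giving the model's age
  and lacrimal terms real signal. A seeded 60% of cases carry a
  post-treatment IgM with expected change −0.5 g/L.
* `generate_clonality()` splits a per-subject total light-chain output
  (log-normal around `total_ig_scale`) between κ and λ. The dominant-chain
  share in cases is Beta-distributed with mean exactly `restriction` and
  concentration `1/noise_sd²`; controls have mean ½. The Beta keeps the
  expectation contract exact at every restriction level and collapses to a
  point mass at `restriction = 1`, where every case score equals the maximal
  value achievable for its total.

What the generators do **not** emulate: missingness and batch structure,
detection-limit censoring, compositional effects of deep proteomes,
correlated background features, informative treatment selection, or any
mechanism behind stage/grade covariates (carried as inert columns). Passing
tests therefore demonstrate that the *procedures* are correct and powered
under the assumed structure, not that any particular real cohort will
reproduce specific values.

## Numerical choices and degenerate inputs

* One integer seed drives everything; sub-streams use fixed offsets
  (`substream_seed()`), all below 2³¹.
* Features tied across both groups get p = 1, not an error; correlations
  with fewer than 5 complete pairs are flagged, not dropped silently.
* BH is applied within layer (DE) and within contrast family (group tests).
* `aic_cutoff_scan` ties resolve to the smaller cutoff; Youden ties to the
  higher specificity then lower cutoff; both documented and deterministic.
* Readers reject, with named errors: duplicate ids, non-numeric cells (with
  row/column), unknown diagnosis classes, non-ISO dates, non-positive IgM,
  and any IgM unit annotation other than g/L — no silent conversion.
* The pipeline's problem sizes (1003 pairs, 205 patients, 2000 bootstrap
  resamples, 200 calibration refits) run in well under a minute; the test
  suite's simulations use 10–500 replicates per property, sized so
  Monte-Carlo error is small relative to the asserted margins.

## Known limitations

* Matching is greedy, not optimal; with heavy confounding the pairing (and
  hence balance) depends on the processing order, which is why the order is
  fixed and documented.
* The AUC bootstrap is percentile-based; for very small strata a BCa or
  exact approach would be preferable.
* The calibration optimism correction refits the *coefficients* but not the
  candidate-selection step; with one candidate term the optimism from
  selection is minor but nonzero.
* The nonlinearity test's χ² reference is asymptotic; at n ≪ 100 its size
  drifts (the suite calibrates it at n = 500).
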