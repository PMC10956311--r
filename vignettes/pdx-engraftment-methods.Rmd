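---
title: "Modelling PDX engraftment from tissue morphometrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PDX engraftment from tissue morphometrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxms)
```

## The problem

Patient-derived xenografts (PDX) — human tumour fragments engrafted into
immunodeficient mice — only become useful preclinical models when the graft
takes and can be passaged, and in breast cancer the take rate is low and
highly variable. Predicting which resected tumours will engraft is therefore
a practical question: it decides which samples are worth implanting.

Two kinds of predictors are in play. Clinicopathological variables (age,
molecular subtype, Ki-67 labelling index, neoadjuvant chemotherapy status,
histologic grade, tumour size, nodal burden, and for NAC-treated patients
the Miller-Payne grade and residual cancer burden) come from routine
pathology. Morphometric variables come from a patch-classified whole-slide
image: the slide is cut into 112x112-pixel patches at 400x, each patch is
assigned one of six tissue classes — adipose, background, necrosis,
carcinoma (in situ and invasive under one umbrella label), stroma, and
terminal ductal lobular units (TDLU) — and a separate segmentation supplies
a per-patch lymphocyte area fraction. This package takes the label grid as
its input: the upstream convolutional classifiers are out of scope, both
because trained weights and images are not distributable and because every
downstream quantity is defined on the label grid alone.

The analysis chain implemented here is:

1. delineate the largest tumour mass on the label grid and compute the six
   intratumoral proportions plus the lymphocyte area fraction
   (`delineate_tumor()`, `compute_proportions()`, `compute_tilp()`,
   `profile_cohort()`);
2. exploratory group comparisons of engraftment success vs failure
   (`summarize_groups()`);
3. univariate logistic screening at p < 0.2, then backward stepwise
   elimination by AIC (`univariate_screen()`, `stepwise_backward_aic()`,
   both on top of `fit_logistic()`), plus a CART classifier with
   cost-complexity pruning (`fit_cart()`, `prune_tree()`);
4. evaluation by ROC/AUC with a 1000-replicate BCa bootstrap, a Youden-index
   cutoff, and PPV/NPV at that cutoff (`roc_auc()`, `bootstrap_auc()`,
   `bootstrap_model_auc()`, `youden_cutoff()`, `ppv_npv()`).

Because no patient-level data are deposited anywhere, the package also
contains a first-class synthetic-data module (`generate_label_map()`,
`generate_cohort()`, `expand_counts()`) whose ground truth makes every stage
testable, and a `reproduce()` operation that regenerates every published
number that is derivable from printed contingency counts alone.

## Morphometric definitions

Within the delineated tumour perimeter, the proportion of patches of class
$c$ is

$$ P_c = 10{,}000 \cdot \frac{\#\{\text{patches of class } c \text{ inside the perimeter}\}}{\#\{\text{patches inside the perimeter}\}} $$

giving AP (adipose), BP (background), NP (necrosis), TDLUP, SP (stroma) and
the raw carcinoma proportion; these six sum to exactly 10,000. The invasive
carcinoma proportion is ICP = carcinomaP x invasive fraction, where the
invasive fraction in [0, 1] is a pathologist-assessed scalar correcting the
unified carcinoma class for its in situ component. TILP is lymphocyte area
inside the perimeter over total intratumoral patch area, x10,000; with
equal-area patches this is 10,000 times the mean per-patch lymphocyte
fraction. The x10,000 scale mirrors how these proportions are reported, and
odds ratios for them are conventionally quoted per 1,000 units
(`scaled_odds_ratio(fit, term, delta = 1000)`).

One wording conflict in the source reporting is left to the user: a
1,000-unit change on the x10,000 scale is 10 percentage points of
intratumoral area, yet the same tables gloss it as "0.1%". The package takes
no position — `delta` is explicit — and this paragraph is the documentation
of the discrepancy.

### Tumour delineation

The source material shows a boundary "encircling the carcinoma component"
but does not state an algorithm, so delineation is a documented convention
here: binary carcinoma mask, morphological closing with a square element of
radius 2 patches (bridging gaps up to ~4 patches), hole filling (so enclosed
necrosis, stroma, TDLU or adipose pockets count as intratumoral — this is
what makes NP etc. non-trivial), then the largest 8-connected component.
The radius, the connectivity (4 available) and the denominator (background
included by default; a tissue-only denominator is a flag, since the
reporting of a BP column implies background was tracked but its role in the
denominator is unstated) are all configurable so alternative
reconstructions can be compared. Ties between equal-sized components go to
the one whose lexicographically smallest (row, col) cell comes first.

Closing is computed on a grid padded by the radius, the canonical
definition; without padding, closing would not contain its input near the
border, and the useful monotonicity (a larger radius never shrinks the
delineated region, which holds for closings by scaled convex structuring
elements) would fail. Grid primitives (box dilation/erosion, hole filling
via the 4-connected complement, components via igraph) are implemented
in-package precisely so these border and connectivity semantics are pinned;
the test suite checks them cell-for-cell against an independent brute-force
flood-fill oracle on random maps.

## Statistical chain

### Logistic regression

`fit_logistic()` is a from-scratch iteratively-reweighted-least-squares
fitter: convergence when the largest coefficient change falls below 1e-8
(cap 50 iterations), standard errors from the observed information, Wald
p-values and 95% intervals $\exp(\beta \pm z_{0.975}\,\mathrm{SE})$. The
exact quantile (1.959964, not 1.96) matters at printed precision: the
published TNBC interval 1.27–75.23 reproduces only with the exact value.
Categorical terms expand against a reference level — the first level in
declared order, matching the implied references of the source tables
(HER2+ for subtype, grade 2, NAC "no") — one coefficient per non-reference
level. Aliased columns are dropped with a warning; separation is flagged
(`separable`), not penalised: no Firth correction is applied, because the
published intervals (e.g. 1.27–75.23) are consistent with plain maximum
likelihood, and a flagged fit with an honest enormous interval is more
faithful than a silently shrunken one.

Screening fits one single-predictor model per variable and passes those
with Wald p < 0.2 to the multivariate step. Backward elimination starts
from the full candidate model, removes the term whose deletion lowers AIC
most, and stops when no deletion lowers AIC; removed terms are never
reconsidered (pure backward, per the source's wording). AIC ties are broken
by removing the term with the larger Wald p in the current fit (a
multi-level term is judged by its smallest coefficient p) — the source is
silent, so this is a package convention. The trace is returned and AIC is
non-increasing along it; on simulated six-variable problems the final model
matches the exhaustive 2^6-subset AIC minimum in well over 80% of runs,
which is the property the test suite asserts.

### Classification tree

`fit_cart()` grows a binary Gini tree with rpart's stopping conventions
(minsplit 20, minbucket 7, maxdepth 30): continuous splits at midpoints of
adjacent distinct values, categorical splits through the
outcome-rate-ordering reduction (optimal for two-class Gini). Pruning uses
cost-complexity on the misclassification risk: the package computes the
exact weakest-link sequence, reported as a printcp-style table (CP scaled
by the root risk, split count, relative training error, cross-validated
error and its standard error). Cross-validation mirrors the rpart scheme —
each fold's tree is pruned at the geometric means of adjacent CP values of
the main sequence — with seeded fold assignment.

Two documented divergences from rpart. First, no surrogate splits exist
here, so variable importance counts primary splits only (the per-variable
sum of realised Gini decreases, normalised to percent); rpart's
surrogate-inclusive importances will differ. Second, for branches that
collapse several splits at once, rpart's CP table reports a conservative
complexity computed during growth rather than the exact weakest-link alpha
— its `prune()` can then return a subtree that is not the cost-complexity
optimum. This package prunes exactly (the tests verify that pruning at any
penalty equals re-deriving the optimal subtree from scratch); the
cross-checks against rpart therefore compare tree structure and relative
errors everywhere, and CP values only where the sequences coincide. A
related corner: splits that reduce Gini but not misclassification risk are
kept in the grown tree (so `cp = 0` is a no-op) but collapse at any
positive penalty, and the CP table lists the risk-relevant sequence.

### Evaluation

`roc_auc()` is the Mann-Whitney statistic with midrank ties, identical to
the trapezoidal area under the empirical ROC. The bootstrap resamples
patient rows with replacement, unstratified (stratification is never
mentioned in the source); for a model, the fixed term set is refitted on
each replicate — no re-screening or re-selection inside the loop, matching
a report of a single "initial AUC" with small bias — and the apparent AUC
on the replicate is recorded, so `bias = mean(replicates) - original` is a
resampling-optimism estimate. Replicates that lose an outcome class are
redrawn and counted. The BCa interval uses
$z_0 = \Phi^{-1}(\text{fraction of replicates below the original})$ and the
jackknife-skewness acceleration; endpoints are order statistics of the
replicate vector, so with $z_0 = a = 0$ the interval is exactly the
percentile interval. Degenerate replicate vectors give a zero-width
interval.

`youden_cutoff()` scans midpoints between adjacent sorted unique scores
plus infinities, calls a case positive at score >= cutoff (the ">="
convention and smallest-cutoff tie-break are package conventions; the
source states neither) and maximises J = sensitivity + specificity - 1.
PPV/NPV with empty denominators are reported as NA with explicit
`*_defined` flags, never silently zero.

### Group comparisons

Continuous variables use the Welch t-test (the source does not say pooled
or Welch; Welch is the safer default). Contingency tables use Pearson's
chi-square without continuity correction when all expected counts are at
least 5, and Fisher's exact test otherwise — a stated convention, since the
source never gives its rule. One printed value resists this convention: the
full-cohort M-stage margin (291/3 vs 58/1) is printed as p = 1.000, but
Fisher's exact test gives 0.520 (verified by direct hypergeometric
enumeration); the printed value is consistent with a Yates-corrected
chi-square. The NAC-column M-stage margin does give Fisher p = 1.000, and
that is the value `reproduce()` checks. No multiple-testing correction is
applied anywhere, matching the source analysis.

## The synthetic-data generators

### Label maps

`generate_label_map()` emulates a patch-classified slide, not pixels: the
target is controllable intratumoral composition, a single dominant tumour
mass, and spatial coherence. Per-class Gaussian random fields are smoothed
(row/column Gaussian kernels, width = `smoothness` patches) and assigned by
argmax after additive per-class offsets are iteratively calibrated to the
target fractions. The tumour region is grown best-first from the maximum of
a smoothed field to `tumor_mass` x grid cells (holes filled), which
guarantees a simply connected blob; its non-carcinoma quota is placed
strictly in the eroded interior, so every pocket is a genuine hole that
delineation recovers, and the surround is filled with the renormalised
non-carcinoma classes (necrosis excluded from the surround when possible,
since necrosis is an intratumoral feature). With a pure-carcinoma
composition the whole grid is carcinoma.

One definitional choice had to be made: the generator cannot simultaneously
make the carcinoma component cover `tumor_mass` of the grid *and* give the
tumour region the full target composition (non-carcinoma classes included)
unless the composition is pure carcinoma. Here `tumor_mass` is the grid
fraction of the tumour *region*; the carcinoma matrix inside it covers
about carcinoma-fraction x `tumor_mass`. This is the reading under which
composition recovery — the property the tests assert (realised intratumoral
fractions within ±0.05 of target on 200x200 grids) — is well defined.

Lymphocyte content is a per-patch area fraction (Beta-distributed around
the configured mean, doubled in stroma to mimic stromal TILs, zero on
background), not a pixel mask: sufficient for TILP, which only ever uses
the per-patch mean.

What the generator does not emulate: stain variation, classifier error
(patches are "classified" by construction), multiple tumour foci,
anisotropic growth, DCIS/IDC geography within the carcinoma class. Passing
tests therefore demonstrate that the measurement and modelling chain is
correct on label grids with known truth — not that any upstream classifier
is accurate on real slides.

### Cohorts

`generate_cohort()` draws independent covariates matching the published
whole-cohort marginals (age 50 ± 12 years truncated to 18–95; Ki-67 and
stromal TIL percentages floor-discretised to the 10-step grid {0, …, 90} as
recorded clinically; tumour size truncated to 0.1–20 cm; positive-node
counts negative binomial with mean 2.8 and the published overdispersion;
subtype/NAC/grade/LVI category frequencies from the printed margins;
Miller-Payne and RCB only for NAC records). The six patch proportions are
Dirichlet on the x10,000 simplex (concentration 8, means from the published
morphometric table), so the sum identity holds by construction, and
ICP = carcinomaP x invasive fraction with the invasive fraction Beta(8, 2).
The outcome is Bernoulli(logistic(beta.x)); the default beta is loosely
matched to the published multivariate odds ratios with the intercept
calibrated so expected prevalence matches the published engraftment rate
(59/353 ≈ 16.7%). The vector actually used is stored in
`attr(cohort, "truth")` — parameter-recovery tests always read the recorded
truth, never the default. Covariate correlations (e.g. Ki-67 x grade) are
not modelled by default because only marginals are published; users can
replace the covariate parameter list.

`expand_counts()` is the bridge from printed tables to record-level data:
it expands an outcome-by-category count table into one row per counted
patient, with the first category as the reference level. Every published
number that depends only on printed counts — the five contingency odds
ratios (TNBC 9.78, HR+ 0.62, grade-3 16.62, NAC 6.03, NAC-group grade-3
9.20), the engraftment and success-group percentages (30.1%, 88.1%, 91.5%,
79.7%, 100%), the sparse-margin exact p — is recomputed this way by
`reproduce()`, which reports computed vs printed values at printed
precision.

## Numerical choices and problem sizes

Tolerances: IRLS stops at max |Δβ| < 1e-8; the AIC identity is exact to
1e-8; contingency fits match the closed-form log odds ratio to 1e-6; AUC
matches brute-force pair counting to 1e-12; BCa endpoints are order
statistics selected with a 1e-9 fuzz on the adjusted probabilities (so
float error in `(1-level)/2` cannot shift an order statistic). Composition
calibration in the map generator iterates offsets (step 0.8 on the
log-ratio, up to 120 iterations, tolerance 0.003 on realised fractions).

The simulation-based checks in the test suite use: 500 cohorts of n = 1000
for Wald coverage (assertion ±0.03 around 0.95); 100 six-variable cohorts
of n = 1000 for stepwise vs exhaustive-subset agreement (≥ 80%); 200
cohorts of n = 300 with 1000 bootstrap replicates each for BCa coverage
(±0.04 around 0.95); 100 random 30x30 maps for the delineation oracle and
one 500x500 map for composition consistency. These sizes were chosen to
keep Monte Carlo error comfortably inside each assertion band while the
whole suite stays in the low minutes on one core.

## Known limitations

- No surrogate splits and no missing-value handling in the tree; records
  must be complete for the variables used.
- Separation in logistic fits is flagged, not corrected; extremely sparse
  candidate sets can make the stepwise path unstable (the screen's
  per-variable error capture keeps the run alive).
- The delineator reports the largest mass only; how multiple disjoint
  masses should be pooled is left open, as it is in the source.
- The bootstrap refits a fixed term set; re-running selection inside each
  replicate (a stricter optimism estimate) is deliberately not offered. An
  optimism-corrected apparent AUC is available behind the `optimism` flag of
  `bootstrap_model_auc()` but is not the default report.
- Synthetic cohorts have independent covariates; effect estimates on them
  cannot exhibit the confounding structure of the real cohort.
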