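---
title: "Elemental fingerprinting of insect flours: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elemental fingerprinting of insect flours: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flourprint)
```

`flourprint` classifies edible insect flours — cricket, buffalo worm and
mealworm — from their ICP-MS multi-element concentration profiles. This
vignette explains the statistical machinery, the defaults and why they
were chosen, what the synthetic-data generator does and does not emulate,
and the package's known limitations.

## The data model

The exchange object is a long tidy table, one row per sample × element:
`sample_id`, `class`, `element` (isotope label, e.g. `"24Mg"`), `value`
in µg/g of dried flour, and a censor `flag`. Twenty isotopes are carried
by the default panel (`insect_panel()`), including both monitored iron
isotopes, with per-class mean concentrations and the method's LOD/LOQ for
each element.

Trace elements near the method's limits are *censored*, not missing:
a value below the LOD is unreliable as a number but certain as a bound,
and a value between LOD and LOQ is imprecise but informative. The
package's policy (`filter_variables()`):

* elements below the LOD in **every** cell (boron, in the default panel)
  are dropped — they carry no quantitative signal;
* between-limit values are **kept as measured** — in these flours,
  selenium in buffalo worms sits between its limits yet still helps
  separate the classes, because its low level is itself characteristic;
* isolated below-LOD cells of otherwise quantified elements get the
  conventional LOD/2 substitution (configurable to `"keep"`).

## Method-validation arithmetic

The validation module implements the standard figures of merit for a
quantitative ICP-MS method:

* calibration: ordinary least squares of response on standard
  concentration; R² is the squared Pearson correlation of the fit, and
  the working range is recorded as the lowest/highest standard;
  weighted regression is not used;
* detection limits: `LOD = 3·SD_blank/a`, `LOQ = 10·SD_blank/a`, with
  `SD_blank` the standard deviation of independent blank responses
  (6 by default) and `a` the calibration slope. The blank SD is measured
  in response units and divided by the slope — the conventional reading.
  LOQ/LOD = 10/3 exactly, and both are only rounded at serialization,
  never internally;
* unit conversion: a digestion that brings 50 mg of dry flour to 100 mL
  maps µg/L to µg/g by the factor volume/mass = 2;
* spike recovery `100·(C_spiked − C_native)/C_added`, per matrix, with a
  default acceptance band of 90–110% — a conventional band, chosen
  because recoveries a little above 110% are the kind flagged as
  marginal in practice; it is a configurable argument, not a constant;
* RSD from replicate unfortified samples, sample SD with the n−1
  denominator (used consistently everywhere in the package).

## Exploration: autoscaling and PCA

Element concentrations span five orders of magnitude (P at thousands of
µg/g, Cd at hundredths), so every multivariate stage operates on
autoscaled data: each element centred on its training mean and divided
by its training SD. Scaling parameters are *fitted on training samples
only* and applied unchanged to test samples — the test set must never
influence any fitted quantity.

PCA is computed from the sample covariance of the autoscaled matrix (via
`prcomp`); explained variance per component is its eigenvalue as a share
of the total. Because eigenvector sign is arbitrary, each loading is
flipped so its largest-magnitude entry is positive — a pure convention
that stabilizes plots and snapshot tests. Biplot rays are the raw
orthonormal loadings (length ≤ 1), with an optional display stretch;
correlation-scaled rays were considered and left as an option because
raw loadings keep the orthonormality property that the tests verify.

Exploratory PCA is typically run on **all** generated variables,
censored ones included — exploration should see the data before any
selection — while the censoring filter is applied before classification.
Both stages take the table you give them, so either behaviour is one
call away.

## The discriminant model

For classes `g = 1..G` with training samples `i = 1..I` on `p` elements:

* `W` = pooled within-class scatter, `T` = total scatter;
  the pooled covariance is `P = W/(I−G)` and the generalized covariance
  `V = T/(I−1)`;
* univariate Wilks' lambda `Λ = SSW/SSTOT`; multivariate
  `Λ = det(W)/det(T)` — equivalently the determinant ratio of the
  df-normalized `P` and `V`, since the df factors cancel;
* canonical variates: the leading eigenvectors of `P⁻¹B`
  (`B = T − W`), computed through the Cholesky factor of `P` as a
  symmetric eigenproblem, scaled so the within-class variance along each
  direction is 1, signs fixed as in PCA. A `G`-class model has
  `min(G−1, p)` of them — two, for the three flour classes;
* classification: a sample goes to the class minimizing the Mahalanobis
  distance under `P` offset by the log-prior — the linear
  (equal-covariance) discriminant rule. A distance rule and a posterior
  rule coincide under the Gaussian equal-covariance assumption, so the
  simpler one is used. Priors default to equal (the 24/24/28 design is
  nearly balanced); proportional priors are an option.

The F-to-enter test for stepwise selection is Rao's one-variable-added
partial-lambda approximation, exact for a single added variable:
`F = ((I−G−p)/(G−1)) · (Λ_p/Λ_{p+1} − 1)` on `(G−1, I−G−p)` degrees of
freedom, where `p` counts the variables already in the model.

Degenerate inputs are errors, not silent results: constant columns in
autoscaling (named in the message), collinear variables in the
multivariate lambda (singularity tested against `1e−12` times the
diagonal scale of `T`), singular pooled covariance in the LDA fit.

## Variable selection

**CovSel.** Greedy covariance selection against the column-centred class
indicator matrix: at each step pick the predictor column with the
largest sum of squared covariances with the (deflated) response columns,
then deflate both blocks by projecting orthogonally to the picked
column. Ties break to the lowest column index; columns whose deflated
norm falls below `1e−10` of the initial scale are skipped. On
orthonormal predictors this reduces to sorting by squared covariance —
one of the tested properties.

**Subset size by cross-validation.** Folds are stratified
("cancelation groups"): shuffled within class and dealt cyclically, so
fold class proportions stay within one sample of the overall ones; the
cycle continues across classes so no fold is left empty. Seven folds by
default. For CovSel, each training fold produces its own ordering and
every prefix size is scored on the held-out fold; the retained size is
the smallest one achieving the minimum pooled misclassification
(parsimony on ties), and the final variables are the full-training-set
ordering truncated to that size. Sizes where any fold's LDA is singular
are excluded as infeasible.

**Stepwise Wilks.** Within each cancelation group, the variable with the
lowest univariate lambda enters first (it must pass the F-to-enter test
at `alpha = 0.05`, the conventional default); each further candidate is
the one with the largest multivariate-lambda decrease, admitted only if
its partial-F p-value is below `alpha` *and* the held-out
misclassification does not increase. The final model takes the
variables most frequently selected across groups — frequency ties break
to the lower mean univariate lambda, then the lower column index — with
the retained count chosen by the best cross-validated classification
(smallest count on ties). The cross-validated error is always pooled
across folds; per-class rates are reported alongside.

**External validation.** `split_train_test()` holds out 45% of the
samples, stratified, with per-class test counts by round-half-up —
11/11/13 test and 41 training samples for the default design. The split
method is a plain stratified random draw with an explicit seed: with no
stated reason to prefer a structured algorithm (duplex, Kennard–Stone),
the least-assumption default wins. The pipeline splits **before**
anything is fitted; censoring retention, scaling, selection and the
model are all functions of the training rows only, and a test mutating
the held-out rows verifies the fitted model is bit-identical.

## The synthetic-data generator

`simulate_flours()` emulates the study conditions the analysis assumes:
24 cricket, 24 buffalo worm and 28 mealworm samples; per-class mean
concentrations for 20 isotopes; and the characteristic censoring pattern
(boron below LOD everywhere; Se and Sr between the limits in buffalo
worms; Cr likewise in mealworms). Censored class means are placed at
LOD/2 (below-LOD) or (LOD+LOQ)/2 (between-limit) — the midpoint
conventions for values known only as bounds.

Noise is a single shared within-class coefficient of variation,
`cv = 0.10` by default: method repeatability for these elements is
roughly 0.4–7% RSD, so 10% is a conservative allowance for
between-aliquot biological spread on top of it, while still leaving the
class-mean differences of the discriminating elements (several
within-class SDs apart) intact. Draws are independent normals per
element, truncated at zero by redraw — at `cv ≤ 0.2` the truncation is
more than 5 SDs away and essentially never triggers; a lognormal would
behave identically at these CVs and was rejected as needless
complexity. Seeds are explicit function arguments everywhere; the same
design and seed reproduce a table bit for bit.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data:

* *per-element, per-class variability*: one shared CV makes an
  element's discriminating power equal to its **relative** class-mean
  spread. Under this model Mn, Na, Cr and Ba (large relative spreads)
  out-discriminate Mg univariately, whereas on real flours Mg can lead
  — real per-element variances differ. Selected element identities are
  therefore seed- and model-dependent; the classification *rates* are
  the stable, tested outcome;
* *between-element correlation*: elements are drawn independently
  within class, so the synthetic covariance structure is diagonal;
  real ionomes are correlated through diet and physiology;
* *instrumental artefacts*: no drift, no isotope interferences, no
  internal-standard correction, no matrix effects — concentrations are
  taken as delivered by a validated method.

## Problem sizes and numerical tolerances

The test suite exercises: the oracle equivalence of both Wilks
statistics against brute-force scatter summation on 100 random
instances (n ≤ 30, p ≤ 4, 3 groups, relative error < 1e−10); the CovSel
first pick against exhaustive search for p ≤ 10; mean recovery of the
generator at 5 000 samples per class within 2%; the LOD estimator over
200 six-blank replicates within 10% (the sample SD of six values is
biased low by about 5%, which the tolerance absorbs); and full-pipeline
determinism and leak-freedom on the default 76-sample design. PCA
reconstruction uses a 1e−10 Frobenius tolerance.

## Limitations

* The LDA is strictly linear: no regularized or quadratic variants, so
  panels with p approaching the per-fold training size will hit
  singularity errors rather than shrinkage.
* The censoring policy is substitution-based; no likelihood-based
  treatment of censored values (e.g. Tobit-style) is attempted.
* No outlier rejection: PCA is for looking, and what you see is what
  the classifier gets.
* The default subset-size cap (`max_vars = min(p, 10)`) is a parsimony
  guard, not a tuned constant; raise it for panels where larger models
  are plausible.
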