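---
title: "Authenticating PDO wines from elemental profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating PDO wines from elemental profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winauth)
```

## The setting

A control laboratory receives a bottle claiming a Protected Designation of
Origin and must decide whether the claim is credible.  The evidence is a
multi-element concentration profile (mg kg⁻¹ on the evaporated-concentrate
scale) over a 16-element panel, with per-element limits of quantification
(LOQ) and detection (LOD): values between LOD and LOQ are numeric but
censored, values below LOD are missing.  Reference sets are small — four
to twelve retail bottles per PDO — so every validation statistic in this
package is built for the small-*n* regime: leave-one-out sensitivity,
non-member specificity, and accuracy, all derived from explicit confusion
counts.

## Data model and preprocessing

`element_matrix` keeps three aligned layers (values, expanded
uncertainties, censor flags).  Before any model fit, `prepare_training()`

1. restricts to the declared variable subset,
2. mean-imputes missing (below-LOD) cells with the fitting set's element
   means, recording the mask — censored-but-numeric values enter as-is,
   since even below-LOQ levels can carry discriminating information,
3. drops elements that are constant within the fitting set (e.g. an
   element wholly below LOD inside one class), and
4. autoscales to zero mean and unit variance.

In prediction mode the stored imputation means and scale parameters are
applied, so a held-out sample never influences its own preprocessing.
Imputation by the class mean understates within-class variance when
censoring is heavy; the mask is kept so users can audit how much of a
model rests on imputed cells.

Variable screening offers the two rules the two model families use:
`elements_above_loq()` keeps elements with at least one uncensored value
("in all or in some samples" — the permissive reading, which retains
partially censored elements whose upper tail is informative), and
`significant_elements()` runs two-sample pooled-variance Student *t*-tests
per element at α = 0.05.  No multiple-testing correction is applied: the
subsets feed discriminant models, where an occasional false-positive
element adds noise but no bias, and correction would starve the
two-category models of variables at these sample sizes.  Welch and
log-scale variants sit behind flags; the default tests raw concentrations.

## The multivariate engines

All engines are NIPALS implementations (successive rank-1 deflation),
the algorithm family that tolerates the imputed-and-masked missingness
pattern and reproduces the behaviour of the chemometrics software lineage
this protocol comes from.  Numerical conventions:

* convergence: relative change in the loading/weight vector below 1e-9,
  iteration cap 10 000; a component that cannot converge raises an error
  in PCA and truncates the model in PLS (a non-converging PLS component
  means the Y-residual carries no extractable X-covariance);
* sign: each loading's largest-magnitude entry is made positive, so
  results are reproducible across platforms;
* ties in classification: `predict.plsda()` assigns the argmax of the
  predicted dummy responses; an exact tie is flagged and resolved to the
  first class in model order — deterministic and auditable.

**SIMCA.**  One PCA per class on its own autoscaled submatrix.  Class
membership is decided by DModX, the residual distance to the class model
normalised by the pooled training residual standard deviation *s₀*
(degrees of freedom (n−A−1)(p−A)), against the F-based critical value
`sqrt(F₀.₉₅(p−A, (n−A−1)(p−A)))`.  The score-space Mahalanobis distance to
the centroid with the Hotelling-T² limit is available as an alternative
acceptance statistic (`statistic = "mahalanobis"`); DModX is the default
because distance-to-model in residual space is what the established SIMCA
software computes, and the proprietary "PS+" reweighting of that software
is deliberately not reproduced.  When a class model fits its training
data exactly (s₀ = 0), an observation in the component plane is at
distance 0 and anything off-plane is rejected.

**Hotelling T².**  T² = Σₐ tₐ²/λₐ with the new-observation limit
`A(n−1)(n+1)/(n(n−A)) F₀.₉₅(A, n−A)`.  Monte-Carlo checks in the test
suite confirm both limits achieve nominal coverage (95 % ± 3 and
5 % ± 2) for training sets of 500 draws from a latent-factor model with
well-identified components; with 5–12 samples per class the DModX limit
is conservative — held-out members are rejected more often than 5 % —
because the scaling and loadings are estimated from very few samples.
This is visible in the SIMCA benchmark's low sensitivities and is a
property of the method at these class sizes, not a calibration defect.

**Component counts.**  No component count is prescribed by the protocol,
so the package treats it as a convention: level models default to 2
components (capped at min(n−2, p)), and `choose_ncomp()` offers a
cross-validated rule — leave-one-out PRESS for PLS, element-wise deletion
with missing-tolerant NIPALS for PCA — retaining components while each
improves cumulative Q² by more than 0.01, floor 1.

**Ward clustering.**  `ward_cluster()` implements minimum-variance
agglomeration via the Lance–Williams recurrence; heights are the exact
within-cluster sum-of-squares increases, merges are `hclust`-compatible,
and the display order puts the larger subtree first.  The test suite
checks the full linkage against brute-force agglomeration.

## The consecutive classification cascade

`run_cascade()` executes an ordered list of levels (default study
configuration: country → region-within-country → PDO-within-region for
reds; PDO-within-country for whites, since whole-country models make no
sense when each white region hosts a single PDO).  Per level and scope:

1. **Eligibility.**  Classes need at least `min_class_size = 5` samples
   ("more than four").  At PDO levels a level can pool unclaimed wines
   and sub-floor PDOs into a "Rest" category (enabled for the Toscana
   reds, where Rest gathers the non-PDO wines plus the one- and
   two-bottle PDOs); elsewhere sub-floor classes are simply not modelled
   and their samples keep whatever status they earned at earlier levels.
   A scope with fewer than two eligible categories is skipped.
2. **Outlier exclusion** (PDO levels): per class, samples beyond the
   95 % Hotelling-T² limit of a class PCA are excluded once, before any
   model is fitted, mirroring the manual exclusion of a wine projected
   clearly outside the confidence ellipse.
3. **Leave-one-out classification.**  Each sample is predicted by a
   PLS-DA fitted on the others.  Multi-category models use all elements
   (discriminant analysis exploits even below-LOQ contrasts);
   two-category models use only the significantly different elements —
   both the significance tests and the scaling are recomputed without
   the held-out sample, a stricter leakage rule than the protocol states
   (it is silent), chosen for honest cross-validation.
4. **Rescue.**  A sample misclassified by a multi-category model gets a
   dedicated two-category model (label class vs predicted class,
   significant elements only).  With zero significant elements the
   rescue is skipped and the first verdict stands.  Two-category level
   models get no rescue — it would refit the same pair.
5. **Threshold overrides.**  Declared expert rules
   (`threshold_rule("Mn", 1, "greater", c("Bierzo", "Ribera del Duero"),
   "Bierzo")`) re-adjudicate within their class pair.  Comparators are
   strict: equality at the boundary leaves the model prediction standing,
   since the protocol defines behaviour only above and below the
   threshold.  A below-LOD value is decidable whenever the threshold is
   at or above the element's LOQ (the value is certainly below it); this
   extension keeps the rule usable exactly where censoring bites, and
   without LOQ context a missing value leaves the rule unapplied with a
   warning.
6. **Elimination.**  Samples whose final verdict still contradicts the
   label are counted as false negatives of their label class at that
   level and removed from all deeper levels — a mislabelled (or
   fraudulent) bottle must not contaminate deeper class models.

Every sample ends in exactly one terminal status — `confirmed`,
`eliminated_at_<level>`, `excluded_outlier`, or `not_classifiable`
(no eligible model at any level) — and the full per-level trace is
returned.  `cascade_accuracy()` reports the confirmed fraction among
samples that entered at least one model; exclusions and eliminations
count against it, never-eligible samples are outside the denominator.

## What the synthetic generator emulates — and what it does not

`study_config()` reproduces the survey design: 20 PDOs in three
countries with the published class sizes (77 reds, 35 whites, one PGI
red, six non-PDO Toscana reds forming the natural Rest pool), the
16-element panel, and the published qualitative contrasts — Ni and Rb
higher in whites and eight elements higher in reds; the La Rioja vs
Castilla y León region contrast carried by Mn, Zn, Rb, Sr, Ba; a Mn-rich
Bierzo (above 1 mg kg⁻¹) against a Mn-poor Ribera del Duero (below LOQ,
partly below LOD, so all three censoring regimes occur).  Concentrations
are multivariate log-normal: strictly positive and right-skewed, with
class shifts additive on the log scale and a single within-class log-sd
of 0.15 per element.  Baseline levels follow the physiological ordering
K ≫ P, S, Mg, Ca > Cl > Fe, Rb, Sr > trace elements; the exact values
are free parameters, as the study's raw tables are not published.  LOD
defaults to LOQ/3.

Deliberately not simulated: element–element correlations within a class
(the covariance is diagonal on the log scale), vintage and variety
effects, measurement-uncertainty heteroscedasticity beyond a constant
10 % relative expanded uncertainty, the evaporation/pre-concentration
step, and any instrument physics.  Passing tests on this generator
therefore demonstrate that the pipeline recovers nested class structure
under censoring at realistic sample sizes — not that real wines of these
PDOs are separable; with real data the within-class correlations and
label errors the generator omits will matter.

`shift_scale` multiplies every class shift: 1 is the realistic default,
2 is the "strong separation" regime used by the end-to-end recovery
test (the acceptance criterion asks for strong class shifts), 0 removes
all class structure, and the test suite checks that accuracy falls
monotonically to the no-information rate as the dial goes to zero.
Within-PDO variances are unknown in the source material; the defaults
were chosen once for test separability, not realism.

## Validation conventions

Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
(TP+TN)/total.  Ratios with zero denominator are reported as undefined
(`NA`), never as 0.  Display percentages round half-up to integers, the
reporting style of the field's tables; full-precision values are always
stored alongside.  The SIMCA specificity pool is same-colour wines by
default (benchmark tables are split by colour); pooling across colours
is available.  Averages across class models are unweighted (each model
counts once, regardless of size), with sample-weighted means reported
alongside.

Problem sizes used by the stochastic checks: coverage uses training sets
of 500 and 5 000/10 000 evaluation draws; the cascade monotonicity check
averages 20 seeds per shift level on the 112-sample mimic.

## Known limitations

* DModX acceptance is conservative for classes of 5–12 samples (see
  above); SIMCA sensitivities on the mimic run below the nominal 95 %
  acceptance by a wide margin, matching the qualitative finding that
  SIMCA performs poorly in this regime.
* The cascade's country classes are multimodal mixtures of region and
  PDO signatures; even under strong shifts an occasional borderline
  sample is eliminated at the country gate.  This mirrors the behaviour
  of the protocol on real data and is why elimination, not silent
  misclassification, is the designed outcome.
* Threshold rules are user-declared, never learned; discovering them
  post hoc on the same data would be circular.
* No VIP scores, no OPLS, no ROC machinery — outside the protocol's
  scope.
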