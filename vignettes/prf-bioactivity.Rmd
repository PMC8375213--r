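---
title: "Modelling bioactivity with probabilistic labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bioactivity with probabilistic labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfbio)
```

## The measurement-error model

Public bioactivity repositories report potencies as pActivity values
(−log10 molar IC50/EC50/Ki/Kd). Replicate measurements of the same
compound–target pair disagree, and the disagreement grows with how
aggressively data are pooled: replicates within one assay typically differ
by a few hundredths of a log unit, replicates pooled across assay protocols
or across measurement types by 0.2–0.5. `replicate_sd()` quantifies this on
any activity table, grouping by a configurable key set. Three presets mirror
common pooling choices: `intra_assay` (compound, target, assay id),
`cross_assay` (compound, target) and `intra_measurement_type` (compound,
target, measurement type). The sample standard deviation (n − 1 denominator)
is the default estimator, with a population-denominator option; the package
deliberately exposes both because published summaries of replicate spread do
not always state their convention.

Given a threshold t and an error sd σ, the probability that a compound with
measured potency p is truly active is modelled as the normal CDF
Φ((p − t)/σ). This is the maximum-entropy choice when only a mean and
variance are credible, and it assumes **homoscedastic** error — one σ for
the whole table. That assumption is explicit and wrong in detail for real
repositories (error varies by assay and potency range); a per-sample σ can
be emulated by calling `delta_y()` per stratum, but the fitted object
records a single `label_config`. At σ = 0 the conversion is the step
function, with equality at the threshold mapping to *active* — the
"pActivity at or above threshold" convention used when curating activity
calls. σ > 0 renders the equality case irrelevant (the label is exactly
0.5 there).

## The probabilistic forest

The learner consumes, per sample, a class-probability pair
(p_A = Δy, p_B = 1 − Δy) instead of a class. Three quantities drive tree
construction:

* node class probabilities: reach-weighted averages
  P̄_A = Σ πᵢ p_{i,A} / Σ πᵢ (`weighted_class_probs()`), where πᵢ is the
  probability that sample i reaches the node;
* node impurity: Ḡ = 1 − (P̄_A² + P̄_B²) (`modified_gini()`);
* split cost: the π-mass-weighted average of the two children's impurities
  (`split_cost()`).

With binary labels and deterministic features π ∈ {0, 1}, and all three
reduce to the textbook class-fraction Gini machinery, so a soft fit with
Δy ∈ {0, 1} and a hard fit are *identical* forests given the same seed —
a property the test suite asserts on fitted trees, not just on formulas.

Randomisation follows the conventional forest recipe: bootstrap resampling
per tree (on by default) and a uniformly drawn feature subset per node
(`max_features`, default ⌈√p⌉). Neither the ensemble size nor depth limits
are prescribed by the method itself; the defaults (100 trees, unlimited
depth, `min_samples_split` 2) are the conventional classification defaults
and are all configurable.

### Splitting conventions and tie rules

Features are binary fingerprint bits, split at 0.5: value 0 routes left, 1
right. Candidate features are evaluated in increasing feature id and a
split is accepted only when its cost is *strictly* below the node impurity;
ties on cost therefore resolve to the lowest feature id, making fits
reproducible across platforms. A node becomes terminal on purity
(Ḡ < 1e−12), on `min_samples_split`/`max_depth`, or when no candidate
strictly improves.

### Feature uncertainty and `keep_proba`

The propagation contract accepts per-feature Gaussian uncertainty (`dx`):
the mass sent right is Φ((x − 0.5)/dx), so a sample can reach several
leaves. Branches whose mass falls below `keep_proba` (default 0.05) are
pruned and the surviving mass renormalised, so predicted class-probability
pairs always sum to 1; if pruning would drop both children, the higher-mass
child survives, so a prediction is never empty. Chemical fingerprints do not
come with error bars, so `dx` defaults to 0 everywhere — π is then exactly
0 or 1, `keep_proba` is inert, and each sample reaches one leaf per tree.
The parameter is retained because it bounds runtime whenever feature
uncertainty *is* supplied. Whether mass should be renormalised after pruning
is a genuinely open convention; renormalisation was chosen so the
normalisation invariant holds exactly rather than approximately.

π is tracked in linear (not log) space: with `dx = 0` underflow is
impossible, and otherwise `keep_proba` bounds the smallest representable
branch mass.

### Prediction outputs

The primary output is the forest mean of per-tree probability-weighted leaf
probabilities. The fraction of trees voting for the active class and the
across-tree dispersion are reported alongside, as both are common
prediction-confidence heuristics for forests; they are secondary summaries
of the same per-tree matrix, which is attached to every prediction object.

## Benchmarking statistics

The evaluation target is the *ideal label*: the soft label of a test
compound under the test-set label configuration. Error margin is the signed
difference ideal − predicted. The margin delta between the baseline and
probabilistic forests is algebraically the difference of their predicted
probabilities — asserted to 1e−12 in the tests rather than trusted. The
relative score expresses an improvement as a percentage of the worse
classifier's *absolute* error: at an ideal label of 0.65, improving 0.75 to
0.70 scores 50% while improving 0.85 to 0.80 scores 25%. The absolute-error
denominator is the only reading that reproduces those reference
percentages, and it is applied uniformly, including when the two classifiers
err on opposite sides of the ideal label (the sign information is preserved
in the per-sample records).

`run_sigma_grid()` crosses training σ with test σ: per training level it
fits one probabilistic and one hard-label forest on identical compounds and
hyperparameters, then per test level recomputes ideal labels and summarises
margins within ideal-label bins (default the five bands 0–0.2 … 0.8–1.0,
left-closed, right-open, last closed). The per-cell "better algorithm" is
the smaller mean absolute margin, with exact equality reported as a tie —
a deliberate, if unlikely, convention. Comparisons between margin
distributions report a one-sample KS statistic against a normal with the
sample's own mean/sd, followed by a Welch (unequal-variance) t-test; the
normality check is reported but never gates the t-test, because the test
sequence is fixed, not adaptive.

## The synthetic generator

`generate_bioactivity()` emulates the statistical structure the method
assumes, not chemistry:

* **Latent potencies** per class come from a two-component truncated-normal
  mixture: a well-separated mode 1.5 log units from the threshold (sd 0.8)
  and a marginal mode centred at the threshold (sd 0.4), mixed with weight
  `near_threshold_weight` (default 0.35). The marginal component exists
  because the regime of interest — labels near 0.5 — must be populated on
  demand; `near_threshold_fraction()` verifies a spec's band occupancy.
  A marginal-heavy profile (`near_threshold_weight = 1`, σ_experimental
  0.1, labels at σ = 1.0) places ≈ 0.6 of labels in the 0.3–0.6 band,
  emulating a target whose reported data cluster at the decision boundary.
* **Observed potency** = latent + N(0, σ_experimental); the default 0.3 is
  the canonical cross-assay error magnitude.
* **Features**: the first `n_informative` bits are Bernoulli with a rate
  that rises logistically with latent potency (0.1 → 0.85 across the
  potency range) — the simplest monotone, learnable planted signal on
  binary features; remaining bits are Bernoulli(0.2) noise, fingerprint-like
  sparsity.
* **Putative inactives** are drawn from a sparse Bernoulli(0.05) background
  and rejection-filtered to Jaccard similarity < 0.4 against every active,
  mirroring sphere-exclusion selection at the structural level only. The
  attempt budget is 200 × the requested count; exhausting it raises an
  error advising a looser cutoff or more features rather than silently
  under-delivering. Putative inactives carry no measurement and receive
  Δy = 0 at every σ.
* **Default condition** (700 compounds): 200 actives, 300 measured
  inactives, 200 putative inactives — an active:inactive ratio of 0.4,
  the typical imbalance of curated per-target bioactivity sets.

What the generator does *not* emulate: real fingerprint bit correlation
structure, heteroscedastic assay-specific noise, censored/qualified
measurements, or the true potency distributions of any particular target.
Passing tests on this generator demonstrate the algorithmic properties
(degeneracy, calibration near the threshold, constraint satisfaction), not
real-data performance.

## Numerical and scale choices

* Labels are computed in double precision via the normal CDF and stored
  unclipped — exact 0 and 1 are legitimate label values; any downstream
  log-based metric should clip to [1e−12, 1 − 1e−12] at the point of use
  rather than expect pre-clipped labels.
* All forest determinism flows from a single integer seed through R's RNG
  (bootstrap indices and feature subsets included), so identical inputs
  give bit-identical forests; fitting restores the caller's RNG state.
* CSV outputs from the command line format floats with 6 significant
  digits — stable diffs, and more precision than any reported quantity
  requires. Model files are versioned serialized containers whose
  round-trip reproduces predictions bit-exactly.
* Benchmark and equivalence checks in the test suite run at deliberately
  modest sizes — forests of 10–100 trees on a few hundred compounds,
  exhaustive split enumeration on ≤ 8-sample datasets, five-seed trend
  checks — sizes at which every assertion is exact or statistically stable
  while the whole suite completes in well under a minute.

## Known limitations

* Two classes only; no regression mode.
* One homoscedastic σ per fitted model.
* Binary features only; the 0/1 routing convention is fixed.
* The feature-uncertainty hook is implemented and tested but has no
  principled default for fingerprints — it is an extension point.
* Relative scores aggregate absolute errors and therefore discard which
  side of the ideal label a classifier errs on; consult the signed margins
  when direction matters.
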