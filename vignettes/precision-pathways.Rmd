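---
title: "Multi-platform precision pathways: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-platform precision pathways: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precpath)
```

## The diagnostic model

`precpath` turns the usual binary classification problem into a ternary
one — positive, negative, or *uncertain* — and chains platforms together so
that uncertainty at one stage is resolved by collecting more data at the
next. Three ingredients define the model.

**Per-platform ensembles.** For each platform, an *r*-repeat, *k*-fold
stratified cross-validation is run (`run_repeated_cv()`). In every repeat
and fold the feature count is tuned by an inner 2-fold cross-validation on
the training folds only, the top features by absolute Welch *t* statistic
are selected, a diagonal linear discriminant (DLDA) model is fitted, and
the held-out fold is predicted. Each patient collects exactly *r*
out-of-sample votes per platform. DLDA assumes class-conditional Gaussian
features with a shared diagonal covariance — a deliberately high-bias,
low-variance choice that behaves well with few samples and many features,
which is the regime multi-omics cohorts live in. Two folds are used by
default because halving the training set makes the fold models more
diverse, which is what gives the vote distribution its resolution.

**Confidence.** If a patient's votes split $p : 1-p$, the confidence score
is $2\,|p - 0.5|$: 1 for unanimity, 0 for an even split. A 50–50 majority
tie is resolved uniformly at random from a dedicated seeded stream, so the
tie-break can never perturb fold randomness. With $r$ votes the attainable
scores are exactly $\{2|m/r - 0.5| : m = 0, \dots, r\}$; with the default
$r = 50$ the grid step is 0.04, so the default threshold 0.9 behaves
identically under $\geq$ and $>$ semantics. We implement "exceeds the
threshold" as `confidence >= threshold`, which makes threshold 1 mean
"classify on unanimity", threshold 0 classify everyone at stage one, and
any value above 1 defer everyone to the final platform.

**Routing and evaluation.** `construct_pathway()` walks each patient along
the platform sequence, classifying at the first stage whose confidence
clears the threshold and forcing the final platform's majority class
otherwise. `evaluate_pathway()` reports accuracy, balanced accuracy
(arithmetic mean of sensitivity and specificity), F1, sensitivity,
specificity and precision with respect to a configured positive class,
together with the cumulative monetary cost (each patient pays for every
platform consumed on their route) and the raw assay count — both are
reported because unit costs are context-dependent while assay counts are
not. `compare_pathways()` evaluates every ordering compatible with the
fixed leading tiers and aggregates ranks: rank 1 is the highest balanced
accuracy and the lowest cost, exact ties receive average ranks, and the
score is the weighted mean of ranks (lower is better). Rank aggregation is
used instead of a weighted sum of raw criteria so the score is invariant to
the units and scale of the cost column.

## Parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `confidence_threshold` | 0.9 | score in [0, 1] | strict enough that only near-consensus patients stop early; on the $r=50$ grid it means $\geq$ 45 of 50 votes agree |
| `fixed_tiers` | 1 | leading platforms | clinical data is conventionally always collected first |
| `weights` | (0.5, 0.5) | accuracy, cost | equal weighting when no health-economic prior exists |
| `folds` (*k*) | 2 | ≥ 2 | maximal model diversity per repeat; keeps both classes trainable under stratification |
| `repeats` (*r*) | 50 | ≥ 1 | a 0.04-step confidence grid; vote fractions stabilize |
| `feature_counts` | 10–100 by 10 | features | spans sparse to dense panels; tuned per training fold |
| `selector` | Welch *t* | — | robust to unequal class variances; the pooled variant differs negligibly in ranking |
| `classifier` | DLDA | — | see above |
| `seed` | 1 | integer | every source of randomness derives from it |

`preprocess_assay()` drops features missing in more than 50% of samples and
imputes the rest with a *k*-nearest-neighbour mean (default 5 neighbours,
Euclidean distance averaged over mutually observed features). The
neighbour count and metric are our documented defaults, not an inference
about any upstream pipeline; both are recorded in the run configuration.

## Transfer to external cohorts

When the training and deployment cohorts measure the same analytes on
different technologies (count-based sequencing vs fluorescence arrays, for
example), raw feature values are not comparable but within-patient ratios
largely are. `transfer_pipeline()` therefore:

1. scales each sample to a common library size (counts-per-million style;
   skippable for intensity data),
2. restricts both cohorts to common features,
3. optionally filters training features by across-sample SD (the cutoff —
   e.g. SD > 5 — is per-platform configuration, mainly to keep the pair
   count manageable on large panels),
4. expands the $m$ features into all $\binom{m}{2}$ pairwise natural-log
   ratios, dropping pairs whose *training* SD is below 0.1 and freezing the
   pair list in a portable `logratio_spec`,
5. standardizes each patient's vector to mean 0, variance 1 — patient-level
   so that no training statistics travel with the model, and
6. trains the frozen ensemble (`train_full_ensemble()`, all $r \cdot k$
   fold models; no refit on the full cohort) and applies it unchanged to
   the external cohort ($r \cdot k$ votes per external patient).

Design points that were genuinely open: the log base (natural), the
pseudocount (default 0 for strictly positive intensities; set 1 for
zero-inflated counts — after library-size normalization the choice does not
affect scale invariance), and the order of operations — we drop low-SD
pairs first and standardize over the retained pairs, since standardizing
over pairs that are then discarded would let removed features influence the
kept ones. External processing applies the frozen spec verbatim and never
recomputes retention. End to end, multiplying any external sample's raw row
by a positive constant changes no route and no prediction.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the method is designed for:
multiple platforms of differing dimensionality, a binary outcome with
configurable balance, and *platform-specific resolvable subpopulations* —
each platform designates the fraction of patients whose classes its
informative features separate (by `effect_size` noise-SD units,
symmetrically around the feature baseline). Intensity platforms are
class-conditional Gaussians; count platforms exponentiate the latent
Gaussian and add per-sample library-size variation, matching the DLDA
working assumptions so that parameter-recovery tests are meaningful.
`generate_external()` redraws from the same structure and applies
per-sample positive scale factors and partial feature-name overlap,
emulating a technology shift.

One generator choice deserves emphasis. Votes for a *fixed* patient vary
only through fold-to-fold model variability, so a patient whose
discriminant margin is large relative to that variability receives
*consistent* votes — and hence high confidence — even when their data carry
no class signal. If off-subpopulation patients were given full-variance
noise on another platform's informative features, many of them would sit
far from the decision boundary by chance and be confidently (and
arbitrarily) classified at the wrong stage. The generator therefore places
off-subpopulation patients at the class midpoint of informative features
with reduced spread (`ambiguity_sd_frac`, default 0.25 of the noise SD),
keeping their margins inside the fold-noise band so their votes genuinely
split. This is the mechanism that makes stage occupancy track the
subpopulation fractions, which is the generator's documented contract. The
reference simulation (the spec defaults) is 200 patients, balanced classes,
two 100-feature platforms with 10 informative features at effect size 8,
resolving 60% and 40% of the cohort.

What the generator does *not* emulate: feature correlation structure,
batch effects, missingness mechanisms, label noise, or the marginal
distributions of any real assay. Tests passing on synthetic cohorts
demonstrate the correctness and calibration of the machinery under its own
assumptions — not clinical performance on real data.

## Numerical conventions

- Pooled DLDA variances are floored at $10^{-8}$ times the mean feature
  variance (falling back on the squared class-mean separation when every
  feature is within-class constant), so constant features cannot produce
  infinite discriminants; data that are entirely constant raise an error.
- Exact discriminant ties go to the first-listed class (alphabetical),
  deterministically. Exact feature-ranking ties keep feature order. Tuning
  ties go to the smaller feature count (parsimony). Tied rank scores fall
  back to lower cost, then lexicographic sequence order.
- All randomness — fold assignment, inner tuning splits, tie-breaks,
  synthetic draws — derives from the configured seed; runs are
  bit-reproducible, and the tie-break stream is independent of the fold
  stream.
- Folds are stratified by class (the natural reading of a random split
  would allow one-class training folds at $k = 2$ under imbalance, which
  leaves the *t* statistic and DLDA undefined).

## Problem sizes

Unit and property tests run on cohorts of 8–60 patients with 3–10 repeats;
the end-to-end behavioural checks use the 200-patient reference simulation
at the full default configuration (50 repeats) over 5 seeds, and the
transfer checks 40-patient train/external pairs. These sizes were chosen so
the entire suite completes in well under a minute on one core while still
exercising every code path at the default parameter values.

## Limitations

- Only two-class outcomes are supported; prognosis-style endpoints must be
  dichotomized upstream.
- One ordering serves the whole cohort: there is no per-patient adaptive
  platform choice, and the same per-platform ensemble serves every stage,
  so subpopulations that would profit from stage-specific models are not
  captured.
- Platform integration in the merged baseline is plain concatenation; no
  multi-view or batch-correction methods are included.
- DLDA is the only classifier on the package's surface; the internal
  architecture would admit others, but none are exposed or tested.
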