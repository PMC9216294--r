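---
title: "ventwatch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventwatch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventwatch)
```

`ventwatch` predicts the onset of invasive mechanical ventilation (IMV)
in hypoxemic ICU patients, hours before it happens, from irregularly
sampled vitals and laboratory time series. This vignette is the
package's own account of its methods: the data model, the windowing and
featurization scheme, the classifier and its transfer-learning
adaptation, the evaluation battery, the feature analyses, and the
synthetic cohort generator the whole pipeline is exercised on — together
with the numerical choices that were genuinely open and how they were
resolved.

## The prediction problem

One hospital stay is a `PatientStay`: timestamped chart events
(`feature_id`, hours since admission, value), static demographics, and
IMV on/off intervals. Hours are half-open, 0-based bins `[h, h+1)`; an
event at exactly time `h` belongs to bin `h`. From the IMV intervals
every hour gets one of four ventilation states: **ONSET** (active now,
not the hour before), **STAY_ON**, **WEAN** (inactive now, active the
hour before) and **STAY_OFF**. The number of ONSET hours equals the
number of maximal ventilation episodes; touching or overlapping
intervals are merged at load time.

A *window sample* at reference time `t` consists of the 6 preceding
hours of features. It is emitted only if the patient is IMV-free for the
whole of the feature window **and** the following gap of 6, 12, 18 or
24 h — a model that predicts ventilation for someone already ventilated,
or about to be within the gap it claims to see across, would be
answering the wrong question. The label is 1 iff an ONSET hour falls in
the 4-hour target window after the gap. The window slides once every
hour, so one true onset can label up to four positive samples; all
reported counts are therefore *window* counts, not patient counts.
Reference times stop early enough that the whole target window fits
inside the stay: onsets after discharge are unknowable, and counting
truncated target windows as negatives would mislabel censored time.

### Cohort eligibility

The cohort filter retains stays with age strictly above 15 years, length
of stay between 12 h and 10 days (inclusive), and at least one
hypoxemic measurement — PaO2 below 60 mmHg or SpO2 below 90%, both
strict — at any time during the stay. Qualification is stay-level
because hypoxemia marks the population of interest, not a feature of a
particular prediction time; restricting it to measurements before each
reference time would make cohort membership time-dependent and the
train/test unit ill-defined. Implausible measurements are *removed*
(not clipped) against per-feature registry bounds before anything else:
clipping would fabricate plausible-looking values at exactly the
physiologic extremes the model cares about.

## Featurization

Every dynamic feature becomes an hourly **triplet**: the hourly mean
value, a 0/1 presence mask, and `tsl`, the hours since the most recent
measured hour. The triplet retains the *measurement process* itself —
in ICU data, that a lactate was ordered at 3 a.m. is informative over
and above its value. For hours before any measurement `tsl = h + 1`:
monotone, bounded by the stay length, and distinct from "measured at
admission" (`tsl = 0`).

Derived respiratory indices — ROX = (SpO2/FiO2)/RR, SpO2/FiO2,
PaO2/FiO2 — are computed from the *raw* hourly means before
standardization (ratios of z-scores are physically meaningless), count
as measured only in hours where every constituent is measured and
strictly positive, and are then treated as ordinary dynamic features.

Standardization (per-feature mean/SD over *measured* hours of the
training split only) precedes imputation: measured hours carry the
z-scored value, unmeasured hours carry the last standardized observation
forward, and hours before any observation carry 0 — which is exactly the
standardized training mean, so the fallback is scale-free. Features with
fewer than two measured training hours or zero variance are flagged
constant and standardized to 0. Re-imputing an imputed grid is a no-op.

Features with fewer than `min_count` measured training hours (default
1000) are dropped entirely — splits on a variable observed a handful of
times are statistically meaningless — and clinician-set *operational*
features (ventilator settings such as set PEEP and set FiO2) can be
toggled out wholesale, producing models usable before any ventilator
data exist.

All splits are at the patient level; standardization and rare-feature
counts only ever see training-split stays.

## The classifier and its adaptation

The classifier is an XGBoost binary-logistic tree ensemble. Window-level
onset prevalence is a few percent, so the positive class is up-weighted
by `scale_pos_weight`, defaulting to the training negative/positive
ratio; weighting is preferred over resampling because it achieves the
same rebalancing without duplicating or discarding windows.
Hyperparameters (depth 3–8, learning rate 0.03–0.3 log-uniform, 50–300
rounds, row/column subsampling 0.6–1, minimum child weight 1–10) are
chosen by random search scored by AUC on a patient-level validation
carve-out. The round count is searched rather than early-stopped so the
chosen configuration is a complete, reproducible description of the
model. Training is single-threaded with an explicit seed; identical
seeds give identical tree dumps.

The validation carve-out defaults to 10% of the 80% development portion
(72/8/20 overall). A much smaller carve-out (fractions of a percent)
makes the search's scoring estimate so noisy at realistic cohort sizes
that it frequently contains a single class; 8% of stays is the smallest
round fraction that kept validation AUCs stable in our experiments.

**Adaptation.** A source model is adapted to a small target cohort by
*continued boosting*: the source trees are preserved verbatim and new
trees are fitted on the target fit portion (default 70% of target
patients), starting from the source model's raw score as the boosting
margin. The number of added rounds and the adaptation learning rate are
random-searched on a target validation subset, with the learning-rate
range deliberately conservative (0.02–0.15): on a fit set of a few dozen
patients, aggressive rates let the new trees overwrite the source signal
with noise. Crucially, the **unadapted source model is always one of the
candidates** — adaptation is a no-op unless some draw actually beats the
source model on target validation. This implements the design contract
of the two-step approach: adaptation must preserve the source model's
predictive strength, including in the limit where the target domain
matches the source and the correct amount of adaptation is none. The
result is a single ensemble (source trees followed by target trees), so
prediction, persistence and importance analysis are uniform across
source, adapted and target-only models.

The one-step ("target-only") comparator trains from scratch on the same
target fit portion, reusing the source pipeline and the source model's
feature list but fitting its own standardization — mirroring how a site
without a large archive would deploy the method.

**Feature importance** is recomputed from the tree dump as the sum over
a variable's splits of the squared split improvement (gain), normalized
to 1 — i.e. split count weighted by squared improvement — with ties
broken by manifest order. Column-level scores (feature × channel ×
in-window hour) are folded back onto base features for interpretation.
The ranking is cross-checked in the tests against the library's own gain
ranking (top-5 membership).

## Evaluation

* **AUC** is the tie-corrected pairwise statistic (midranks), verified
  against exhaustive O(n²) pair counting in the tests.
* **Decision threshold.** The alarm threshold μ is anchored at a false
  positive rate of 0.2: among observed scores satisfying FPR ≤ 0.2, μ
  maximizes sensitivity, and among those minimizes FPR. With overlapping
  score distributions this lands the achieved FPR as close to 0.2 as the
  discrete scores allow; with separable scores it spends no false alarms
  that buy no recall (FPR 0 at full sensitivity). The achieved FPR is
  always reported — the anchor is an operating-point convention, not a
  guarantee. Classification is non-strict (`probability ≥ μ`), so μ = 0
  is the all-positive classifier.
* **Fβ** uses the standard convention in which β = 0.5 weights
  *precision* above recall. Descriptions that gloss β = 0.5 as
  recall-weighted circulate in the applied literature; the formula
  `(1+β²)PR/(β²P+R)` is unambiguous and is what is implemented and
  tested, defined as 0 when P = R = 0. **MCC** is defined as 0 when any
  marginal factor is 0.
* **Precision by probability bin** partitions `[μ, 1]` (fixed edges at
  0.1 intervals, edges at or below μ discarded; last bin closed). Empty
  bins report `NA`, not 0 — an empty bin has no precision. The
  count-weighted mean of bin precisions equals overall precision above
  μ, an identity the tests enforce. This view is the package's answer to
  low overall precision under imbalance: precision climbs steeply with
  predicted probability, so the probability itself is the clinically
  actionable output.
* **Stability.** `sensitivity_auc_ci()` re-runs the entire
  split→train→test procedure over repeated patient-level splits
  (default 30; the acceptance suite uses 10) and reports a t-interval
  over split AUCs. Splits yielding single-class test sets are resampled
  with a logged fresh seed.

## The synthetic cohort generator

Real counterparts of this package's data are access-restricted, so the
generator is a first-class module that defines the study conditions for
every experiment. Per stay: a latent severity
`s(h) = frailty + drift·h + AR(1)`, with per-stay frailty (SD 0.9), a
per-stay linear deterioration trend (SD 0.03/h) and a small fast
fluctuation (AR 0.9, innovation SD 0.08); each dynamic feature is
`baseline + loading·s(h) + AR(1) noise`, observed at feature-specific
Poisson rates (1/h for vitals down to 0.06/h for slow labs); IMV onset
fires from a per-hour logistic hazard in current severity (intercept
−15, slope 5), after which the ventilation interval runs to a lognormal
extubation or discharge. Lengths of stay are 24–96 h, inside the
cohort's 12 h–10 day eligibility window.

The parameterization encodes three deliberate commitments. First,
deterioration is **trend-dominated**: persistent components (frailty,
drift) dominate the fast noise, so onsets are anticipatable many hours
ahead — matching the clinical observation that ventilation-bound
patients usually decline over many hours, and giving the synthetic task
a forecast difficulty comparable to the real one (a severity-informed
upper bound of roughly 0.9 AUC) rather than an unlearnably noisy one.
Second, the hazard intercept is calibrated so roughly 10% of stays reach
onset, between the ~50% of a general hypoxemic ICU population and the
~15% of a hospitalized COVID-19 cohort. Third, SpO2 loads negatively on
severity so deteriorating stays become hypoxemic and qualify for the
cohort filter, while a configurable fraction of never-hypoxemic stays
(default 12%) exercises the exclusion path. Respiratory rate carries the
dominant loading — deterioration toward ventilation is respiratory-led —
which is the planted ground truth behind the importance-recovery tests.
Two operational features (set PEEP, set FiO2) track severity because
clinicians escalate support as patients worsen.

The **domain shift** (`default_shift()`) moves the target cohort the way
a respiratory-virus cohort differs from a general ICU source: higher
respiratory rate with a stronger respiratory coupling to outcome, lower
heart rate and white counts with weakened couplings, higher FiO2 for the
same oxygenation (hence lower PaO2/FiO2), slightly higher blood
pressure, and a higher baseline hazard among the hypoxemic. Additive
mean shifts are enough to genuinely degrade an unadapted tree model —
tree thresholds are not shift-invariant — while leaving the signal
recoverable by adaptation.

What the generator does **not** emulate: pharmacology, interventions
feeding back into physiology, multi-episode ventilation, non-stationary
measurement rates (e.g. denser charting when staff worry), inter-feature
noise correlation beyond the shared severity factor, and real marginal
distributions feature by feature. Passing tests therefore demonstrate
that the pipeline's machinery is correct and that the two-step method
behaves as designed under controlled shift — not that the reported AUCs
transfer to any particular hospital's data.

```{r generator-demo}
coh <- simulate_cohort(sim_config(n_stays = 120, seed = 1))
coh
filtered <- filter_cohort(coh, quiet = TRUE)
filtered
head(cohort_summary(filtered), 7)
```

## Feature analyses

The lagged Pearson matrix treats every feature's value channel at each
in-window hour as a separate variable (plus statics and the 0/1 outcome,
whose correlations are point-biserial r). Constant variables get r = 0
and a flag rather than NaN. The time-ordered DAG draws an edge from
earlier-lag to later-lag variables (statics earliest, outcome latest)
whenever |r| clears a threshold — acyclic by construction, read as a
display of timeline dependencies, not a causal claim. Tier clustering
walks features in descending importance: each unassigned feature at or
above the importance floor (default 0.01, the customary display cutoff)
seeds a tier that absorbs all unassigned features correlated with it at
|r| ≥ 0.5; leftovers form a residual tier. Both cutoffs are configurable
since no canonical values exist. The importance-vs-correlation odds
ratio median-splits both rankings (⌈n/2⌉ top), cross-tabulates joint
membership, and applies the Haldane–Anscombe 0.5 correction when a cell
is empty.

## Numerical and degenerate-input choices

* Hour bins half-open, events at integer times belong to the starting
  bin; ventilation activity of hour `h` is overlap of `[h, h+1)` with
  any interval.
* Stays shorter than `feature_window + gap + target_window` yield zero
  samples (logged), not an error.
* Larger gaps never increase the emitted sample count (enforced as a
  property test).
* Importance ties break by manifest order; split-search draws and every
  booster's RNG derive deterministically from the master seed (kept
  within 32-bit range).
* Saved models are the library's canonical JSON tree dump plus a
  versioned JSON sidecar (manifest, standardization, hyperparameters,
  seeds); loading checks the format version and fails loudly on
  truncation.
* The HDF5-style hourly interchange layout is realized as a wide hourly
  CSV (`hourly-csv`); the lossless event-level format is the CSV bundle.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make the
statistical claims meaningful while remaining desk-scale: source cohorts
of 2,000 simulated stays (≈ 30–35k windows after filtering and
windowing), shifted targets of 300 stays with a 70/30 fit/evaluation
split, five seeds for the transfer and null-shift experiments, ten
repeated splits for the AUC interval, and exhaustive windowing oracles
over 100+ random stays at all four gap horizons.

## Known limitations

Probabilities are raw boosted scores, not calibrated; the precision-by-
bin table is the intended calibration surrogate. Adaptation supports
frozen source trees only (continued boosting); leaf-refresh variants are
out of scope. The generator's independence assumptions above mean
external validity must come from real data. Finally, the evaluation
counts windows, so a patient contributing many windows weighs more than
one contributing few; this mirrors how the alarm would actually fire in
deployment but differs from per-patient error rates.
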