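---
title: "Profile-routed prediction of postprandial glycemic events and bolus adjustment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-routed prediction of postprandial glycemic events and bolus adjustment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

After a meal, people with type 1 diabetes face two opposite risks inside the
same four-hour horizon: hypoglycemia when the meal bolus overshoots (or carbs
were over-counted), and hyperglycemia when it undershoots. `ppgs` implements a
dual prediction system that forecasts both risks at meal onset from the
preceding six hours of CGM data, and a bolus-adjustment layer that acts on
those forecasts before the insulin is delivered.

# Meal instances and features

Each meal becomes one instance. The preprandial window is the 72 five-minute
CGM samples ending at meal onset $m_0$ (inclusive); the postprandial window is
the 48 samples after $m_0$. Thirteen time-domain features are extracted:

* `cgm_at_meal` — glucose at $m_0$ (mg/dL);
* `mean_cgm_h1` … `mean_cgm_h6` — mean glucose over each of the six hours
  before the meal, most recent first;
* `lbgi_6h`, `hbgi_6h` — the Kovatchev low/high blood-glucose risk indices
  over the window, using the mg/dL parameterization
  $f(BG) = 1.509(\ln(BG)^{1.084} - 5.381)$, with LBGI the mean of $10f^2$
  where $f<0$ and HBGI the analogue for $f>0$;
* `excursion_60` — $BG(m_0) - BG(m_0 - 60\,\text{min})$;
* `cho` — announced carbohydrates (g);
* `meal_hour` — integer local clock hour;
* `mib` — the meal insulin bolus (U).

Windows with less than 90% coverage on either side are dropped; interior CGM
gaps of at most 15 minutes are filled linearly, longer gaps stay missing, and
boluses within ±15 minutes of meal onset are attributed to the meal. These
three rules are the package's own: the source datasets do not prescribe
window-level gap handling, and real logs jitter bolus timestamps around meal
entries.

Labels: postprandial hypoglycemia is glucose ≤ 70 mg/dL sustained for at
least 15 minutes (three consecutive samples) anywhere in the horizon.
Hyperglycemia uses two phases — ≥ 250 mg/dL in the first two hours, or ≥ 180
mg/dL in hours two to four — with the same 15-minute sustain rule applied to
both phases for a consistent event definition (the threshold pair reflects
the higher metabolic activity right after a meal). The sample at exactly
120 min opens the second phase.

# Glycemic profiling

Training instances are split into four subsets by label: hypoglycemia,
non-hypoglycemia (for system S1) and hyperglycemia, non-hyperglycemia (S2).
Within each subset a 10×10 self-organizing map is trained online (Gaussian
neighbourhood; learning rate decaying 0.5 → 0.01 and radius 5 → 1, both
exponentially; 500 epochs by default; seeded uniform-range initialisation),
and k-means (k = 3, 10 seeded restarts) clusters the 100 prototype weights.
Each cluster's centroid — the mean of its member prototypes, not of raw
instances — is stored, giving 12 behavioural-subgroup centroids (6 per
system) plus the z-scoring statistics used for all distances.

Design choices made here, where the method description leaves room:

* **Clustering vector.** The feature list counts 13 entries but the
  clustering operates on a 12-dimensional vector. We exclude `meal_hour`:
  Euclidean distance on a cyclic integer is ill-posed. A flag
  (`include_hour`) restores all 13.
* **Normalization.** One set of z statistics is fitted on the full training
  set and shared by all four subsets and both systems, so distances to all
  of a system's centroids live in a single comparable space and the
  classifiers reuse the same statistics.
* **Cluster-label feature.** Each instance carries one cluster id per system
  (0–2 event clusters, 3–5 non-event clusters); a training instance gets its
  subset-specific id, a test instance the id of its nearest centroid in that
  system. Each system's classifiers see only their own label.
* `choose_k()` reports the silhouette argmax with the elbow curve as a
  diagnostic; the default pipeline pins k = 3 and records the diagnostic.

# The dual classifier and routing

Each system trains six random forests, one per subgroup. A subgroup's
training set is its cluster's instances plus — because a subgroup is
single-label by construction and a binary classifier needs both classes —
equally many opposite-label instances nearest the subgroup centroid
(class-balanced, centroid-local negatives). This is the largest inferential
gap in the method description, which never states the negatives; "all
opposite-label instances" is available as a config option
(`negatives = "all"`).

Hyperparameters (trees 100–500, depth 3–12, min leaf 1–8) come from a
25-draw randomized search with cross-validation. MCC is the selection
criterion and also picks each model's decision threshold on out-of-fold
scores: random-forest induction cannot minimize MCC directly, so "MCC as the
loss" is realized as model- and threshold-selection. Baselines (one pooled
forest per target on the 13 raw features, no cluster feature) use Youden's J
for their thresholds instead, as described for them.

At inference the two centroids of a system nearest the instance select two
models; each votes through its own threshold; the fused vote is the logical
AND (an event is called only when both concur) and the fused continuous
score — used for ROC — is the minimum of the two probabilities, the natural
AND-consistent choice. Both selected centroids may belong to the same event
class; the distance ranking is unconstrained.

The evaluation protocol is a repeated stratified 90/10 split (20 iterations
by default; medians reported). Stratification uses the joint
(hypo, hyper) label combination so one split preserves both prevalences;
it is instance-level, mirroring the source protocol — a patient-grouped
split would be stricter against within-patient leakage and is the
recommended extension. Profiling and all training happen inside each
training split only.

# Explainability

Shapley values are computed by exact subset enumeration with the marginal
(interventional) value function: $f(S)$ is the model's mean prediction over a
seeded background sample with off-subset features replaced by background
values. The choice of the marginal convention is ours; with at most 13
features ($2^{13}$ subsets) exact mode is feasible and doubles as the oracle
for the seeded permutation-sampling estimator provided for larger feature
sets. Pairwise interaction values use the same enumeration; the returned
matrix splits each pairwise effect across its two symmetric cells with main
effects on the diagonal, so each row sums to the feature's Shapley value. The
CHO × MIB cell is exported as the headline interaction view.

LIME fits a weighted ridge regression around the instance: Gaussian
perturbations scaled by training standard deviations, proximity kernel
$\pi(x,z) = \exp(-d^2/w^2)$ on the standardized scale, and the ridge penalty
as the complexity term, with all features retained so they can be ranked.

Attributions target the deployed fused score of the two routed models by
default, so explanations refer to the prediction actually acted on; per-model
attribution is available through the same functions.

# Bolus adjustment

The standard calculator is $MIB = CHO/CR + (CGM_{meal} - CGM_{target})/CF$
with a 150 mg/dL target. When an event is predicted the dose is refined:

$$B_{mod} = MIB\,(1 + \text{adjustment factor})$$

The adjustment factor combines two logistic terms in meal glucose and the
correction factor. Taken literally on raw mg/dL arguments both sigmoids
saturate at 1 and the factor pins near +1 — doubling every flagged dose,
which contradicts the method's own safety outcomes. The default
(`mode = "normalized"`) therefore evaluates
$\sigma((CGM_{meal}-CGM_{target})/s_g) + \sigma((CF-CF_{ref})/s_{cf}) - 1$
(scales $s_g = 50$ mg/dL, $s_{cf} = 10$ mg/dL/U, $CF_{ref} = 40$): zero at
reference inputs, in $(-1,1)$, sign-correct (below-target glucose reduces the
dose). The literal form stays behind a flag for fidelity testing. This is the
package's principal deviation, flagged here deliberately.

The final gate: no predicted event delivers MIB unchanged; a hypoglycemia
prediction takes precedence over hyperglycemia; with a falling 60-minute CGM
trend (OLS slope < 0; a zero slope counts as non-falling) the dose becomes
$\alpha B_{mod} - IOB$ (hypo, $\alpha = 1.02$) or $\gamma B_{mod} - IOB$
(hyper, $\gamma = 1.01$), clamped at zero. The gains are multiplicative
uplifts — the net reduction on a falling trend comes from the insulin-on-board
subtraction, matching the stated rationale of mitigating excessive dose
reduction; whether the source formula meant multiplication cannot be
verified from the text and is noted as such. IOB itself is never defined in
the method description; we use linear decay over a 4-hour duration of
insulin action, counting prior boluses only.

# The virtual cohort and closed-loop evaluation

The simulator is a deliberately minimal 6-state glucose–insulin plant (plasma
glucose, remote insulin action, two gut compartments, two subcutaneous
insulin compartments; fixed-step RK4 at 1 min in compiled code), **not** a
reimplementation of the full meal-simulation model the study used, whose
equations are out of scope here. Its role is to exercise the pipeline
end-to-end under the stated variability scenario: 10 adults, 120 days, three
meals/day, ±20 min timing jitter, ±20% content variation, carb misestimation
drawn Normal(0, 0.2) truncated at ±0.4 ("within ±40%", read as ±2 sd), 5-min
CGM sampling with additive Gaussian noise (sd 5 mg/dL), and a sinusoidal
circadian multiplier (per-patient amplitude 0.1–0.3, random phase) on insulin
sensitivity and meal absorption — the functional form is ours; the scenario
only states that both vary circadianly. Basal insulin is implicit in the
steady-state construction: with no inputs the plant rests exactly at its
basal glucose.

Patient parameters are drawn log-uniformly from documented ranges; therapy
CR/CF derive from each patient's physiology with a log-uniform 0.8–1.25
mis-titration factor, and CR sits 10% above the fasting-derived value because
insulin action in this plant scales with ambient glucose. These ranges were
fixed once so that the open-loop cohort's overall time-in-range and
coefficient of variation bracket the reference profile of the simulated
study population (median TIR ≈ 70–80%, CV ≈ 32–44% across seeds), and were
not revisited.

Closed-loop evaluation is strictly paired: all stochastic inputs of a
patient-run (meal times, contents, misestimations, sensor noise) are drawn
up-front from the run's seed, so the "before" (standard bolus) and "after"
(full adjustment pipeline) runs face bit-identical conditions, and a null
configuration (α = γ = 1, zero adjustment factor, no IOB) reproduces the
open-loop trace bit-exactly. Outcomes are summarized as cohort
median [IQR] per phase with a paired Wilcoxon signed-rank test — implemented
with tie-averaged ranks, zero-difference exclusion, an exact
convolution-based null for n ≤ 25 and a tie-corrected normal approximation
above.

## What the stand-in plant does and does not show

Under the fixed study conditions the adjustment consistently reduces
postprandial hypoglycemia exposure (both % time < 54 and < 70 mg/dL) at the
cost of a moderate hyperglycemia increase — the qualitative trade-off the
method reports. The plant's postprandial excursions are however larger than
the reference simulator's (median postprandial % time > 180 runs in the
30–50% range versus ≈ 13% reported), so absolute postprandial hyperglycemia
levels are not comparable and the fixed 25% bound on post-adjustment
hyperglycemia exposure is not attainable on this plant; the corresponding
acceptance check is expected to fail and is retained unweakened. Passing
closed-loop tests demonstrate the pipeline's mechanics and the direction of
its effect, not clinical performance. Exercise, stress, illness, pump
dynamics and CGM drift are unmodeled.

# Evaluation metrics

Time-in-range bands follow the printed boundary conventions of the reference
tables: < 54; [54, 70]; (70, 180]; > 180; > 250 — the last two overlap as
printed, and the internal (180, 250] band completes the partition identity
that the test suite asserts. "BG excursion" in the postprandial table is
undefined at source; we use mean postprandial glucose minus the glucose at
meal onset, whose magnitude matches the printed values, and time-to-peak is
the first maximum. AUC is the rank (Mann–Whitney) statistic, cross-checked
against an $O(n^2)$ pairwise oracle; MCC uses the zero-denominator → 0
convention.

# Problem sizes in the shipped tests and acceptance script

The simulation-backed checks run at reduced scale chosen as the smallest
sizes at which every behavioural subgroup keeps enough members to train on:
cohorts of 8–10 patients × 15–30 days, protocol runs of 2–5 iterations with
3–5 search draws, and SOM training at 60–120 epochs. The planted-subgroup
harness uses three subgroups at 4 sd separation (recovery checks) and a
1.2 sd label shift with subgroup-conditional label rules (protocol
direction checks) — the regime where subgroup-local models genuinely carry
information a pooled model must work harder for. Scale parameters are all
exposed, so the full study conditions (10 × 120 days, 20 iterations, 25
draws) run unchanged via `run_config()` defaults.

# Known limitations

* The plant is a pipeline testbed, not a physiological model; its parameter
  ranges target overall glycemic brackets only (see above).
* Instance-level splitting follows the source protocol; per-patient
  generalization is not measured by it.
* The centroid-local negatives rule is an interpretation (documented above);
  subgroup-model behaviour depends on it.
* LIME explanations are local by construction and are exported as rank
  summaries; they do not measure interaction effects, which is what the
  Shapley interaction view is for.
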