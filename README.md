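# ppgs — postprandial glycemic event prediction and bolus adjustment

`ppgs` is an R package for people working on data-driven insulin dosing in
type 1 diabetes (T1D): it predicts, at meal onset, whether the next four
hours will bring a hypoglycemic or hyperglycemic excursion, explains those
predictions, and uses them to refine the meal insulin bolus before delivery.

Each meal becomes an instance described by 13 time-domain features of the
preceding 6 h of CGM data (glucose at the meal, six hourly means, the
Kovatchev risk indices LBGI/HBGI, the 60-min excursion, carbohydrates, clock
hour, and the meal bolus). The core model is a **dual profile-routed
ensemble**:

* meal instances are profiled into behavioural subgroups by a two-stage
  unsupervised step — a 10×10 self-organizing map per event-label subset,
  then k-means (k = 3) over the SOM prototypes — giving 12 stored subgroup
  centroids (6 per system);
* two systems of six random forests each (S1 for hypoglycemia, S2 for
  hyperglycemia) are trained on those subgroups, with centroid-local
  class-balanced negatives, MCC-based hyperparameter and threshold
  selection;
* at inference the two nearest centroids of a system route the instance to
  two specialized models whose votes are fused by a logical AND gate
  (fused score = min of the two event probabilities).

Around the core: exact Shapley values and pairwise interaction values
(subset enumeration, with a seeded sampling estimator as fallback), LIME
local surrogates, a minimal 6-state glucose–insulin simulator for virtual
T1D cohorts, the sigmoid bolus-adjustment algorithm
(`MIB = CHO/CR + (CGM_meal − CGM_target)/CF`, `B_mod = MIB(1 + af)`,
trend/IOB-gated final dose), and time-in-range / Wilcoxon reporting.

## Worked example

Simulate a small cohort, build the meal-instance dataset, fit the dual
system, and inspect it:

```r
library(ppgs)

scenario  <- sim_scenario(n_patients = 10, n_days = 30, seed = 42)
cohort    <- generate_cohort(scenario)            # list of patient_record
instances <- build_dataset(cohort)                # one row per meal

fit <- ppg_system(instances, seed = 1,
                  control = ppg_control(n_draws = 5, cv_folds = 3))
print(fit)
#> Dual postprandial glycemic-event prediction system
#>   fitted on 900 meal instances (seed 1)
#>   profile index: 12 centroids (k = 3 per subset)
#>   S1 (hypoglycemia): 6 subgroup RFs, median CV MCC 1.00
#>   S2 (hyperglycemia): 6 subgroup RFs, median CV MCC 1.00
```

(High in-sample CV MCC is expected here: subgroup training sets are
centroid-local and class-balanced, so they are nearly separable; held-out
performance is what `run_protocol()` measures.)

Predict both events for new meals and evaluate properly with the repeated
90/10 protocol (profiling and training re-done inside every split):

```r
predict(fit, instances[1:3, ])        # fused AND-gate votes, S1 and S2
#>      S1 S2
#> [1,]  0  0
#> [2,]  1  1
#> [3,]  1  0

res <- run_protocol(instances, n_iter = 5, seed = 7,
                    control = ppg_control(n_draws = 5, cv_folds = 3))
print(res)
#> Repeated-split evaluation (5 iterations), median metrics:
#>           model accuracy   mcc sensitivity specificity   auc
#>  baseline_hyper     78.0 0.562        78.0        84.0 0.890
#>   baseline_hypo     87.9 0.693        94.7        87.5 0.971
#>              S1     74.7 0.501        84.2        72.2 0.923
#>              S2     64.8 0.290        63.4        68.0 0.768
```

On this small, fairly homogeneous simulated cohort the pooled baselines are
competitive — profile routing earns its keep when behavioural subgroups
genuinely differ, which is what the planted-structure tests in
`tests/testthat/` verify (there the routed systems match or beat the
baselines on MCC and AUC).

Glycemic reporting and a single-meal bolus recommendation:

```r
tir_report(cohort[[1]]$trace)$pct_70_180      # % time 70-180 mg/dL
#> [1] 74.6356
rec <- recommend_bolus(fit, cgm_history = cohort[[1]]$trace$values[2:73],
                       cho = 60, meal_hour = 8,
                       therapy = cohort[[1]]$therapy)
print(rec)
#> <bolus_recommendation> MIB 11.38 U -> B_mod 9.05 U -> B_final 11.38 U (no_event)
```

No event was predicted for this meal, so the standard calculator dose is
delivered unchanged; had S1 flagged hypoglycemia on a falling trend, the
modified dose (here 9.05 U, reduced because meal glucose sits below target)
would have been delivered with the alpha uplift and insulin-on-board
subtracted.

The closed-loop evaluation runs the whole pipeline against the simulator as
plant, strictly paired (identical meal/noise draws before and after
adjustment):

```r
cl <- closed_loop_evaluate(fit, sim_scenario(n_patients = 10, n_days = 15,
                                             seed = 555))
print(cl)   # cohort median [IQR] postprandial outcomes per phase
```

On synthetic cohorts the adjustment consistently reduces postprandial
hypoglycemia with a moderate increase in time above 180 mg/dL — the intended
safety trade-off (the acceptance run below prints, for its seed, a median
postprandial % time < 54 mg/dL of 0.23 before vs 0.05 after adjustment).

`exec/ppgs` wraps the same functions for shell use
(`ppgs all --seed 1 --out runs/demo`), and `run_pipeline()` writes every
stage artifact plus a `run.json` manifest whose hashes are bit-reproducible
under a fixed seed.

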