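Package: ppgs
Title: Postprandial Glycemic Event Prediction and Insulin Bolus Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting postprandial hypoglycemia and hyperglycemia
    from continuous glucose monitoring (CGM) logs and for refining pre-meal
    insulin boluses with the resulting predictions. Meal instances are
    summarised by 13 time-domain features, profiled into behavioural
    subgroups with a self-organizing map followed by k-means on the map
    prototypes, and classified by centroid-routed random-forest ensembles
    fused through an AND gate. Exact Shapley values, pairwise Shapley
    interactions and LIME local surrogates explain the fitted systems.
    A minimal glucose-insulin simulator generates virtual type 1 diabetes
    cohorts and serves as the plant for paired closed-loop evaluation of
    the bolus-adjustment algorithm, with time-in-range reporting and
    paired Wilcoxon testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    cluster,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
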