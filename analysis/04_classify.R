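#!/usr/bin/env Rscript
# Stage 4: per-ROI MKL SVM under two-tiered leave-one-out cross-validation.
#
# Outer LOO estimates test performance; inside each outer training set the
# features are z-scaled, ANOVA-filtered (10% per ROI) and unit-normalized,
# ROIs are ranked by recursive kernel elimination, and an inner LOO selects
# (C, gamma) and the peak-region ROI counts whose classifiers vote on the
# held-out subject. Per-fold records and aggregates go to
# results/classification.json.

library(mklconn)

ft <- read_feature_table("results/features")
labels <- data.table::fread("results/labels.csv")$group

cv <- nested_loo_evaluate(ft, labels, C_grid = c(1, 10), gamma_grid = 1)
print(cv)

jsonlite::write_json(
  list(accuracy = cv$accuracy, inner_accuracy = cv$inner_accuracy,
       sensitivity = cv$sensitivity, specificity = cv$specificity,
       peak_rois_mean = cv$peak_rois_mean, peak_rois_sd = cv$peak_rois_sd,
       folds = lapply(cv$folds, function(f)
         f[c("subject", "true", "predicted", "C", "gamma", "peak_counts",
             "inner_accuracy")])),
  "results/classification.json", auto_unbox = TRUE, digits = NA)
cat("per-fold records written to results/classification.json\n")
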