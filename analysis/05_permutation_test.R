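#!/usr/bin/env Rscript
# Stage 5: balanced permutation null for the classifier.
#
# 99 balanced label permutations (class counts preserved); each is re-run
# through the outer LOO with the hyperparameters fixed from the real-label
# run and the accuracy maximized over ROI counts along the ranking — the
# deliberately conservative (positively biased) null. Writes
# results/permutation.json.

library(mklconn)

ft <- read_feature_table("results/features")
labels <- data.table::fread("results/labels.csv")$group
cv <- jsonlite::read_json("results/classification.json", simplifyVector = TRUE)

B <- 99L
perms <- balanced_permutations(labels, B = B, seed = stage_seed(1L, "permtest"))
nd <- null_distribution(ft, labels, perms,
                        C = stats::median(cv$folds$C),
                        gamma = cv$folds$gamma[1],
                        observed = cv$accuracy)
print(nd)
jsonlite::write_json(list(p_value = nd$p_value, observed = nd$observed,
                          B = nd$B, null_values = nd$values),
                     "results/permutation.json", auto_unbox = TRUE,
                     digits = NA)
cat("null distribution written to results/permutation.json\n")
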