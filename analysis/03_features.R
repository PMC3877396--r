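#!/usr/bin/env Rscript
# Stage 3: seed correlation maps and the per-ROI PCA feature table.
#
# Each motor seed's mean course is correlated with every voxel; maps are
# reduced across subjects by ROI with PCA (fixed score count per ROI,
# cohort-wide fit as in the reference procedure) and concatenated into the
# classifier's feature table, written to results/features.{csv,json}.

library(mklconn)

pre <- read_cohort("results/cohort_preprocessed")

cmaps <- cohort_seed_maps(pre)
cat(sprintf("%d seed maps per subject over %d voxels\n",
            nrow(cmaps$seeds), ncol(cmaps$maps[[1]]$maps)))

ft <- pca_reduce_maps(cmaps, k = 3)
print(ft)
write_feature_table(ft, "results/features")
data.table::fwrite(data.frame(subject = ft$subject_ids,
                              group = cohort_labels(pre)),
                   "results/labels.csv")
cat("feature table written to results/features.csv\n")
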