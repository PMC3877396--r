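#!/usr/bin/env Rscript
# Stage 2: nuisance regression, detrending and 0.03-0.06 Hz band-pass.
#
# For every subject the 16 nuisance series (6 motion + CSF + WM and their
# first derivatives) are regressed out, the series linearly detrended, and
# band-passed with a zero-phase order-4 Butterworth filter. The preprocessed
# cohort is written to results/cohort_preprocessed/.

library(mklconn)

cohort <- read_cohort("results/cohort")
pre <- preprocess_cohort(cohort)

## variance removed by the nuisance stage, as a sanity report
s <- cohort$subjects[[1]]
nuis <- build_nuisance_matrix(s$motion, s$csf, s$wm)
res <- regress_out(s$region_series, nuis)
cat(sprintf("nuisance regression removed %.0f%% of region-series variance (subject 1)\n",
            100 * (1 - mean(apply(res, 2, var) / apply(s$region_series, 2, var)))))

write_cohort(pre, "results/cohort_preprocessed")
cat("preprocessed cohort written to results/cohort_preprocessed/\n")
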