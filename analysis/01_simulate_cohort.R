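#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-group study cohort.
#
# The bundle emulates a slice-electrophysiology study of striatal large
# cholinergic interneurons in wild-type-like (WT) vs Huntington-model-like
# (HD) mice: 33 vs 39 cell-attached spike trains at 0.3-3.9 Hz with more
# regular pacemakers in WT; spontaneous IPSC-like traces (higher event rate
# and a larger action-potential-dependent fraction in HD); RC seal-test
# steps at the group-typical membrane values; and a sectioned-striatum
# sphere phantom (smaller radius in HD: atrophy with preserved cell number).
# Everything is a pure function of the seed; rerunning reproduces the same
# files byte for byte.

suppressPackageStartupMessages(library(lciphys))

seed <- as.integer(Sys.getenv("LCIPHYS_SEED", "20260927"))
out_dir <- "results/cohort"

bundle <- gen_cohort(seed = seed)
write_study_bundle(bundle, out_dir)

cat(sprintf("cohort seed %d: %d cells (%s), bundle written to %s\n",
            seed, nrow(bundle$cells),
            paste(table(bundle$cells$group), collapse = " + "), out_dir))
print(table(bundle$cells$group, bundle$cells$true_class))
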