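#!/usr/bin/env Rscript
# Stage 5: call per-CpG 5mC and 5hmC from the paired BS/oxBS amplicon
# reads (conversion-aware matching, >= 100 reads per treatment per
# replicate, 5hmC = BS minus oxBS level, clamped at 0) and average the
# two biological replicates.
library(retrosilence)

cfg <- run_config(seed = 20260922 %% 10000L, outdir = "results/demo",
                  fragment_split_prob = 0.4)
run_pipeline(cfg, stages = "oxbs")

me <- read.table("results/demo/methylation.tsv", header = TRUE, sep = "\t")
tru <- read.table("results/demo/truth_methylation.tsv", header = TRUE, sep = "\t")
m <- merge(me, tru, by = c("amplicon", "pos"))
message(sprintf("%d CpGs called; max |error| 5mC %.3f, 5hmC %.3f",
                nrow(m), max(abs(m$five_mC.x - m$five_mC.y)),
                max(abs(m$five_hmC.x - m$five_hmC.y))))
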