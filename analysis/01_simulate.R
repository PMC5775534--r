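#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a toy genome with four ERV-like
# repeat classes (an IAP-like class activated >tenfold in the depleted
# condition), RNA-seq alignments for 3+3 replicates, paired BS/oxBS
# amplicon reads with known per-CpG 5mC/5hmC, and a peak set enriched at
# the IAP-like class. All ground truth is written alongside the data.
library(retrosilence)

cfg <- run_config(seed = 20260922 %% 10000L, outdir = "results/demo",
                  fragment_split_prob = 0.4)
run_pipeline(cfg, stages = "simulate")

copies <- read.table("results/demo/truth_copies.tsv", header = TRUE, sep = "\t")
message(sprintf("planted %d copies across %d classes (%d full-length > 5 kb)",
                nrow(copies), length(unique(copies$class)),
                sum(copies$full_length)))
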