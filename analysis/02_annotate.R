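#!/usr/bin/env Rscript
# Stage 2: parse the RepeatMasker fragment table and build the merged
# element annotation (same-strand same-name fragments within 100 bp merge;
# elements spanning > 5 kb are full-length).
library(retrosilence)

cfg <- run_config(seed = 20260922 %% 10000L, outdir = "results/demo",
                  fragment_split_prob = 0.4)
run_pipeline(cfg, stages = "annotate")

el <- read.table("results/demo/elements.tsv", header = TRUE, sep = "\t")
message(sprintf("%d merged elements; %d built from split fragments; %d full-length",
                nrow(el), sum(el$n_fragments > 1), sum(el$full_length)))
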