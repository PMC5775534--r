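#!/usr/bin/env Rscript
# Stage 4: negative-binomial differential expression over class-level
# counts (median-of-ratios size factors, trend-guarded dispersions, Wald
# test); a class is called at |log2FC| > 1 and raw p < 0.05.
library(retrosilence)

cfg <- run_config(seed = 20260922 %% 10000L, outdir = "results/demo",
                  fragment_split_prob = 0.4)
run_pipeline(cfg, stages = "diffexp")

de <- read.table("results/demo/diffexp.tsv", header = TRUE, sep = "\t")
called <- de[de$call, ]
message(sprintf("%d/%d classes called differentially expressed: %s",
                nrow(called), nrow(de),
                paste(sprintf("%s (log2FC %.2f)", called$feature,
                              called$log2FoldChange), collapse = ", ")))
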