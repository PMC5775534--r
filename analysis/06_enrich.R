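#!/usr/bin/env Rscript
# Stage 6: test peak enrichment over repeat classes against 1000 shuffles
# of the peaks across the mappable genome (add-one empirical p).
library(retrosilence)

cfg <- run_config(seed = 20260922 %% 10000L, outdir = "results/demo",
                  fragment_split_prob = 0.4)
run_pipeline(cfg, stages = "enrich")

en <- read.table("results/demo/enrichment.tsv", header = TRUE, sep = "\t")
for (i in order(en$p_empirical))
  message(sprintf("%s: %d peaks observed vs %.1f expected (ratio %.2f, p %.4g)",
                  en$repeat_name[i], en$observed[i], en$null_mean[i],
                  en$ratio[i], en$p_empirical[i]))
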