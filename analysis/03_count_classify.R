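#!/usr/bin/env Rscript
# Stage 3: count reads over the merged annotation under both regimes —
# inclusive (random-primary multi-mappers, class level) and unique (copy
# level, RPM) — then apply the > 0.25 RPM detectability filter and the
# tenfold copy-activation rule (depleted vs control, 0.1 RPM pseudocount).
library(retrosilence)

cfg <- run_config(seed = 20260922 %% 10000L, outdir = "results/demo",
                  fragment_split_prob = 0.4)
run_pipeline(cfg, stages = "count")

su <- read.table("results/demo/classification_summary.tsv", header = TRUE,
                 sep = "\t")
for (i in seq_len(nrow(su)))
  message(sprintf("%s: %d/%d detectable copies >tenfold up (%s%%)",
                  su$repeat_name[i], su$n_up[i], su$n_detectable[i],
                  su$percent_up[i]))
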