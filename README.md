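# retrosilence

Quantifying retroelement (ERV/IAP) activation, DNA (hydroxy)methylation
and chromatin-mark enrichment at repeats — the complete computational
chain, exercised end to end on synthetic data with known ground truth.

## The problem

Young endogenous retroviruses such as mouse IAPs are silenced by
SETDB1-dependent H3K9me3; depleting SETDB1 derepresses them. Measuring
that derepression from RNA-seq is hard because young ERV copies are
nearly identical, so short reads multi-map. This package implements, as
reusable R functions behind a small set of analysis scripts:

* **Repeat annotation** — parse RepeatMasker `.out` files; merge
  same-strand fragments of the same repeat name within 100 bp into
  elements; classify elements spanning > 5 kb as full-length
  (`parse_repeatmasker()`, `merge_fragments()`, `classify_full_length()`).
* **Two counting regimes** — *inclusive*: each read counted once at its
  primary placement, chosen uniformly at random among equally-best
  placements, per repeat class; *unique*: only single-placement reads,
  per element copy, with RPM = count × 10⁶ / library size
  (`count_by_class_inclusive()`, `count_by_copy_unique()`).
* **Differential expression** — negative-binomial Wald test written from
  first principles (median-of-ratios size factors, trend-guarded
  method-of-moments dispersions, IRLS, BH); a class is called at
  |log₂FC| > 1 and raw p < 0.05 (`nb_wald_test()`).
* **Copy-level activation** — copies with > 0.25 RPM in any sample are
  detectable; a copy is upregulated when
  (mean depleted RPM + 0.1)/(mean control RPM + 0.1) > 10
  (`filter_detectable()`, `classify_fold_change()`,
  `summarize_classification()`).
* **5mC/5hmC calling** — conversion-aware matching of BS/oxBS amplicon
  reads; per CpG, 5mC = oxBS level, 5hmC = max(0, BS − oxBS), QC at
  ≥ 100 reads per treatment (`match_amplicon_reads()`,
  `call_methylation()`).
* **Peak enrichment** — observed peak–class overlaps versus N
  length-preserving shuffles over mappable regions, add-one empirical p
  (`enrichment_test()`).
* **Synthetic data with ground truth** — a toy genome with planted
  repeat classes (including exact-copy duplicates that genuinely
  multi-map), condition-specific fold changes, BS/oxBS reads from known
  per-CpG levels, and enriched or null peak sets
  (`simulation_config()`, `build_toy_genome()`, ...).

## Worked example

The numbered scripts under `analysis/` run the demo study into
`results/demo/` (each is a thin driver over `run_pipeline()`):

```sh
Rscript analysis/01_simulate.R       # toy genome, SAM, FASTQ, BED + truth
Rscript analysis/02_annotate.R      # merged element annotation
Rscript analysis/03_count_classify.R
Rscript analysis/04_diffexp.R
Rscript analysis/05_oxbs.R
Rscript analysis/06_enrich.R
```

Output of a run:

```
planted 24 copies across 4 classes (11 full-length > 5 kb)
24 merged elements; 10 built from split fragments; 11 full-length
IAPEz: 4/4 detectable copies >tenfold up (100%)
L1MdA: 0/4 detectable copies >tenfold up (0%)
MERVL: 0/4 detectable copies >tenfold up (0%)
RLTR4: 0/4 detectable copies >tenfold up (0%)
2/5 classes called differentially expressed: IAPEz (log2FC 4.11), MERVL (log2FC 1.32)
55 CpGs called; max |error| 5mC 0.022, 5hmC 0.016
IAPEz: 253 peaks observed vs 76.3 expected (ratio 3.31, p 0.000999)
L1MdA: 11 peaks observed vs 63.4 expected (ratio 0.17, p 1)
MERVL: 21 peaks observed vs 72.6 expected (ratio 0.29, p 1)
RLTR4: 10 peaks observed vs 62.0 expected (ratio 0.16, p 1)
```

Reading this: the generator planted a 20-fold activation of the IAP-like
class and a 3-fold activation of MERVL in the "depleted" condition. The
pipeline recovers exactly those two classes in the differential call
(log₂FC 4.11 ≈ log₂20 after normalisation; 1.32 for the 3-fold class
after library-composition correction), classifies all four detectable
IAP copies (the two identical copies have no unique reads and fall below
the 0.25 RPM filter) as more-than-tenfold upregulated, calls per-CpG 5mC
and 5hmC to within ~0.02 of the planted truth at realistic conversion
efficiencies, and assigns the planted peak enrichment its smallest
attainable permutation p-value, 1/(N+1).

The same classification arithmetic applied to published copy counts —
1009 IAP copies with detectable signal, of which 681 (naïve) or 257
(primed) exceed the tenfold threshold — yields 67% and 25%:

```r
summarize_classification(n_detectable = 1009, n_up = 681)$percent_up  # 67
summarize_classification(n_detectable = 1009, n_up = 257)$percent_up  # 25
```

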