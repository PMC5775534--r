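test_that("toy genome construction plants the configured fragments", {
  cfg <- simulation_config(seed = 5, n_classes = 2, copies_per_class = 3)
  sim <- build_toy_genome(cfg)
  expect_equal(nrow(sim$fragments), 6L)  # no splitting by default
  expect_setequal(unique(sim$fragments$repeat_name), c("IAPEz", "MERVL"))
  expect_equal(nrow(sim$copies), 6L)
  expect_true(all(sim$copies$end <= sim$chrom_length))
  # genome holds each copy (oriented) at its recorded coordinates
  g <- as.character(sim$genome[[1]])
  for (i in seq_len(nrow(sim$copies))) {
    got <- substr(g, sim$copies$start[i], sim$copies$end[i])
    want <- sim$copy_seqs[[sim$copies$copy_id[i]]]
    if (sim$copies$strand[i] == "-") want <- retrosilence:::revcomp_chr(want)
    expect_identical(got, want)
  }
})

test_that("same seed gives byte-identical FASTA; divergence 0 gives identical copies", {
  cfg <- simulation_config(seed = 11, n_classes = 2, copies_per_class = 3)
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(build_toy_genome(cfg), f1)
  write_genome_fasta(build_toy_genome(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg0 <- simulation_config(seed = 3, n_classes = 2, copies_per_class = 3,
                            inter_copy_divergence = 0)
  sim0 <- build_toy_genome(cfg0)
  for (cl in unique(sim0$copies$class)) {
    seqs <- unlist(sim0$copy_seqs[sim0$copies$copy_id[sim0$copies$class == cl]])
    expect_length(unique(seqs), 1L)
  }
})

test_that("copies that do not fit a fixed chromosome are rejected", {
  cfg <- simulation_config(seed = 1, chrom_length = 1000L)
  expect_error(build_toy_genome(cfg), "fit")
})

test_that("identical copies produce exact-tie multi-mapped reads", {
  cfg <- simulation_config(seed = 9, n_classes = 1, copies_per_class = 2,
                           inter_copy_divergence = 0,
                           library_sizes = 500L, background_fraction = 0)
  sim <- build_toy_genome(cfg)
  s <- simulate_rnaseq_alignments(sim, "A", 1)
  aln <- read_sam_alignments(write_sam_tmp(s$sam))
  expect_true(all(aln$n_placements == 2L))
  expect_equal(attr(aln, "library_size"), 500L)
})

test_that("empty library yields a header-only SAM and conditions are validated", {
  cfg <- simulation_config(seed = 2, copies_per_class = 3)
  sim <- build_toy_genome(cfg)
  s <- simulate_rnaseq_alignments(sim, "A", 1, library_size = 0L)
  expect_true(all(startsWith(s$sam, "@")))
  aln <- read_sam_alignments(write_sam_tmp(s$sam))
  expect_equal(nrow(aln), 0L)
  expect_error(simulate_rnaseq_alignments(sim, "C", 1), "arg")
})

test_that("read counts equal the library size and fold changes match the analytic oracle", {
  cfg <- simulation_config(seed = 13, library_sizes = 20000L)
  sim <- build_toy_genome(cfg)
  sa <- simulate_rnaseq_alignments(sim, "A", 1)
  sb <- simulate_rnaseq_alignments(sim, "B", 1)
  expect_equal(sum(sa$truth_class), 20000L)  # conservation, exact
  expect_equal(sum(sb$truth_class), 20000L)

  # analytic expectation: multinomial over copies + fixed background weight
  cp <- sim$copies; rl <- cfg$read_length
  w0 <- pmax(cp$length - rl + 1L, 0L)
  bg <- cfg$background_fraction / (1 - cfg$background_fraction) * sum(w0)
  wA <- tapply(w0, cp$class, sum)
  wB <- tapply(w0 * cfg$class_fold_changes[cp$class], cp$class, sum)
  pA <- wA / (sum(wA) + bg); pB <- wB / (sum(wB) + bg)
  N <- 20000L
  for (cl in names(pA)) {
    for (side in list(c(pA[[cl]], sa$truth_class[[cl]]),
                      c(pB[[cl]], sb$truth_class[[cl]]))) {
      p <- side[1]; cnt <- side[2]
      expect_lt(abs(cnt - N * p), 3 * sqrt(N * p * (1 - p)))
    }
  }
  # realized B/A ratio tracks the composition-aware expectation, and the
  # IAP-like class is planted to exceed the tenfold threshold even after
  # the composition shift from its own activation
  obs_ratio <- sb$truth_class[["IAPEz"]] / sa$truth_class[["IAPEz"]]
  exp_ratio <- pB[["IAPEz"]] / pA[["IAPEz"]]
  se_log <- sqrt((1 - pA[["IAPEz"]]) / (N * pA[["IAPEz"]]) +
                   (1 - pB[["IAPEz"]]) / (N * pB[["IAPEz"]]))
  expect_lt(abs(log(obs_ratio) - log(exp_ratio)), 3 * se_log)
  expect_gt(obs_ratio, 10)
})

test_that("bisulfite chemistry limit cases hold exactly", {
  cfg <- simulation_config(seed = 21, bs_conversion_efficiency = 1,
                           oxidation_efficiency = 1)
  amp <- "ATTCGATCTTCGAATT"  # CpGs at 4 and 11; non-CpG C at 8
  truth1 <- data.frame(amplicon = "a", pos = c(4L, 11L),
                       five_mC = 1, five_hmC = 0)
  for (tr in c("BS", "oxBS")) {
    rd <- fastq_seqs(simulate_bisulfite_reads(amp, truth1, tr, 50, cfg))
    expect_true(all(substr(rd, 4, 4) == "C"))
    expect_true(all(substr(rd, 11, 11) == "C"))
  }
  truth2 <- data.frame(amplicon = "a", pos = c(4L, 11L),
                       five_mC = 0, five_hmC = 1)
  rd_bs <- fastq_seqs(simulate_bisulfite_reads(amp, truth2, "BS", 50, cfg))
  rd_ox <- fastq_seqs(simulate_bisulfite_reads(amp, truth2, "oxBS", 50, cfg))
  expect_true(all(substr(rd_bs, 4, 4) == "C"))
  expect_true(all(substr(rd_ox, 4, 4) == "T"))
  # non-CpG cytosines are unmethylated: fully converted at efficiency 1
  expect_true(all(substr(rd_bs, 8, 8) == "T"))
  expect_error(
    simulate_bisulfite_reads(amp, data.frame(amplicon = "a", pos = c(4L, 11L),
                                             five_mC = 0.8, five_hmC = 0.4),
                             "BS", 10, cfg),
    "five_mC")
})

test_that("simulated C-fractions match the binomial oracle and the 5hmC difference law", {
  cfg <- simulation_config(seed = 23, bs_conversion_efficiency = 1,
                           oxidation_efficiency = 1)
  amp <- "ATTCGATCTTCGAATT"
  truth <- data.frame(amplicon = "a", pos = c(4L, 11L),
                      five_mC = 0.7, five_hmC = 0.1)
  n <- 10000L
  bs <- fastq_seqs(simulate_bisulfite_reads(amp, truth, "BS", n, cfg))
  ox <- fastq_seqs(simulate_bisulfite_reads(amp, truth, "oxBS", n, cfg))
  for (p in c(4L, 11L)) {
    fbs <- mean(substr(bs, p, p) == "C")
    fox <- mean(substr(ox, p, p) == "C")
    expect_lt(abs(fbs - 0.8), 3 * sqrt(0.8 * 0.2 / n))
    expect_lt(abs(fox - 0.7), 3 * sqrt(0.7 * 0.3 / n))
    # expected BS - oxBS C-fraction equals true 5hmC
    expect_lt(abs((fbs - fox) - 0.1),
              3 * sqrt(0.8 * 0.2 / n + 0.7 * 0.3 / n))
  }
})

test_that("peak simulation respects enrichment limits and is deterministic", {
  cfg <- small_config(seed = 31)
  sim <- build_toy_genome(cfg)
  expect_error(simulate_peaks(sim, n_peaks = -1), "non-negative")
  expect_error(simulate_peaks(sim, enriched_classes = "NOPE"), "planted")

  # enrichment fraction 1: every peak overlaps the enriched class
  cfg1 <- small_config(seed = 31, peak_enrichment_fraction = 1)
  sim1 <- build_toy_genome(cfg1)
  pk <- simulate_peaks(sim1, enriched_classes = "IAPEz", config = cfg1)
  iap <- sim1$copies[sim1$copies$class == "IAPEz", ]
  gr <- GenomicRanges::GRanges(iap$chrom, IRanges::IRanges(iap$start, iap$end))
  expect_true(all(GenomicRanges::countOverlaps(pk$peaks, gr) > 0))

  # null set: no planted class labels; determinism of the BED bytes
  pk0a <- simulate_peaks(sim, enriched_classes = character(0), config = cfg)
  pk0b <- simulate_peaks(sim, enriched_classes = character(0), config = cfg)
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  rtracklayer::export.bed(pk0a$peaks, f1)
  rtracklayer::export.bed(pk0b$peaks, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(pk0a$peaks == pk0b$peaks))
  expect_false(any(pk0a$truth))
})
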