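# hand-built SAM: 3 reads inside one element, 1 in none, 1 multi-mapped
tiny_sam <- function() {
  rl <- 50L
  seq <- strrep("A", rl)
  rec <- function(qn, flag, pos) sprintf("%s\t%d\tchr1\t%d\t50\t%dM\t*\t0\t0\t%s\t%s",
                                         qn, flag, pos, rl, seq, strrep("I", rl))
  c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:chr1\tLN:100000",
    rec("r1", 0L, 1100L), rec("r2", 0L, 1200L), rec("r3", 0L, 1300L),
    rec("r4", 0L, 50000L),
    rec("r5", 0L, 2100L), rec("r5", 256L, 1150L))
}

tiny_annotation <- function() {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1000L, 2000L), end = c(1600L, 2600L)))
  S4Vectors::mcols(gr)$repeat_name <- c("IAPEz", "MERVL")
  S4Vectors::mcols(gr)$copy_id <- c("IAPEz_1", "MERVL_1")
  gr
}

test_that("inclusive counting attributes primaries and conserves reads", {
  aln <- read_sam_alignments(write_sam_tmp(tiny_sam()))
  expect_equal(attr(aln, "library_size"), 5L)
  ct <- count_by_class_inclusive(aln, tiny_annotation())
  expect_equal(ct$counts[["IAPEz"]], 3L)
  expect_equal(ct$counts[["MERVL"]], 1L)  # r5's primary is in MERVL
  expect_equal(ct$unassigned, 1L)
  expect_equal(sum(ct$counts) + ct$unassigned, ct$library_size)

  # empty SAM: all-zero table
  empty <- read_sam_alignments(write_sam_tmp(tiny_sam()[1:2]))
  ct0 <- count_by_class_inclusive(empty, tiny_annotation())
  expect_true(all(ct0$counts == 0L))
  expect_equal(ct0$unassigned, 0L)
})

test_that("unique-regime counting drops multi-mapped reads", {
  aln <- read_sam_alignments(write_sam_tmp(tiny_sam()))
  cu <- count_by_copy_unique(aln, tiny_annotation())
  expect_equal(cu$counts[["IAPEz_1"]], 3L)
  expect_equal(cu$counts[["MERVL_1"]], 0L)  # r5 is multi-mapped
  expect_equal(unname(cu$rpm), unname(cu$counts) * 1e6 / 5)
})

test_that("a read on a chromosome missing from the annotation is an error", {
  sam <- c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:chr2\tLN:10000",
           sprintf("r1\t0\tchr2\t100\t50\t50M\t*\t0\t0\t%s\t%s",
                   strrep("A", 50), strrep("I", 50)))
  aln <- read_sam_alignments(write_sam_tmp(sam))
  expect_error(count_by_class_inclusive(aln, tiny_annotation()), "chr2")
})

test_that("simulated counts equal the ground-truth bookkeeping exactly", {
  cfg <- small_config(seed = 17)
  sim <- build_toy_genome(cfg)
  el <- merge_fragments(parse_repeatmasker({
    f <- tempfile(); write_repeatmasker_out(sim, f); f
  }))
  for (cond in c("A", "B")) {
    s <- simulate_rnaseq_alignments(sim, cond, 1)
    aln <- read_sam_alignments(write_sam_tmp(s$sam))
    ct <- count_by_class_inclusive(aln, el)
    truth <- s$truth_class
    expect_equal(ct$counts[names(truth)[names(truth) != "unassigned"]],
                 truth[names(truth) != "unassigned"])
    expect_equal(ct$unassigned, truth[["unassigned"]])
    expect_equal(sum(ct$counts) + ct$unassigned, s$library_size)  # exact

    cu <- count_by_copy_unique(aln, el)
    # element copy_ids are positional per class; map truth by coordinates
    key_el <- paste(GenomicRanges::start(el), GenomicRanges::end(el))
    key_tr <- paste(sim$copies$start, sim$copies$end)
    expect_equal(unname(cu$counts[match(key_tr, key_el)]),
                 unname(s$truth_unique_by_copy))

    # unique-regime class totals never exceed inclusive-regime counts
    cls_of <- S4Vectors::mcols(el)$repeat_name
    uniq_by_class <- tapply(cu$counts, cls_of, sum)
    expect_true(all(uniq_by_class[names(ct$counts)] <= ct$counts))

    # RPM conservation: features + unassigned sum to one million
    expect_equal(sum(ct$counts * 1e6 / ct$library_size) +
                   ct$unassigned * 1e6 / ct$library_size, 1e6)
  }
})

test_that("fully identical copies leave the unique-regime table empty", {
  cfg <- simulation_config(seed = 19, n_classes = 2, copies_per_class = 2,
                           inter_copy_divergence = 0, library_sizes = 1000L,
                           background_fraction = 0)
  sim <- build_toy_genome(cfg)
  f <- tempfile(); write_repeatmasker_out(sim, f)
  el <- merge_fragments(parse_repeatmasker(f))
  aln <- read_sam_alignments(write_sam_tmp(simulate_rnaseq_alignments(sim, "A", 1)$sam))
  cu <- count_by_copy_unique(aln, el)
  expect_true(all(cu$counts == 0L))
})

test_that("detectability filter is strict at 0.25 RPM", {
  rpm <- rbind(a = c(0.3, 0), b = c(0.25, 0.25), c = c(0, 0))
  keep <- filter_detectable(rpm, 0.25)
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE))
})

test_that("fold-change classification matches the stated arithmetic", {
  r <- classify_fold_change(c(x = 0.5), c(x = 6.0), fold = 10, pseudocount = 0.1)
  expect_equal(r$ratio, 6.1 / 0.6)
  expect_true(r$upregulated)
  r2 <- classify_fold_change(c(x = 2), c(x = 2), fold = 10, pseudocount = 0.1)
  expect_false(r2$upregulated)
  expect_equal(r2$ratio, 1)
  expect_error(classify_fold_change(c(x = -1), c(x = 2)), "negative")
  # matrices: means over replicates
  rm <- classify_fold_change(rbind(x = c(0.4, 0.6)), rbind(x = c(5, 7)),
                             fold = 10, pseudocount = 0.1)
  expect_equal(rm$ratio, 6.1 / 0.6)
})

test_that("classification summary reproduces printed percentages", {
  expect_equal(summarize_classification(n_detectable = 1009, n_up = 681)$percent_up, 67)
  expect_equal(summarize_classification(n_detectable = 1009, n_up = 257)$percent_up, 25)
  expect_equal(summarize_classification(rep(FALSE, 5))$percent_up, 0)
  expect_true(is.na(summarize_classification(logical(0))$percent_up))
})

test_that("a planted tenfold class is recovered at the copy level", {
  cfg <- simulation_config(seed = 29, copies_per_class = 6L,
                           library_sizes = c(20000L, 20000L, 20000L))
  sim <- build_toy_genome(cfg)
  f <- tempfile(); write_repeatmasker_out(sim, f)
  el <- merge_fragments(parse_repeatmasker(f))
  alns <- lapply(simulate_rnaseq_experiment(sim, cfg), function(s)
    read_sam_alignments(write_sam_tmp(s$sam)))
  cpt <- build_copy_count_table(alns, el)
  ctl <- grepl("^A_", colnames(cpt$rpm))
  keep <- filter_detectable(cpt$rpm, 0.25)
  cls <- classify_fold_change(cpt$rpm[keep, ctl], cpt$rpm[keep, !ctl])
  cls$class <- S4Vectors::mcols(el)$repeat_name[match(cls$copy_id,
                                                      S4Vectors::mcols(el)$copy_id)]
  iap <- cls[cls$class == "IAPEz", ]
  expect_gte(mean(iap$upregulated), 0.9)
  expect_true(all(!cls$upregulated[cls$class %in% c("RLTR4", "L1MdA")]))
})
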