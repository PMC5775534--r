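rm_header <- c("header line one", "header line two", "")

test_that("RepeatMasker parsing handles the dialect", {
  f <- tempfile()
  writeLines(c(rm_header,
    " 1203  1.0 0.0 0.0  chr1  100  700  (19300) +  IAPEz  LTR/ERVK  1 601 (0) 1",
    " 1204  2.0 0.0 0.0  chr1  900  1400 (18600) C  IAPEz  LTR/ERVK  1 501 (0) 2"), f)
  fr <- parse_repeatmasker(f)
  expect_length(fr, 2L)
  expect_equal(GenomicRanges::start(fr), c(100L, 900L))
  expect_equal(GenomicRanges::end(fr), c(700L, 1400L))
  expect_equal(as.character(GenomicRanges::strand(fr)), c("+", "-"))
  expect_equal(S4Vectors::mcols(fr)$repeat_name, c("IAPEz", "IAPEz"))

  writeLines(c(rm_header,
    " 1203  1.0 0.0 0.0  chr1  100  700  (19300) +  IAPEz  LTR/ERVK  1 601 (0) 1",
    " bad row with too few"), f)
  expect_error(parse_repeatmasker(f), "line 5")
})

test_that("planted fragments round-trip through the .out writer and parser", {
  cfg <- simulation_config(seed = 5, n_classes = 2, copies_per_class = 3,
                           fragment_split_prob = 0.5)
  sim <- build_toy_genome(cfg)
  f <- tempfile()
  write_repeatmasker_out(sim, f)
  fr <- parse_repeatmasker(f)
  expect_length(fr, nrow(sim$fragments))
  expect_equal(GenomicRanges::start(fr), sim$fragments$start)
  expect_equal(GenomicRanges::end(fr), sim$fragments$end)
  expect_equal(S4Vectors::mcols(fr)$repeat_name, sim$fragments$repeat_name)
  # merging reconstructs the planted elements exactly
  el <- merge_fragments(fr)
  expect_length(el, nrow(sim$copies))
  expect_setequal(GenomicRanges::start(el), sim$copies$start)
  expect_setequal(GenomicRanges::end(el), sim$copies$end)
})

test_that("fragment merging follows the gap/strand/name rules", {
  fr <- frag_granges("chr1", c(100, 450), c(400, 700), c("+", "+"),
                     c("IAPEz", "IAPEz"))
  el <- merge_fragments(fr, gap = 100)
  expect_length(el, 1L)
  expect_equal(GenomicRanges::start(el), 100L)
  expect_equal(GenomicRanges::end(el), 700L)
  expect_equal(S4Vectors::mcols(el)$n_fragments, 2L)

  # gap of exactly 100 merges; 101 does not
  fr2 <- frag_granges("chr1", c(100, 501), c(400, 700), c("+", "+"),
                      c("IAPEz", "IAPEz"))
  expect_length(merge_fragments(fr2, gap = 100), 1L)
  fr3 <- frag_granges("chr1", c(100, 502), c(400, 700), c("+", "+"),
                      c("IAPEz", "IAPEz"))
  expect_length(merge_fragments(fr3, gap = 100), 2L)

  # same coordinates, opposite strands: no merge
  frs <- frag_granges("chr1", c(100, 450), c(400, 700), c("+", "-"),
                      c("IAPEz", "IAPEz"))
  expect_length(merge_fragments(frs), 2L)

  # different names: no merge, unless collapsed under an umbrella
  frn <- frag_granges("chr1", c(100, 450), c(400, 700), c("+", "+"),
                      c("IAPEz-int", "IAPLTR1"))
  expect_length(merge_fragments(frn), 2L)
  um <- merge_fragments(frn, name_scope = c("IAPEz-int", "IAPLTR1"),
                        collapse_scope = TRUE, scope_label = "IAP")
  expect_length(um, 1L)
  expect_equal(S4Vectors::mcols(um)$repeat_name, "IAP")

  # names outside the scope pass through unmerged
  sc <- merge_fragments(fr, gap = 100, name_scope = "OTHER")
  expect_length(sc, 2L)
  expect_true(all(S4Vectors::mcols(sc)$n_fragments == 1L))

  # single fragment: identity
  one <- merge_fragments(fr[1])
  expect_length(one, 1L)
  expect_equal(GenomicRanges::start(one), 100L)
  expect_equal(S4Vectors::mcols(one)$n_fragments, 1L)

  expect_error(merge_fragments(fr, gap = -1), "non-negative")
})

test_that("merging equals the brute-force transitive-closure oracle", {
  set.seed(42)
  for (i in 1:200) {
    df <- random_fragment_set(sample.int(30L, 1L))
    fr <- frag_granges(df$chrom, df$start, df$end, df$strand, df$name)
    got <- elements_table(merge_fragments(fr, gap = 100))
    want <- oracle_merge(df, gap = 100)
    rownames(want) <- NULL
    expect_equal(got[, c("chrom", "strand", "name", "start", "end", "n")],
                 want, ignore_attr = TRUE)
  }
})

test_that("merging is idempotent and conserves coverage up to bridged gaps", {
  set.seed(43)
  for (i in 1:25) {
    df <- random_fragment_set(sample.int(30L, 1L))
    fr <- frag_granges(df$chrom, df$start, df$end, df$strand, df$name)
    el <- merge_fragments(fr, gap = 100)
    el2 <- merge_fragments(el, gap = 100)
    expect_equal(elements_table(el)[, -6], elements_table(el2)[, -6])
    expect_true(all(S4Vectors::mcols(el2)$n_fragments == 1L))

    # per name+strand: element span covers the inputs, and the extra bases
    # are exactly the bridged gaps (span - covered input bases)
    key <- paste(df$strand, df$name)
    et <- elements_table(el)
    for (k in unique(key)) {
      d <- df[key == k, ]
      ik <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      ek <- et[paste(et$strand, et$name) == k, ]
      ee <- IRanges::IRanges(ek$start, ek$end)
      # inputs are contained in elements
      expect_equal(sum(IRanges::width(IRanges::setdiff(ik, ee))), 0L)
      # bridged-only: every extra base lies between two input fragments
      extra <- IRanges::setdiff(ee, ik)
      expect_true(all(IRanges::width(extra) <= 100L))
    }
  }
})

test_that("full-length classification uses the strict 5 kb rule", {
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1, 1, 1), width = c(5200, 5000, 100)))
  expect_equal(classify_full_length(el), c(TRUE, FALSE, FALSE))
})

test_that("BED export converts coordinates and round-trips", {
  fr <- frag_granges("chr1", c(100, 450), c(400, 700), c("+", "+"),
                     c("IAPEz", "IAPEz"))
  el <- merge_fragments(fr)
  f <- tempfile(fileext = ".bed")
  write_bed(el, f)
  line <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_equal(as.integer(line[2]), 99L)   # 0-based start
  expect_equal(as.integer(line[3]), 700L)  # half-open end
  expect_equal(line[4], "IAPEz")
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(el))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(el))

  f0 <- tempfile(fileext = ".bed")
  write_bed(el[0], f0)
  expect_length(readLines(f0), 0L)
})
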