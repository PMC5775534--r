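# Small simulation used across tests: 4 classes x 4 copies, light libraries.
small_config <- function(seed = 7L, ...) {
  simulation_config(seed = seed, copies_per_class = 4L,
                    library_sizes = c(8000L, 8000L),
                    n_bs_reads = 2000L, n_peaks = 150L, ...)
}

# GRanges fragment set from a plain table
frag_granges <- function(chrom, start, end, strand, name) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$repeat_name <- name
  gr
}

# Brute-force transitive-closure merge oracle: repeatedly merge any two
# clusters with same (chrom, strand, name) whose gap (bases strictly
# between) is <= gap, until no pair merges. Returns a canonical table.
oracle_merge <- function(df, gap = 100L) {
  cl <- split(df, paste(df$chrom, df$strand, df$name))
  out <- lapply(cl, function(d) {
    spans <- lapply(seq_len(nrow(d)), function(i)
      list(start = d$start[i], end = d$end[i], n = 1L))
    repeat {
      merged <- FALSE
      for (i in seq_along(spans)) {
        for (j in seq_along(spans)) {
          if (i >= j) next
          a <- spans[[i]]; b <- spans[[j]]
          g <- max(a$start, b$start) - min(a$end, b$end) - 1L
          if (g <= gap) {
            spans[[i]] <- list(start = min(a$start, b$start),
                               end = max(a$end, b$end), n = a$n + b$n)
            spans <- spans[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    data.frame(chrom = d$chrom[1], strand = d$strand[1], name = d$name[1],
               start = vapply(spans, `[[`, 1L, "start"),
               end = vapply(spans, `[[`, 1L, "end"),
               n = vapply(spans, `[[`, 1L, "n"))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$chrom, out$start, out$name, out$strand), , drop = FALSE]
}

# canonical table from merge_fragments() output for oracle comparison
elements_table <- function(el) {
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(el)),
                  strand = as.character(GenomicRanges::strand(el)),
                  name = S4Vectors::mcols(el)$repeat_name,
                  start = GenomicRanges::start(el),
                  end = GenomicRanges::end(el),
                  n = as.integer(S4Vectors::mcols(el)$n_fragments))
  d <- d[order(d$chrom, d$start, d$name, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

random_fragment_set <- function(n, n_names = 2L, span = 3000L) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(300L, n, replace = TRUE)
  data.frame(chrom = "chr1",
             start = start, end = start + width - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             name = sample(paste0("REP", seq_len(n_names)), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# O(n^2) overlap oracle: peaks overlapping >=1 bp of any copy of a class
oracle_overlap_counts <- function(peaks, annotation) {
  classes <- sort(unique(S4Vectors::mcols(annotation)$repeat_name))
  ps <- GenomicRanges::start(peaks); pe <- GenomicRanges::end(peaks)
  as <- GenomicRanges::start(annotation); ae <- GenomicRanges::end(annotation)
  an <- S4Vectors::mcols(annotation)$repeat_name
  vapply(stats::setNames(classes, classes), function(k) {
    hit <- 0L
    for (i in seq_along(ps)) {
      for (j in which(an == k)) {
        if (ps[i] <= ae[j] && pe[i] >= as[j]) { hit <- hit + 1L; break }
      }
    }
    hit
  }, 1L)
}

write_sam_tmp <- function(lines) {
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  f
}

fastq_seqs <- function(fq_lines) fq_lines[seq(2L, length(fq_lines), by = 4L)]
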