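#' Pipeline run configuration
#'
#' Bundles the simulation conditions and every downstream threshold into
#' one object. Thresholds default to the analysis constants: 100 bp merge
#' gap, 5 kb full-length span, 0.25 RPM detectability, twofold
#' differential-expression rule at p < 0.05, tenfold copy-level
#' activation, 100-read CpG coverage, and 1000 shuffles for the peak
#' permutation test.
#'
#' @param seed global seed; forwarded to the simulation config.
#' @param outdir output directory for all stage files.
#' @param sim optional [simulation_config()]; built from `seed` and `...`
#'   if missing (extra arguments are passed through).
#' @param gap merge gap in bp.
#' @param full_length_bp full-length span threshold in bp (strict).
#' @param rpm_threshold detectability threshold (strict).
#' @param copy_fold copy-level fold-change threshold (strict).
#' @param pseudocount RPM pseudocount for the copy-level ratio.
#' @param de_lfc log2 fold-change threshold of the DE call (1 = twofold).
#' @param alpha raw p-value threshold of the DE call.
#' @param min_coverage per-treatment CpG coverage floor.
#' @param n_shuffles permutation count for the enrichment test.
#' @param n_bs_replicates BS/oxBS biological replicates.
#' @param enriched_classes classes planted as peak-enriched.
#' @param ... forwarded to [simulation_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, outdir = "results/demo", sim = NULL,
                       gap = 100L, full_length_bp = 5000L,
                       rpm_threshold = 0.25, copy_fold = 10,
                       pseudocount = 0.1, de_lfc = 1, alpha = 0.05,
                       min_coverage = 100L, n_shuffles = 1000L,
                       n_bs_replicates = 2L, enriched_classes = NULL, ...) {
  sim <- sim %||% simulation_config(seed = seed, ...)
  stopifnot(gap >= 0, full_length_bp > 0, rpm_threshold > 0, copy_fold > 0,
            pseudocount > 0, de_lfc > 0, alpha > 0, min_coverage > 0,
            n_shuffles >= 1)
  structure(list(
    seed = as.integer(seed), outdir = outdir, sim = sim,
    gap = as.integer(gap), full_length_bp = as.integer(full_length_bp),
    rpm_threshold = rpm_threshold, copy_fold = copy_fold,
    pseudocount = pseudocount, de_lfc = de_lfc, alpha = alpha,
    min_coverage = as.integer(min_coverage),
    n_shuffles = as.integer(n_shuffles),
    n_bs_replicates = as.integer(n_bs_replicates),
    enriched_classes = enriched_classes %||% sim$class_names[1]
  ), class = "run_config")
}

#' Serialise / restore a run configuration
#'
#' Round-trips a [run_config()] through a human-readable YAML file
#' unchanged.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # yaml serialises named atomic vectors as plain sequences; a list keeps names
  x$sim$class_fold_changes <- as.list(x$sim$class_fold_changes)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- x$sim
  sim$class_fold_changes <- unlist(sim$class_fold_changes)
  sim$copy_length_range <- as.integer(sim$copy_length_range)
  sim$library_sizes <- as.integer(sim$library_sizes)
  class(sim) <- "simulation_config"
  x$sim <- sim
  x$enriched_classes <- unlist(x$enriched_classes)
  class(x) <- "run_config"
  x
}

stage_log <- function(outdir, ...) {
  msg <- paste0(...)
  message(msg)
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg, "\n",
      file = file.path(outdir, "run.log"), append = TRUE)
}

need_file <- function(path, stage, produced_by) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires '", basename(path),
         "' produced by stage '", produced_by, "'")
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order over flat TSV/FASTA/
#' SAM/FASTQ/BED interchange files in `config$outdir`:
#' \describe{
#'   \item{simulate}{toy genome, RepeatMasker fragments, per-sample SAM
#'     alignments, BS/oxBS FASTQ, peak + mappable BED, ground truth.}
#'   \item{annotate}{parse RepeatMasker output, merge fragments, classify
#'     full-length, write `elements.bed`/`elements.tsv`.}
#'   \item{count}{class-level inclusive counts, copy-level unique counts
#'     with RPM, detectability filter and tenfold classification.}
#'   \item{diffexp}{NB Wald test on class counts (background included as a
#'     normalisation feature).}
#'   \item{oxbs}{conversion-aware read matching, CpG tallies, 5mC/5hmC
#'     calls per replicate and the cross-replicate aggregate.}
#'   \item{enrich}{peak permutation enrichment over repeat classes.}
#' }
#' A manifest (`manifest.tsv`) records the package version, seed, and the
#' md5 checksum and row count of every output; a rerun with the same
#' config reproduces identical files.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to run (upstream outputs must exist).
#' @return invisibly, a list of key results and file paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "annotate", "count",
                                    "diffexp", "oxbs", "enrich")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out, f)
  res <- list(outdir = out)
  save_run_config(config, pth("config.yaml"))

  if ("simulate" %in% stages) {
    stage_log(out, "[simulate] building toy genome (seed ", config$sim$seed, ")")
    sim <- build_toy_genome(config$sim)
    write_genome_fasta(sim, pth("genome.fa"))
    write_repeatmasker_out(sim, pth("repeats.out"))
    write_amplicons_fasta(sim, pth("amplicons.fa"))
    write_tsv_(sim$copies, pth("truth_copies.tsv"))
    write_tsv_(sim$amplicon_truth, pth("truth_methylation.tsv"))
    samples <- simulate_rnaseq_experiment(sim, config$sim)
    for (s in samples)
      writeLines(s$sam, pth(sprintf("sample_%s.sam", s$sample)))
    write_tsv_(as.data.frame(sapply(samples, `[[`, "truth_class")),
               pth("truth_class_counts.tsv"), rownames = TRUE)
    write_tsv_(as.data.frame(sapply(samples, `[[`, "truth_unique_by_copy")),
               pth("truth_unique_counts.tsv"), rownames = TRUE)
    for (r in seq_len(config$n_bs_replicates)) {
      for (tr in c("BS", "oxBS")) {
        fq <- unlist(lapply(seq_along(sim$amplicons), function(ai) {
          nm <- names(sim$amplicons)[ai]
          simulate_bisulfite_reads(
            sim$amplicons[[nm]],
            sim$amplicon_truth[sim$amplicon_truth$amplicon == nm, ],
            treatment = tr, n_reads = config$sim$n_bs_reads,
            config = config$sim, seed_offset = 20L * ai + 2L * r)
        }))
        writeLines(fq, pth(sprintf("%s_rep%d.fastq", tolower(tr), r)))
      }
    }
    pk <- simulate_peaks(sim, enriched_classes = config$enriched_classes,
                         config = config$sim)
    rtracklayer::export.bed(pk$peaks, pth("peaks.bed"))
    rtracklayer::export.bed(pk$mappable, pth("mappable.bed"))
    write_tsv_(data.frame(class = names(pk$truth), enriched = pk$truth),
               pth("truth_peaks.tsv"))
    stage_log(out, "[simulate] ", length(samples), " samples, ",
              nrow(sim$copies), " planted copies")
    res$sim <- sim
  }

  if ("annotate" %in% stages) {
    need_file(pth("repeats.out"), "annotate", "simulate")
    frags <- parse_repeatmasker(pth("repeats.out"))
    elements <- merge_fragments(frags, gap = config$gap,
                                full_length_bp = config$full_length_bp)
    write_bed(elements, pth("elements.bed"))
    write_tsv_(data.frame(
      chrom = as.character(seqnames(elements)),
      start = GenomicRanges::start(elements),
      end = GenomicRanges::end(elements),
      strand = as.character(GenomicRanges::strand(elements)),
      repeat_name = mcols(elements)$repeat_name,
      n_fragments = mcols(elements)$n_fragments,
      full_length = mcols(elements)$full_length,
      copy_id = mcols(elements)$copy_id), pth("elements.tsv"))
    stage_log(out, "[annotate] ", length(frags), " fragments -> ",
              length(elements), " elements (",
              sum(mcols(elements)$full_length), " full-length)")
    res$elements <- elements
  }

  if (any(c("count", "diffexp", "oxbs", "enrich") %in% stages)) {
    elements <- if (file.exists(pth("elements.tsv"))) {
      e <- read_tsv_(pth("elements.tsv"))
      gr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                   strand = e$strand)
      mcols(gr)$repeat_name <- e$repeat_name
      mcols(gr)$n_fragments <- e$n_fragments
      mcols(gr)$full_length <- e$full_length
      mcols(gr)$copy_id <- e$copy_id
      gr
    } else NULL
  }

  if ("count" %in% stages) {
    need_file(pth("elements.tsv"), "count", "annotate")
    sams <- sort(list.files(out, pattern = "^sample_.*\\.sam$",
                            full.names = TRUE))
    if (!length(sams))
      stop("stage 'count' requires SAM files produced by stage 'simulate'")
    names(sams) <- sub("^sample_(.*)\\.sam$", "\\1", basename(sams))
    alns <- lapply(sams, read_sam_alignments)
    ct <- build_class_count_table(alns, elements)
    write_tsv_(as.data.frame(rbind(ct$counts, `_unassigned` = ct$unassigned)),
               pth("class_counts.tsv"), rownames = TRUE)
    write_tsv_(data.frame(sample = names(ct$library_sizes),
                          library_size = ct$library_sizes),
               pth("library_sizes.tsv"))
    cpt <- build_copy_count_table(alns, elements)
    write_tsv_(as.data.frame(cpt$counts), pth("copy_counts.tsv"), rownames = TRUE)
    write_tsv_(as.data.frame(round(cpt$rpm, 4)), pth("copy_rpm.tsv"),
               rownames = TRUE)
    ctl <- grepl("^A_", colnames(cpt$rpm))
    detect <- filter_detectable(cpt$rpm, config$rpm_threshold)
    cls <- classify_fold_change(cpt$rpm[detect, ctl, drop = FALSE],
                                cpt$rpm[detect, !ctl, drop = FALSE],
                                fold = config$copy_fold,
                                pseudocount = config$pseudocount)
    cls$repeat_name <- mcols(elements)$repeat_name[
      match(cls$copy_id, mcols(elements)$copy_id)]
    cls$full_length <- mcols(elements)$full_length[
      match(cls$copy_id, mcols(elements)$copy_id)]
    write_tsv_(cls, pth("copy_classification.tsv"))
    summ <- do.call(rbind, lapply(split(cls, cls$repeat_name), function(d) {
      s <- summarize_classification(d$upregulated)
      data.frame(repeat_name = d$repeat_name[1],
                 n_detectable = s$n_detectable, n_up = s$n_up,
                 percent_up = s$percent_up)
    }))
    write_tsv_(summ, pth("classification_summary.tsv"))
    stage_log(out, "[count] ", sum(detect), "/", length(detect),
              " copies detectable; per-class %up: ",
              paste(summ$repeat_name, summ$percent_up, sep = "=",
                    collapse = ", "))
    res$class_table <- ct; res$copy_table <- cpt
    res$classification <- cls; res$classification_summary <- summ
  }

  if ("diffexp" %in% stages) {
    need_file(pth("class_counts.tsv"), "diffexp", "count")
    cc <- as.matrix(read_tsv_(pth("class_counts.tsv"), rownames = TRUE))
    condition <- factor(ifelse(grepl("^A_", colnames(cc)), "control",
                               "depleted"),
                        levels = c("control", "depleted"))
    de <- nb_wald_test(cc, condition, lfc_threshold = config$de_lfc,
                       alpha = config$alpha)
    write_tsv_(de, pth("diffexp.tsv"))
    stage_log(out, "[diffexp] called: ",
              paste(de$feature[de$call], collapse = ", "))
    res$diffexp <- de
  }

  if ("oxbs" %in% stages) {
    need_file(pth("amplicons.fa"), "oxbs", "simulate")
    amp <- as.character(readDNAStringSet(pth("amplicons.fa")))
    calls <- list()
    for (r in seq_len(config$n_bs_replicates)) {
      bsr <- need_file(pth(sprintf("bs_rep%d.fastq", r)), "oxbs", "simulate")
      oxr <- need_file(pth(sprintf("oxbs_rep%d.fastq", r)), "oxbs", "simulate")
      tallies <- lapply(c(BS = bsr, oxBS = oxr), function(f) {
        reads <- as.character(readDNAStringSet(f, format = "fastq"))
        asg <- match_amplicon_reads(reads, amp)
        tally_cpg_states(reads, asg, amp)
      })
      call <- call_methylation(tallies$BS, tallies$oxBS,
                               min_coverage = config$min_coverage)
      write_tsv_(call, pth(sprintf("methylation_rep%d.tsv", r)))
      calls[[r]] <- call
    }
    aggr <- aggregate_amplicon(calls)
    write_tsv_(aggr, pth("methylation.tsv"))
    stage_log(out, "[oxbs] ", nrow(aggr), " CpGs called (mean 5mC ",
              round(mean(aggr$five_mC), 3), ", mean 5hmC ",
              round(mean(aggr$five_hmC), 3), ")")
    res$methylation <- aggr; res$methylation_replicates <- calls
  }

  if ("enrich" %in% stages) {
    need_file(pth("elements.tsv"), "enrich", "annotate")
    peaks <- read_bed(need_file(pth("peaks.bed"), "enrich", "simulate"))
    mappable <- read_bed(need_file(pth("mappable.bed"), "enrich", "simulate"))
    enr <- enrichment_test(peaks, elements, mappable,
                           N = config$n_shuffles,
                           seed = config$seed + 400L)
    write_tsv_(enr, pth("enrichment.tsv"))
    stage_log(out, "[enrich] min p: ",
              paste(enr$repeat_name[which.min(enr$p_empirical)],
                    round(min(enr$p_empirical), 5)))
    res$enrichment <- enr
  }

  files <- sort(setdiff(list.files(out),
                        c("manifest.tsv", "run.log", "config.yaml")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))),
    n_rows = vapply(files, function(f) {
      if (grepl("\\.tsv$", f)) length(readLines(file.path(out, f))) - 1L
      else NA_integer_
    }, 1L),
    package_version = as.character(utils::packageVersion("retrosilence")),
    seed = config$seed)
  write_tsv_(manifest, pth("manifest.tsv"))
  invisible(res)
}
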