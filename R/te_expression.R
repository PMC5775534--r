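#' Read SAM alignments
#'
#' Loads a SAM file (via Rsamtools) into a flat table of placements. A
#' read's placements are its primary record plus any secondary (flag
#' 0x100) records; a read is "uniquely mapped" iff it has exactly one
#' placement.
#'
#' @param path SAM file.
#' @return data.frame of class `read_alignments` with columns `qname`,
#'   `chrom`, `start`, `end`, `is_primary`, `n_placements`, and attribute
#'   `library_size` (number of primary records).
#' @export
read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "qwidth"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  df <- data.frame(
    qname = x$qname,
    chrom = as.character(x$rname),
    start = x$pos,
    end = x$pos + x$qwidth - 1L,
    is_primary = bitwAnd(x$flag, 256L) == 0L,
    stringsAsFactors = FALSE)
  tb <- table(df$qname)
  df$n_placements <- if (nrow(df)) as.integer(tb[df$qname]) else integer(0)
  attr(df, "library_size") <- sum(df$is_primary)
  class(df) <- c("read_alignments", class(df))
  df
}

# Attribute placements to features: a placement is attributed to the
# feature covering >= min_frac of its span; ties across distinct features
# are broken by longest feature, then lexicographic name.
attribute_placements <- function(chrom, start, end, features, feature_names,
                                 min_frac = 0.5) {
  if (length(chrom) &&
      !all(unique(chrom) %in% as.character(seqlevels(features))))
    stop("alignment references a chromosome absent from the annotation: ",
         paste(setdiff(unique(chrom), as.character(seqlevels(features))),
               collapse = ", "))
  assign <- rep(NA_integer_, length(chrom))
  if (!length(chrom)) return(assign)
  r <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(r, features, ignore.strand = TRUE)
  if (!length(hits)) return(assign)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  ow <- pmin(end[qh], GenomicRanges::end(features)[sh]) -
        pmax(start[qh], GenomicRanges::start(features)[sh]) + 1L
  keep <- ow >= min_frac * (end[qh] - start[qh] + 1L)
  qh <- qh[keep]; sh <- sh[keep]
  if (!length(qh)) return(assign)
  ord <- order(qh, -GenomicRanges::width(features)[sh], feature_names[sh])
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  assign[qh[first]] <- sh[first]
  assign
}

#' Count reads per repeat class under the inclusive mapping regime
#'
#' Each read is counted at most once, attributed to the repeat class
#' overlapping its primary placement (which was chosen uniformly at random
#' among the read's equally-best placements upstream). A read whose
#' primary placement covers no repeat by at least `min_frac` of its span
#' is tallied as unassigned, so that assigned + unassigned equals the
#' library size exactly.
#'
#' @param aln a `read_alignments` table from [read_sam_alignments()].
#' @param annotation GRanges of repeat elements with metadata column
#'   `repeat_name`.
#' @param min_frac minimum fraction of the read span inside the element.
#' @return list with `counts` (named integer vector over classes),
#'   `unassigned` and `library_size`.
#' @export
count_by_class_inclusive <- function(aln, annotation, min_frac = 0.5) {
  classes <- sort(unique(mcols(annotation)$repeat_name))
  pri <- aln[aln$is_primary, , drop = FALSE]
  idx <- attribute_placements(pri$chrom, pri$start, pri$end, annotation,
                              mcols(annotation)$repeat_name, min_frac)
  cls <- mcols(annotation)$repeat_name[idx]
  counts <- stats::setNames(
    vapply(classes, function(k) sum(cls == k, na.rm = TRUE), 1L), classes)
  list(counts = counts, unassigned = sum(is.na(idx)),
       library_size = attr(aln, "library_size"))
}

#' Count uniquely mapped reads per element copy
#'
#' Only reads with a single placement are counted; multi-mapped reads
#' contribute nothing. Attribution follows the same overlap rule as the
#' inclusive regime. A companion RPM vector (count x 1e6 / total library
#' size) is returned.
#'
#' @param aln a `read_alignments` table.
#' @param elements GRanges of merged elements with metadata column
#'   `copy_id` (falls back to `repeat_name` + index).
#' @param min_frac minimum fraction of the read span inside the element.
#' @return list with `counts` and `rpm` (named by copy), `library_size`.
#' @export
count_by_copy_unique <- function(aln, elements, min_frac = 0.5) {
  ids <- mcols(elements)$copy_id %||%
    sprintf("%s_%d", mcols(elements)$repeat_name, seq_along(elements))
  u <- aln[aln$is_primary & aln$n_placements == 1L, , drop = FALSE]
  idx <- attribute_placements(u$chrom, u$start, u$end, elements, ids, min_frac)
  counts <- stats::setNames(tabulate(idx, nbins = length(elements)), ids)
  N <- attr(aln, "library_size")
  rpm <- if (N > 0) counts * 1e6 / N else counts * 0
  list(counts = counts, rpm = rpm, library_size = N)
}

#' Build a class-level count table over samples
#' @param alns named list of `read_alignments` (one per sample).
#' @param annotation GRanges with `repeat_name`.
#' @param min_frac overlap rule threshold.
#' @return list of class `class_count_table`: `counts` (classes x samples),
#'   `unassigned`, `library_sizes`.
#' @export
build_class_count_table <- function(alns, annotation, min_frac = 0.5) {
  per <- lapply(alns, count_by_class_inclusive, annotation = annotation,
                min_frac = min_frac)
  counts <- do.call(cbind, lapply(per, `[[`, "counts"))
  colnames(counts) <- names(alns)
  structure(list(
    counts = counts,
    unassigned = vapply(per, `[[`, 1L, "unassigned"),
    library_sizes = vapply(per, `[[`, 1L, "library_size")),
    class = "class_count_table")
}

#' Build a copy-level unique-read count table over samples
#' @inheritParams build_class_count_table
#' @param elements GRanges of merged elements.
#' @return list of class `copy_count_table`: `counts` and `rpm`
#'   (copies x samples), `library_sizes`.
#' @export
build_copy_count_table <- function(alns, elements, min_frac = 0.5) {
  per <- lapply(alns, count_by_copy_unique, elements = elements,
                min_frac = min_frac)
  counts <- do.call(cbind, lapply(per, `[[`, "counts"))
  rpm <- do.call(cbind, lapply(per, `[[`, "rpm"))
  colnames(counts) <- colnames(rpm) <- names(alns)
  structure(list(
    counts = counts, rpm = rpm,
    library_sizes = vapply(per, `[[`, 1L, "library_size")),
    class = "copy_count_table")
}

#' Filter copies by the detectability rule
#'
#' A copy is retained iff its RPM exceeds `threshold` (strictly) in at
#' least one sample.
#'
#' @param rpm copies x samples RPM matrix.
#' @param threshold RPM threshold (default 0.25, strict).
#' @return named logical vector.
#' @export
filter_detectable <- function(rpm, threshold = 0.25) {
  apply(rpm, 1L, function(x) max(x) > threshold)
}

#' Classify per-copy fold change between conditions
#'
#' A copy is upregulated iff
#' `(mean depleted RPM + pseudocount) / (mean control RPM + pseudocount)`
#' exceeds `fold` (strictly).
#'
#' @param rpm_control,rpm_depleted RPM matrices (copies x replicates) or
#'   vectors of per-copy means.
#' @param fold fold-change threshold (default 10).
#' @param pseudocount RPM pseudocount guarding against division by zero.
#' @return data.frame with per-copy mean RPMs, ratio and the call.
#' @export
classify_fold_change <- function(rpm_control, rpm_depleted, fold = 10,
                                 pseudocount = 0.1) {
  mc <- if (is.matrix(rpm_control)) rowMeans(rpm_control) else rpm_control
  md <- if (is.matrix(rpm_depleted)) rowMeans(rpm_depleted) else rpm_depleted
  if (any(mc < 0) || any(md < 0)) stop("negative RPM")
  ratio <- (md + pseudocount) / (mc + pseudocount)
  data.frame(copy_id = names(mc) %||% seq_along(mc),
             mean_rpm_control = unname(mc), mean_rpm_depleted = unname(md),
             ratio = unname(ratio), upregulated = unname(ratio > fold),
             stringsAsFactors = FALSE)
}

#' Summarise the copy-level classification
#'
#' @param calls logical vector of upregulation calls over detectable
#'   copies; alternatively pass `n_detectable` and `n_up` directly (e.g.
#'   to recompute a percentage from published counts).
#' @param n_detectable,n_up counts; default derived from `calls`.
#' @return list with `n_detectable`, `n_up`, and `percent_up` (nearest
#'   integer percent; `NA` when nothing is detectable).
#' @export
summarize_classification <- function(calls = NULL,
                                     n_detectable = length(calls),
                                     n_up = sum(calls)) {
  pct <- if (n_detectable > 0) round(100 * n_up / n_detectable) else NA_real_
  list(n_detectable = as.integer(n_detectable), n_up = as.integer(n_up),
       percent_up = pct)
}
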