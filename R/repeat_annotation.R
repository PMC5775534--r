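#' Parse a RepeatMasker .out file
#'
#' Reads the standard RepeatMasker output dialect: three header lines,
#' whitespace-delimited columns, strand "C" denoting the minus strand,
#' 1-based inclusive query coordinates. Fragments are returned in file
#' order as a [GenomicRanges::GRanges] (1-based closed, the Bioconductor
#' convention) with metadata columns `repeat_name` and `repeat_family`.
#'
#' @param path path to a RepeatMasker .out file.
#' @return GRanges of repeat fragments.
#' @export
parse_repeatmasker <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-seq_len(3L)] else lines <- character(0)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- (seq_along(keep) + 3L)[keep]
  if (!length(lines))
    return(GenomicRanges::GRanges(
      repeat_name = character(0), repeat_family = character(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 14L | nf > 16L)
  if (length(bad))
    stop("malformed RepeatMasker row at line ", lineno[bad[1]],
         ": expected 14-16 columns, found ", nf[bad[1]])
  f <- function(i) vapply(fields, `[[`, "", i)
  strand <- f(9)
  if (!all(strand %in% c("+", "C")))
    stop("invalid strand column (expected '+' or 'C') at line ",
         lineno[which(!strand %in% c("+", "C"))[1]])
  gr <- GenomicRanges::GRanges(
    seqnames = f(5),
    ranges = IRanges::IRanges(start = as.integer(f(6)), end = as.integer(f(7))),
    strand = ifelse(strand == "C", "-", "+"))
  mcols(gr)$repeat_name <- f(10)
  mcols(gr)$repeat_family <- f(11)
  gr
}

#' Merge same-strand repeat fragments into elements
#'
#' Two fragments merge iff they lie on the same chromosome and strand,
#' carry the same repeat name, and the number of bases strictly between
#' them is at most `gap` (100 bp by default, the "within 100 bp" rule read
#' inclusively). Merging is transitive and exhaustive. Names outside
#' `name_scope` pass through unmerged as single-fragment elements.
#'
#' @param fragments GRanges from [parse_repeatmasker()] (metadata column
#'   `repeat_name` required).
#' @param gap maximum number of bases strictly between two fragments for
#'   them to merge; must be non-negative.
#' @param name_scope repeat names eligible for merging; `NULL` (default)
#'   merges every name. Internal and LTR fragments of one family can be
#'   merged under a single umbrella by setting `collapse_scope = TRUE`,
#'   in which case all in-scope names are treated as one name labelled
#'   `scope_label`.
#' @param collapse_scope merge across the names in `name_scope` as if they
#'   were one repeat.
#' @param scope_label label for collapsed elements.
#' @param full_length_bp span threshold for the full-length call
#'   (strictly greater than; see [classify_full_length()]).
#' @return GRanges of merged elements, sorted by (chrom, start), with
#'   metadata columns `repeat_name`, `n_fragments`, `full_length`, and a
#'   stable `copy_id`.
#' @export
merge_fragments <- function(fragments, gap = 100L, name_scope = NULL,
                            collapse_scope = FALSE, scope_label = "merged",
                            full_length_bp = 5000L) {
  if (gap < 0) stop("gap must be non-negative")
  stopifnot(is(fragments, "GRanges"),
            "repeat_name" %in% names(mcols(fragments)))
  nm <- mcols(fragments)$repeat_name
  in_scope <- if (is.null(name_scope)) rep(TRUE, length(fragments))
              else nm %in% name_scope
  key <- nm
  if (collapse_scope) key[in_scope] <- scope_label

  res <- list()
  # out-of-scope fragments pass through unmerged
  if (any(!in_scope)) {
    g <- fragments[!in_scope]
    el <- GenomicRanges::granges(g)
    mcols(el)$repeat_name <- nm[!in_scope]
    mcols(el)$n_fragments <- 1L
    res[[length(res) + 1L]] <- el
  }
  if (any(in_scope)) {
    g <- fragments[in_scope]
    for (k in unique(key[in_scope])) {
      gk <- g[key[in_scope] == k]
      red <- GenomicRanges::reduce(gk, min.gapwidth = gap + 1L,
                                   with.revmap = TRUE,
                                   ignore.strand = FALSE)
      el <- GenomicRanges::granges(red)
      mcols(el)$repeat_name <- k
      mcols(el)$n_fragments <- lengths(mcols(red)$revmap)
      res[[length(res) + 1L]] <- el
    }
  }
  out <- sort(do.call(c, res), ignore.strand = TRUE)
  mcols(out)$full_length <- classify_full_length(out, full_length_bp)
  mcols(out)$copy_id <- sprintf("%s_%d", mcols(out)$repeat_name,
                                stats::ave(seq_along(out),
                                           mcols(out)$repeat_name,
                                           FUN = seq_along))
  out
}

#' Classify elements as full-length
#'
#' An element is full-length iff its span exceeds `min_bp` (strictly
#' greater than 5 kb by default); an element of exactly `min_bp` is
#' truncated.
#'
#' @param elements GRanges (or anything with a [GenomicRanges::width()]).
#' @param min_bp span threshold in bp.
#' @return logical vector.
#' @export
classify_full_length <- function(elements, min_bp = 5000L) {
  GenomicRanges::width(elements) > min_bp
}

#' Write merged elements as BED6
#'
#' 0-based half-open coordinates (the BED convention); name column is the
#' repeat name, score is the number of merged fragments.
#'
#' @param elements GRanges from [merge_fragments()].
#' @param path output file.
#' @export
write_bed <- function(elements, path) {
  g <- elements
  mcols(g) <- NULL
  mcols(g)$name <- mcols(elements)$repeat_name
  mcols(g)$score <- as.numeric(mcols(elements)$n_fragments %||%
                                 rep(0L, length(elements)))
  rtracklayer::export.bed(g, path)
  invisible(path)
}

#' Read a BED file as GRanges
#'
#' Thin wrapper over [rtracklayer::import()]; BED's 0-based half-open
#' coordinates are converted to the 1-based closed GRanges convention.
#'
#' @param path BED file.
#' @return GRanges.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
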