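#' Configuration for the synthetic retroelement dataset
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe the emulated study design: a few ERV-like repeat classes with
#' near-identical young copies (so that short reads multi-map), one
#' IAP-like class strongly activated (>tenfold) in the "depleted"
#' condition B versus control condition A, three replicates per
#' condition, gene-like background reads dominating the library, and
#' paired BS/oxBS amplicon reads with known per-CpG 5mC/5hmC levels.
#'
#' @param seed integer RNG seed; every generator operation derives its own
#'   stream as `seed + operation offset`, so stages can be regenerated
#'   independently and identical configs give byte-identical outputs.
#' @param n_classes number of repeat classes to plant (first four are
#'   named IAPEz, MERVL, RLTR4, L1MdA).
#' @param copies_per_class copies planted per class.
#' @param copy_length_range numeric length-2, bp; spans both sides of the
#'   5 kb full-length boundary by default so truncated and full-length
#'   copies coexist.
#' @param inter_copy_divergence per-site substitution rate between a copy
#'   and its class consensus, in \[0,1). The first
#'   `n_identical_copies` copies of each class are exact consensus copies
#'   (young, recently inserted elements), which is what makes reads from
#'   them multi-map.
#' @param n_identical_copies number of exact (zero-divergence, equal
#'   length) copies per class.
#' @param read_length RNA-seq read length, bp.
#' @param library_sizes integer vector, reads per replicate (same for both
#'   conditions); its length sets the number of replicates.
#' @param class_fold_changes named multiplicative expression change of
#'   each class in condition B versus A. Default plants a 20-fold
#'   IAP-like activation and a 3-fold secondary class.
#' @param background_fraction expected fraction of reads drawn from
#'   non-repeat (gene-like) background sequence.
#' @param fragment_split_prob probability that a planted copy is recorded
#'   as two RepeatMasker fragments separated by a <=100 bp gap (so that
#'   downstream merging has real work to do).
#' @param bs_conversion_efficiency probability an unprotected cytosine is
#'   read as T after bisulfite conversion.
#' @param oxidation_efficiency probability a 5hmC is oxidised (and hence
#'   converted) under the oxBS treatment.
#' @param n_amplicons,amplicon_length amplicons for the BS/oxBS assay.
#' @param n_bs_reads reads per amplicon per treatment per replicate.
#' @param n_peaks,peak_width,peak_enrichment_fraction ChIP-seq peak set:
#'   total peaks, their width, and the fraction placed inside copies of
#'   the enriched classes.
#' @param chrom_length optional fixed chromosome length; an error is
#'   raised if the planted copies do not fit.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_classes = 4L,
                              copies_per_class = 6L,
                              copy_length_range = c(3000L, 7000L),
                              inter_copy_divergence = 0.03,
                              n_identical_copies = 2L,
                              read_length = 100L,
                              library_sizes = c(20000L, 20000L, 20000L),
                              class_fold_changes = NULL,
                              background_fraction = 0.9,
                              fragment_split_prob = 0,
                              bs_conversion_efficiency = 0.99,
                              oxidation_efficiency = 0.95,
                              n_amplicons = 2L,
                              amplicon_length = 300L,
                              n_bs_reads = 10000L,
                              n_peaks = 300L,
                              peak_width = 200L,
                              peak_enrichment_fraction = 0.8,
                              chrom_length = NULL) {
  stopifnot(length(copy_length_range) == 2L,
            copy_length_range[1] <= copy_length_range[2],
            inter_copy_divergence >= 0, inter_copy_divergence < 1,
            background_fraction >= 0, background_fraction < 1,
            fragment_split_prob >= 0, fragment_split_prob <= 1,
            bs_conversion_efficiency >= 0, bs_conversion_efficiency <= 1,
            oxidation_efficiency >= 0, oxidation_efficiency <= 1,
            peak_enrichment_fraction >= 0, peak_enrichment_fraction <= 1,
            all(library_sizes >= 0))
  base_names <- c("IAPEz", "MERVL", "RLTR4", "L1MdA")
  base_fams  <- c("LTR/ERVK", "LTR/ERVL", "LTR/ERV1", "LINE/L1")
  if (n_classes > 4L) {
    base_names <- c(base_names, sprintf("RLTR%d", 10L + seq_len(n_classes - 4L)))
    base_fams  <- c(base_fams, rep("LTR/ERVK", n_classes - 4L))
  }
  class_names <- base_names[seq_len(n_classes)]
  class_families <- base_fams[seq_len(n_classes)]
  if (is.null(class_fold_changes)) {
    fc <- rep(1, n_classes)
    fc[1] <- 20
    if (n_classes >= 2L) fc[2] <- 3
    class_fold_changes <- stats::setNames(fc, class_names)
  } else {
    if (is.null(names(class_fold_changes)) ||
        !all(names(class_fold_changes) %in% class_names))
      stop("class_fold_changes must be named by planted class names")
    fc <- stats::setNames(rep(1, n_classes), class_names)
    fc[names(class_fold_changes)] <- class_fold_changes
    class_fold_changes <- fc
  }
  n_identical_copies <- min(n_identical_copies, copies_per_class)
  structure(list(
    seed = as.integer(seed), n_classes = as.integer(n_classes),
    copies_per_class = as.integer(copies_per_class),
    copy_length_range = as.integer(copy_length_range),
    inter_copy_divergence = inter_copy_divergence,
    n_identical_copies = as.integer(n_identical_copies),
    read_length = as.integer(read_length),
    library_sizes = as.integer(library_sizes),
    class_names = class_names, class_families = class_families,
    class_fold_changes = class_fold_changes,
    background_fraction = background_fraction,
    fragment_split_prob = fragment_split_prob,
    bs_conversion_efficiency = bs_conversion_efficiency,
    oxidation_efficiency = oxidation_efficiency,
    n_amplicons = as.integer(n_amplicons),
    amplicon_length = as.integer(amplicon_length),
    n_bs_reads = as.integer(n_bs_reads),
    n_peaks = as.integer(n_peaks), peak_width = as.integer(peak_width),
    peak_enrichment_fraction = peak_enrichment_fraction,
    chrom_length = chrom_length
  ), class = "simulation_config")
}

#' Build a toy genome with planted repeat copies and known ground truth
#'
#' Constructs a single-chromosome genome in which each repeat class has a
#' random consensus and each copy is a (possibly truncated, possibly
#' strand-flipped, possibly mutated) version of it, separated by random
#' background sequence. Also generates amplicon references with known
#' per-CpG 5mC/5hmC levels for the BS/oxBS assay, and a RepeatMasker-style
#' fragment table that, after merging, reconstructs the planted elements.
#'
#' Copies `1..n_identical_copies` of each class are exact full-length
#' consensus copies; the next copy is forced to the lower end of
#' `copy_length_range` so a truncated element always exists. When
#' `inter_copy_divergence == 0`, all copies of a class are identical
#' strings (equal length, no mutations).
#'
#' @param config a [simulation_config()].
#' @return a `toy_simulation` list: `genome` (named [Biostrings::DNAStringSet]),
#'   `copies` (ground-truth table), `copy_seqs` (consensus-orientation copy
#'   sequences), `fragments` (RepeatMasker-style rows), `gaps` (background
#'   intervals), `amplicons`, `amplicon_truth`, and the `config`.
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  k <- config$n_classes; m <- config$copies_per_class
  lo <- config$copy_length_range[1]; hi <- config$copy_length_range[2]
  div <- config$inter_copy_divergence
  n_id <- if (div == 0) m else config$n_identical_copies

  consensus <- stats::setNames(
    vapply(seq_len(k), function(i) random_dna(hi), ""), config$class_names)

  copies <- list(); copy_seqs <- list()
  for (ci in seq_len(k)) {
    cls <- config$class_names[ci]
    lens <- if (div == 0) rep(round((lo + hi) / 2), m)
            else round(runif(m, lo, hi))
    if (div > 0) {
      lens[seq_len(n_id)] <- hi           # identical copies: full consensus
      if (m > n_id) lens[n_id + 1L] <- lo # guarantee a truncated copy
    }
    strands <- sample(c("+", "-"), m, replace = TRUE)
    for (j in seq_len(m)) {
      s <- substr(consensus[[cls]], 1L, lens[j])
      if (j > n_id) s <- mutate_dna(s, div)
      id <- sprintf("%s_%d", cls, j)
      copy_seqs[[id]] <- s
      copies[[id]] <- data.frame(
        copy_id = id, class = cls, length = lens[j], strand = strands[j],
        identical_group = j <= n_id, stringsAsFactors = FALSE)
    }
  }
  copies <- do.call(rbind, copies)

  # lay copies along the chromosome in shuffled order, background between
  ord <- sample(nrow(copies))
  gap_lens <- sample(400:900, nrow(copies) + 1L, replace = TRUE)
  needed <- sum(copies$length) + sum(gap_lens)
  if (!is.null(config$chrom_length)) {
    if (needed > config$chrom_length ||
        max(copies$length) > config$chrom_length)
      stop("planted copies do not fit: need ", needed,
           " bp but chrom_length is ", config$chrom_length)
  }
  pieces <- character(0); pos <- 1L
  gstart <- integer(nrow(copies)); gend <- integer(nrow(copies))
  gaps <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_along(ord)) {
    g <- gap_lens[i]
    pieces <- c(pieces, random_dna(g))
    gaps <- rbind(gaps, data.frame(start = pos, end = pos + g - 1L))
    pos <- pos + g
    ci <- ord[i]
    s <- copy_seqs[[copies$copy_id[ci]]]
    if (copies$strand[ci] == "-") s <- revcomp_chr(s)
    pieces <- c(pieces, s)
    gstart[ci] <- pos; gend[ci] <- pos + copies$length[ci] - 1L
    pos <- pos + copies$length[ci]
  }
  g <- gap_lens[length(gap_lens)]
  pieces <- c(pieces, random_dna(g))
  gaps <- rbind(gaps, data.frame(start = pos, end = pos + g - 1L))
  pos <- pos + g
  chrom_seq <- paste(pieces, collapse = "")
  if (!is.null(config$chrom_length) && config$chrom_length > nchar(chrom_seq))
    chrom_seq <- paste0(chrom_seq, random_dna(config$chrom_length - nchar(chrom_seq)))
  copies$chrom <- "chr1"; copies$start <- gstart; copies$end <- gend
  copies$full_length <- copies$length > 5000L

  # RepeatMasker-style fragments (1-based inclusive); a split copy becomes
  # two same-strand fragments separated by a gap of at most 100 bp
  frags <- list()
  fam <- stats::setNames(config$class_families, config$class_names)
  for (i in seq_len(nrow(copies))) {
    split <- runif(1) < config$fragment_split_prob && copies$length[i] >= 400L
    if (split) {
      gapw <- sample(5:95, 1L)
      a <- round(copies$length[i] * runif(1, 0.3, 0.6))
      s1 <- copies$start[i]; e1 <- s1 + a - 1L
      s2 <- e1 + gapw + 1L; e2 <- copies$end[i]
      rows <- data.frame(chrom = "chr1", start = c(s1, s2), end = c(e1, e2))
    } else {
      rows <- data.frame(chrom = "chr1", start = copies$start[i], end = copies$end[i])
    }
    rows$strand <- copies$strand[i]
    rows$repeat_name <- copies$class[i]
    rows$repeat_family <- fam[[copies$class[i]]]
    rows$copy_id <- copies$copy_id[i]
    frags[[i]] <- rows
  }
  fragments <- do.call(rbind, frags)
  fragments <- fragments[order(fragments$start), , drop = FALSE]
  rownames(fragments) <- NULL

  # amplicons with planted per-CpG 5mC/5hmC truth
  amplicons <- character(0); truth <- list()
  for (a in seq_len(config$n_amplicons)) {
    len <- config$amplicon_length
    s <- strsplit(random_dna(len), "", fixed = TRUE)[[1]]
    planted <- seq(15L, len - 5L, by = 24L)
    s[planted] <- "C"; s[planted + 1L] <- "G"
    seq_a <- paste(s, collapse = "")
    cpg <- gregexpr("CG", seq_a, fixed = TRUE)[[1]]
    cpg <- cpg[cpg > 0]
    nm <- sprintf("IAP_LTR_amp%d", a)
    amplicons[nm] <- seq_a
    truth[[a]] <- data.frame(
      amplicon = nm, pos = as.integer(cpg),
      five_mC = round(runif(length(cpg), 0.4, 0.85), 3),
      five_hmC = round(runif(length(cpg), 0, 0.12), 3),
      stringsAsFactors = FALSE)
  }
  amplicon_truth <- do.call(rbind, truth)

  structure(list(
    genome = Biostrings::DNAStringSet(stats::setNames(chrom_seq, "chr1")),
    chrom = "chr1", chrom_length = nchar(chrom_seq),
    consensus = consensus, copies = copies, copy_seqs = copy_seqs,
    fragments = fragments, gaps = gaps,
    amplicons = amplicons, amplicon_truth = amplicon_truth,
    config = config
  ), class = "toy_simulation")
}

#' Write the toy genome as FASTA
#' @param sim a `toy_simulation`.
#' @param path output file.
#' @export
write_genome_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(sim$genome, path)
  invisible(path)
}

#' Write amplicon references as FASTA
#' @param sim a `toy_simulation`.
#' @param path output file.
#' @export
write_amplicons_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$amplicons), path)
  invisible(path)
}

#' Write the planted fragments in RepeatMasker .out format
#'
#' Emits the standard dialect: three header lines, whitespace-delimited
#' columns, strand "C" for minus, 1-based inclusive query coordinates.
#' @param sim a `toy_simulation`.
#' @param path output file.
#' @export
write_repeatmasker_out <- function(sim, path) {
  f <- sim$fragments
  hdr <- c(
    "   SW   perc perc perc  query     position in query              matching  repeat          position in repeat",
    "score   div. del. ins.  sequence  begin  end          (left)     repeat    class/family  begin  end    (left)  ID",
    "")
  left <- sim$chrom_length - f$end
  rows <- sprintf(" %5d %5.1f %4.1f %4.1f  %s %8d %8d (%d) %s %-12s %-14s %6d %6d (%d) %4d",
                  1000L + seq_len(nrow(f)), 1.0, 0.0, 0.0, f$chrom,
                  f$start, f$end, left,
                  ifelse(f$strand == "-", "C", "+"),
                  f$repeat_name, f$repeat_family,
                  1L, f$end - f$start + 1L, 0L, seq_len(nrow(f)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# sorted per-pair difference positions between copies of one class, used to
# find exact-tie alternative placements for a read window
copy_diff_index <- function(sim, cls) {
  ids <- sim$copies$copy_id[sim$copies$class == cls]
  raws <- lapply(sim$copy_seqs[ids], charToRaw)
  n <- length(ids)
  idx <- vector("list", n * n)
  dim(idx) <- c(n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) { idx[[a, b]] <- integer(0); next }
    L <- min(length(raws[[a]]), length(raws[[b]]))
    idx[[a, b]] <- which(raws[[a]][seq_len(L)] != raws[[b]][seq_len(L)])
  }
  list(ids = ids, lens = lengths(raws), diffs = idx)
}

#' Simulate RNA-seq alignments for one sample as SAM
#'
#' Draws `library_size` reads from planted copies (weight = class
#' expression in the given condition times the number of read start
#' positions) and from non-repeat background. Each read record carries
#' every equally-best (exact-tie) placement across same-class copies: the
#' primary is chosen uniformly at random, the rest are written as
#' secondary alignments (flag 0x100), so downstream counting can exercise
#' both the inclusive and the unique mapping regime.
#'
#' @param sim a `toy_simulation`.
#' @param condition "A" (control) or "B" (depleted).
#' @param replicate replicate index; selects the library size and offsets
#'   the RNG stream.
#' @param config defaults to `sim$config`.
#' @param library_size overrides the configured library size.
#' @return list with `sam` (character lines), `truth_class` (named vector
#'   of per-class read counts incl. `unassigned`), `truth_unique_by_copy`
#'   (reads with a single placement, per copy), `library_size`, `sample`.
#' @export
simulate_rnaseq_alignments <- function(sim, condition = c("A", "B"),
                                       replicate = 1L, config = sim$config,
                                       library_size = NULL) {
  condition <- match.arg(condition)
  set.seed(config$seed + 100L + 50L * (condition == "B") + as.integer(replicate))
  N <- as.integer(library_size %||% config$library_sizes[replicate])
  rl <- config$read_length
  label <- sprintf("%s_%d", condition, replicate)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", sim$chrom, sim$chrom_length),
              "@PG\tID:retrosim\tPN:retrosim")
  cls_all <- sort(unique(sim$copies$class))
  empty_truth <- stats::setNames(rep(0L, length(cls_all) + 1L),
                                 c(cls_all, "unassigned"))
  if (N == 0L) {
    return(list(sam = header, truth_class = empty_truth,
                truth_unique_by_copy = stats::setNames(
                  rep(0L, nrow(sim$copies)), sim$copies$copy_id),
                library_size = 0L, sample = label))
  }
  cp <- sim$copies
  fc <- config$class_fold_changes
  expr <- if (condition == "B") fc[cp$class] else rep(1, nrow(cp))
  w0 <- pmax(cp$length - rl + 1L, 0L)  # baseline (condition A) weights
  w <- expr * w0
  bf <- config$background_fraction
  # background (gene-like) expression is condition-independent: anchor it to
  # the baseline repeat weights so repeat activation raises the repeat share
  # of the library instead of silently deflating every other class
  bgw <- if (bf > 0) bf / (1 - bf) * sum(w0) else 0
  nsrc <- as.vector(rmultinom(1L, N, c(w, bgw)))
  n_bg <- nsrc[length(nsrc)]; n_copy <- nsrc[-length(nsrc)]

  diff_idx <- lapply(stats::setNames(cls_all, cls_all),
                     function(cl) copy_diff_index(sim, cl))
  gstr <- as.character(sim$genome[[1]])

  acc <- list()  # per-source vectors of SAM fields
  truth_class <- empty_truth
  uniq_copy <- stats::setNames(rep(0L, nrow(cp)), cp$copy_id)
  ridx <- 0L

  for (ci in which(n_copy > 0L)) {
    n <- n_copy[ci]
    cls <- cp$class[ci]
    di <- diff_idx[[cls]]
    k <- match(cp$copy_id[ci], di$ids)
    offs <- sample.int(cp$length[ci] - rl + 1L, n, replace = TRUE) - 1L
    # tie set per read: same-class copies with an identical window
    ties <- matrix(FALSE, n, length(di$ids))
    ties[, k] <- TRUE
    for (j in seq_along(di$ids)) {
      if (j == k) next
      ok_len <- offs + rl <= di$lens[j]
      d <- di$diffs[[k, j]]
      if (length(d) == 0L) { ties[, j] <- ok_len; next }
      hits <- findInterval(offs + rl, d) - findInterval(offs, d)
      ties[, j] <- ok_len & hits == 0L
    }
    tie_list <- apply(ties, 1L, which, simplify = FALSE)
    nplace <- lengths(tie_list)
    pick <- floor(runif(n) * nplace) + 1L  # uniform among equal-best
    rows_map <- match(di$ids, cp$copy_id)
    rd <- rep(seq_len(n), nplace)             # read index per placement
    cj <- unlist(tie_list, use.names = FALSE) # copy index per placement
    is_prim <- sequence(nplace) == pick[rd]
    row <- rows_map[cj]
    off_rep <- offs[rd]
    start <- ifelse(cp$strand[row] == "+", cp$start[row] + off_rep,
                    cp$end[row] - off_rep - rl + 1L)
    names_i <- sprintf("%s_r%07d", label, ridx + seq_len(n))
    ridx <- ridx + n
    acc[[length(acc) + 1L]] <- list(
      qn = names_i[rd],
      fl = ifelse(is_prim, 0L, 256L) + ifelse(cp$strand[row] == "-", 16L, 0L),
      po = as.integer(start),
      mq = ifelse(nplace[rd] == 1L, 50L, 1L))
    sel <- nplace[rd] == 1L  # unique reads: their only placement
    if (any(sel)) {
      tb <- table(cp$copy_id[row[sel]])
      uniq_copy[names(tb)] <- uniq_copy[names(tb)] + as.integer(tb)
    }
    truth_class[cls] <- truth_class[cls] + n
  }
  if (n_bg > 0L) {
    gp <- sim$gaps
    gw <- pmax(gp$end - gp$start + 1L - rl + 1L, 0L)
    gi <- sample.int(nrow(gp), n_bg, replace = TRUE, prob = gw)
    starts <- gp$start[gi] + floor(runif(n_bg) * gw[gi])
    acc[[length(acc) + 1L]] <- list(
      qn = sprintf("%s_r%07d", label, ridx + seq_len(n_bg)),
      fl = rep(0L, n_bg), po = as.integer(starts), mq = rep(50L, n_bg))
    ridx <- ridx + n_bg
    truth_class["unassigned"] <- n_bg
  }
  qn <- unlist(lapply(acc, `[[`, "qn"), use.names = FALSE)
  fl <- unlist(lapply(acc, `[[`, "fl"), use.names = FALSE)
  po <- unlist(lapply(acc, `[[`, "po"), use.names = FALSE)
  mq <- unlist(lapply(acc, `[[`, "mq"), use.names = FALSE)
  sq <- substring(gstr, po, po + rl - 1L)
  qual <- strrep("I", rl)
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  qn, fl, sim$chrom, po, mq, rl, sq, qual)
  list(sam = c(header, recs), truth_class = truth_class,
       truth_unique_by_copy = uniq_copy, library_size = N, sample = label)
}

#' Simulate the full two-condition RNA-seq experiment
#'
#' @param sim a `toy_simulation`.
#' @param config defaults to `sim$config`.
#' @return named list of [simulate_rnaseq_alignments()] results, one per
#'   sample (`A_1 ... B_n`).
#' @export
simulate_rnaseq_experiment <- function(sim, config = sim$config) {
  out <- list()
  for (cond in c("A", "B"))
    for (r in seq_along(config$library_sizes)) {
      x <- simulate_rnaseq_alignments(sim, cond, replicate = r, config = config)
      out[[x$sample]] <- x
    }
  out
}

#' Simulate bisulfite or oxidative-bisulfite reads from an amplicon
#'
#' Chemistry contract, per cytosine per read: an unmethylated C is read as
#' T with probability `bs_conversion_efficiency`; 5mC is read as C under
#' both treatments; 5hmC is read as C under BS and, under oxBS, as T with
#' probability `oxidation_efficiency * bs_conversion_efficiency`. Non-CpG
#' cytosines are simulated as unmethylated. Reads span the full amplicon
#' (top strand).
#'
#' @param amplicon reference sequence (character or DNAString).
#' @param truth data.frame with `pos` (1-based C of each CpG), `five_mC`,
#'   `five_hmC`; must cover every CpG of the amplicon.
#' @param treatment "BS" or "oxBS".
#' @param n_reads reads to simulate.
#' @param config a [simulation_config()] (efficiencies + seed).
#' @param seed_offset extra RNG offset so each amplicon/treatment/replicate
#'   has its own stream.
#' @return character vector of FASTQ lines.
#' @export
simulate_bisulfite_reads <- function(amplicon, truth,
                                     treatment = c("BS", "oxBS"),
                                     n_reads, config, seed_offset = 0L) {
  treatment <- match.arg(treatment)
  set.seed(config$seed + 200L + as.integer(seed_offset) +
             (treatment == "oxBS"))
  s <- as.character(amplicon)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(truth$five_mC + truth$five_hmC > 1))
    stop("invalid truth: five_mC + five_hmC > 1 at some CpG")
  cpg <- gregexpr("CG", s, fixed = TRUE)[[1]]; cpg <- cpg[cpg > 0]
  if (!all(cpg %in% truth$pos))
    stop("truth must cover every CpG of the amplicon")
  cpos <- which(ch == "C")
  mm <- stats::setNames(rep(0, length(cpos)), cpos)
  hh <- mm
  tr <- truth[match(intersect(truth$pos, cpos), truth$pos), , drop = FALSE]
  mm[as.character(tr$pos)] <- tr$five_mC
  hh[as.character(tr$pos)] <- tr$five_hmC
  conv <- config$bs_conversion_efficiency
  ox <- config$oxidation_efficiency
  pC <- if (treatment == "BS") mm + hh + (1 - mm - hh) * (1 - conv)
        else mm + hh * (1 - ox * conv) + (1 - mm - hh) * (1 - conv)
  reads <- if (n_reads > 0L) {
    base <- matrix(ch, nrow = n_reads, ncol = length(ch), byrow = TRUE)
    if (length(cpos)) {
      u <- matrix(runif(n_reads * length(cpos)), nrow = n_reads)
      isC <- u < matrix(pC, n_reads, length(cpos), byrow = TRUE)
      base[, cpos] <- ifelse(isC, "C", "T")
    }
    apply(base, 1L, paste, collapse = "")
  } else character(0)
  qual <- strrep("I", nchar(s))
  ids <- sprintf("@%s", sprintf("bsread_%s_%d_%06d",
                                treatment, seed_offset, seq_len(n_reads)))
  as.vector(rbind(ids, reads, rep("+", n_reads), rep(qual, n_reads)))
}

#' Simulate a ChIP-seq peak set over the toy genome
#'
#' A fraction `peak_enrichment_fraction` of peaks is placed wholly inside
#' copies of the enriched classes; the remainder is placed uniformly over
#' the mappable regions.
#'
#' @param sim a `toy_simulation`.
#' @param enriched_classes classes to enrich (subset of planted classes);
#'   empty means a fully null peak set.
#' @param n_peaks number of peaks.
#' @param config defaults to `sim$config`.
#' @param mappable optional [GenomicRanges::GRanges] of mappable regions;
#'   default is the whole chromosome.
#' @return list with `peaks` (GRanges, mcols `name` and `planted`),
#'   `mappable` (GRanges), `truth` (named logical enrichment per class).
#' @export
simulate_peaks <- function(sim, enriched_classes = character(0),
                           n_peaks = sim$config$n_peaks,
                           config = sim$config, mappable = NULL) {
  if (n_peaks < 0) stop("n_peaks must be non-negative")
  cls <- sort(unique(sim$copies$class))
  if (!all(enriched_classes %in% cls))
    stop("enriched_classes must be planted repeat classes")
  set.seed(config$seed + 300L)
  if (is.null(mappable))
    mappable <- GenomicRanges::GRanges(
      sim$chrom, IRanges::IRanges(1L, sim$chrom_length))
  wdt <- config$peak_width
  n_enr <- if (length(enriched_classes)) {
    round(config$peak_enrichment_fraction * n_peaks)
  } else 0L
  starts <- integer(0); planted <- character(0)
  if (n_enr > 0L) {
    tgt <- enriched_classes[1L + (seq_len(n_enr) - 1L) %% length(enriched_classes)]
    for (cl in enriched_classes) {
      nn <- sum(tgt == cl)
      if (nn == 0L) next
      cc <- sim$copies[sim$copies$class == cl & sim$copies$length >= wdt, ]
      wts <- cc$length - wdt + 1L
      pick <- sample.int(nrow(cc), nn, replace = TRUE, prob = wts)
      off <- vapply(wts[pick], function(x) sample.int(x, 1L), 1L) - 1L
      starts <- c(starts, cc$start[pick] + off)
      planted <- c(planted, rep(cl, nn))
    }
  }
  n_bg <- n_peaks - length(starts)
  if (n_bg > 0L) {
    bg <- place_uniform(rep(wdt, n_bg), mappable)
    starts <- c(starts, bg$start)
    planted <- c(planted, rep("background", n_bg))
  }
  peaks <- GenomicRanges::GRanges(
    sim$chrom, IRanges::IRanges(start = starts, width = wdt))
  mcols(peaks)$name <- sprintf("peak_%04d", seq_along(peaks))
  mcols(peaks)$planted <- planted
  truth <- stats::setNames(cls %in% enriched_classes, cls)
  list(peaks = sort(peaks), mappable = mappable, truth = truth)
}
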