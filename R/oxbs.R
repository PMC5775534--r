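#' CpG positions of an amplicon
#' @param amplicon reference sequence (character or DNAString).
#' @return 1-based positions of the C of each CpG.
#' @export
amplicon_cpg_positions <- function(amplicon) {
  s <- as.character(amplicon)
  p <- gregexpr("CG", s, fixed = TRUE)[[1]]
  as.integer(p[p > 0])
}

# named character vector of amplicon references (as.character drops names)
as_amplicon_vec <- function(amplicons) {
  v <- as.character(amplicons)
  names(v) <- names(amplicons) %||% sprintf("amplicon_%d", seq_along(v))
  v
}

#' Conversion-aware matching of amplicon bisulfite reads
#'
#' Amplicon reads span the whole reference, so alignment reduces to
#' ungapped conversion-aware matching: each read is compared against each
#' amplicon in both orientations, with reference-C positions (forward) or
#' reference-G positions (reverse, after reverse-complementing the read)
#' exempted from mismatch counting, because a converted or unconverted
#' base is legitimate there. The read is assigned to the
#' amplicon/orientation minimising mismatches if that minimum is at most
#' `max_mismatch_frac` of the read length; otherwise it is unassigned.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of reads.
#' @param amplicons named character vector (or DNAStringSet) of
#'   references.
#' @param max_mismatch_frac mismatch tolerance as a fraction of read
#'   length.
#' @return data.frame with `read` (index), `amplicon` (NA if unassigned),
#'   `orientation` ("fwd"/"rev"), `mismatches`.
#' @export
match_amplicon_reads <- function(reads, amplicons, max_mismatch_frac = 0.1) {
  rd <- as.character(reads)
  amp <- as_amplicon_vec(amplicons)
  n <- length(rd)
  best_mm <- rep(Inf, n)
  best_amp <- rep(NA_character_, n)
  best_ori <- rep(NA_character_, n)
  rc <- revcomp_chr(rd)
  lens <- nchar(rd)
  for (a in names(amp)) {
    ach <- strsplit(amp[[a]], "", fixed = TRUE)[[1]]
    for (ori in c("fwd", "rev")) {
      exempt_base <- if (ori == "fwd") "C" else "G"
      seqs <- if (ori == "fwd") rd else rc
      for (L in unique(lens)) {
        if (L > length(ach)) next  # read longer than the amplicon
        sel <- which(lens == L)
        ref <- ach[seq_len(L)]
        M <- matrix(unlist(strsplit(seqs[sel], "", fixed = TRUE),
                           use.names = FALSE), ncol = L, byrow = TRUE)
        mmm <- M != matrix(ref, length(sel), L, byrow = TRUE)
        mmm[, ref == exempt_base] <- FALSE
        mm <- rowSums(mmm)
        upd <- sel[mm < best_mm[sel]]
        if (length(upd)) {
          best_mm[upd] <- mm[mm < best_mm[sel]]
          best_amp[upd] <- a
          best_ori[upd] <- ori
        }
      }
    }
  }
  ok <- best_mm <= max_mismatch_frac * lens
  data.frame(read = seq_len(n),
             amplicon = ifelse(ok, best_amp, NA_character_),
             orientation = ifelse(ok, best_ori, NA_character_),
             mismatches = ifelse(is.finite(best_mm), best_mm, NA_real_),
             stringsAsFactors = FALSE)
}

#' Tally converted/unconverted states at each CpG
#'
#' At each CpG C position, a read base C increments `n_C` (unconverted)
#' and T increments `n_T` (converted); any other base is ignored.
#' Reverse-orientation reads are reverse-complemented into top-strand
#' coordinates, where the bottom-strand CpG cytosine appears at the G of
#' the CpG: G there counts as unconverted, A as converted.
#'
#' @param reads character vector / DNAStringSet (same set passed to
#'   [match_amplicon_reads()]).
#' @param assignment data.frame from [match_amplicon_reads()].
#' @param amplicons named character vector of references.
#' @return data.frame: `amplicon`, `pos`, `n_C`, `n_T`, `coverage`.
#' @export
tally_cpg_states <- function(reads, assignment, amplicons) {
  rd <- as.character(reads)
  amp <- as_amplicon_vec(amplicons)
  out <- list()
  for (a in names(amp)) {
    cpg <- amplicon_cpg_positions(amp[[a]])
    nC <- nT <- stats::setNames(rep(0L, length(cpg)), cpg)
    fwd <- rd[which(assignment$amplicon == a & assignment$orientation == "fwd")]
    if (length(fwd)) {
      for (j in seq_along(cpg)) {
        b <- substr(fwd, cpg[j], cpg[j])
        nC[j] <- nC[j] + sum(b == "C"); nT[j] <- nT[j] + sum(b == "T")
      }
    }
    rev <- rd[which(assignment$amplicon == a & assignment$orientation == "rev")]
    if (length(rev)) {
      rc <- revcomp_chr(rev)
      for (j in seq_along(cpg)) {
        b <- substr(rc, cpg[j] + 1L, cpg[j] + 1L)
        nC[j] <- nC[j] + sum(b == "G"); nT[j] <- nT[j] + sum(b == "A")
      }
    }
    out[[a]] <- data.frame(amplicon = a, pos = cpg,
                           n_C = unname(nC), n_T = unname(nT),
                           coverage = unname(nC + nT),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call 5mC and 5hmC from paired BS/oxBS tallies
#'
#' BS measures 5mC + 5hmC (unconverted C fraction), oxBS measures 5mC
#' alone, so `five_mC = level_oxBS` and
#' `five_hmC = max(0, level_BS - level_oxBS)`. A CpG passes QC iff both
#' treatments have coverage of at least `min_coverage` reads (inclusive).
#' CpGs missing one treatment are emitted with `qc_pass = FALSE` and a
#' missingness flag; levels are reported regardless of QC.
#'
#' @param counts_bs,counts_oxbs tallies from [tally_cpg_states()].
#' @param min_coverage minimum reads per treatment (default 100).
#' @return data.frame per CpG: coverages, levels, `five_mC`, `five_hmC`,
#'   `qc_pass`, `missing_treatment`.
#' @export
call_methylation <- function(counts_bs, counts_oxbs, min_coverage = 100L) {
  m <- merge(counts_bs, counts_oxbs, by = c("amplicon", "pos"),
             all = TRUE, suffixes = c("_BS", "_oxBS"))
  m <- m[order(m$amplicon, m$pos), , drop = FALSE]
  cov_bs <- m$coverage_BS; cov_ox <- m$coverage_oxBS
  level_bs <- ifelse(!is.na(cov_bs) & cov_bs > 0, m$n_C_BS / cov_bs, NA_real_)
  level_ox <- ifelse(!is.na(cov_ox) & cov_ox > 0, m$n_C_oxBS / cov_ox, NA_real_)
  missing <- is.na(cov_bs) | is.na(cov_ox)
  data.frame(
    amplicon = m$amplicon, pos = m$pos,
    coverage_BS = ifelse(is.na(cov_bs), 0L, cov_bs),
    coverage_oxBS = ifelse(is.na(cov_ox), 0L, cov_ox),
    level_BS = level_bs, level_oxBS = level_ox,
    five_mC = level_ox,
    five_hmC = ifelse(is.na(level_bs) | is.na(level_ox), NA_real_,
                      pmax(0, level_bs - level_ox)),
    qc_pass = !missing & !is.na(cov_bs) & !is.na(cov_ox) &
      cov_bs >= min_coverage & cov_ox >= min_coverage,
    missing_treatment = missing,
    stringsAsFactors = FALSE)
}

#' Average methylation calls across replicates
#'
#' Unweighted mean of levels across QC-passing replicates per CpG; CpGs
#' with no passing replicate are omitted.
#'
#' @param calls list of data.frames from [call_methylation()], one per
#'   biological replicate.
#' @return data.frame per CpG with mean levels and `n_replicates`.
#' @export
aggregate_amplicon <- function(calls) {
  all <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  all <- all[all$qc_pass, , drop = FALSE]
  if (!nrow(all))
    return(data.frame(amplicon = character(0), pos = integer(0),
                      level_BS = numeric(0), level_oxBS = numeric(0),
                      five_mC = numeric(0), five_hmC = numeric(0),
                      n_replicates = integer(0)))
  agg <- stats::aggregate(
    all[, c("level_BS", "level_oxBS", "five_mC", "five_hmC")],
    by = list(amplicon = all$amplicon, pos = all$pos), FUN = mean)
  nrep <- stats::aggregate(list(n_replicates = all$qc_pass),
                           by = list(amplicon = all$amplicon, pos = all$pos),
                           FUN = length)
  out <- merge(agg, nrep, by = c("amplicon", "pos"))
  out[order(out$amplicon, out$pos), , drop = FALSE]
}
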