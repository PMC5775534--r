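`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA string
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Substitute bases at rate `rate`; substituted base always differs.
#' @noRd
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(ch)) < rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(ch[idx], function(b) sample(setdiff(bases, b), 1L), "")
    ch[idx] <- repl
  }
  paste(ch, collapse = "")
}

#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic TSV writers: fixed quoting/sep so reruns are byte-identical
write_tsv_ <- function(df, path, rownames = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = rownames, col.names = TRUE)
}

read_tsv_ <- function(path, rownames = FALSE) {
  read.table(path, sep = "\t", header = TRUE,
             row.names = if (rownames) 1L else NULL,
             stringsAsFactors = FALSE, check.names = FALSE)
}
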