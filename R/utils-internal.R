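# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere in memory; substring extraction converts to R's 1-based indexing.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom Biostrings DNAStringSet reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract [start, end) (0-based half-open) from a sequence string.
subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Open reading frame free of stop codons, length a multiple of 3.
random_orf <- function(n_codons) {
  codons <- do.call(paste0, expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                                        stringsAsFactors = FALSE))
  codons <- setdiff(codons, STOP_CODONS)
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

random_umi <- function(n, len = 6L) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Per-base integer comparison of two equal-length strings; TRUE where equal.
match_vector <- function(a, b) {
  utf8ToInt(a) == utf8ToInt(b)
}

phred_string <- function(len, q = 35L) {
  strrep(intToUtf8(33L + q), len)
}

# Translate and scan for a stop codon in frame starting at 1-based pos `from`.
has_inframe_stop <- function(seq, from = 1L) {
  n <- nchar(seq)
  if (n - from + 1L < 3L) return(FALSE)
  starts <- seq.int(from, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  any(codons %in% STOP_CODONS)
}

abort_if <- function(cond, msg) if (cond) rlang::abort(msg)
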