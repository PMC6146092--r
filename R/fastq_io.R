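#' Write a read-pair tibble as gzipped FASTQ R1/R2
#'
#' @param reads tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Named list with the two file paths.
#' @export
write_fastq_pair <- function(reads, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- file.path(dir, paste0(prefix, "_R1.fastq.gz"))
  r2 <- file.path(dir, paste0(prefix, "_R2.fastq.gz"))
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- reads$read_id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = TRUE)
  }
  write_one(reads$seq1, reads$qual1, r1)
  write_one(reads$seq2, reads$qual2, r2)
  list(r1 = r1, r2 = r2)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1,r2 paths to the mate FASTQ files (plain or gzipped).
#' @return Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  abort_if(length(s1) != length(s2), "mate files differ in read count")
  id1 <- sub("\\s.*$", "", names(s1))
  id2 <- sub("\\s.*$", "", names(s2))
  abort_if(!identical(id1, id2), "mate files are not in the same read order")
  tibble::tibble(
    read_id = id1,
    seq1 = unname(as.character(s1)),
    qual1 = unname(as.character(S4Vectors::mcols(s1)$qualities)),
    seq2 = unname(as.character(s2)),
    qual2 = unname(as.character(S4Vectors::mcols(s2)$qualities))
  )
}
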