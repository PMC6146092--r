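# Shared fixtures, built once per test run. All synthetic, generated in code.

fixture_env <- new.env()

# small 12-gene locus with one 3'-identical pair
small_ref <- function() {
  if (is.null(fixture_env$small_ref)) {
    fixture_env$small_ref <- simulate_locus(n_v = 12, n_pairs = 1, seed = 42)
  }
  fixture_env$small_ref
}

# tiny pairless locus for caller unit tests
tiny_ref <- function() {
  if (is.null(fixture_env$tiny_ref)) {
    fixture_env$tiny_ref <- simulate_locus(n_v = 6, seed = 11)
  }
  fixture_env$tiny_ref
}

# uniform-frequency truth + gDNA calls on the small locus
small_calls <- function() {
  if (is.null(fixture_env$small_calls)) {
    ref <- small_ref()
    cfg <- sim_config(n_molecules = 4000, seed = 7)
    truth <- simulate_repertoire(ref, cfg)
    reads <- simulate_gdna_library(truth, ref, cfg)
    calls <- call_vj(prep_reads(reads), ref, "gdna", sample_id = "s1")
    fixture_env$small_calls <- list(ref = ref, cfg = cfg, truth = truth,
                                    reads = reads, calls = calls)
  }
  fixture_env$small_calls
}

# a read pair with the given mate sequences and uniform quality
make_pair <- function(seq1, seq2, q1 = 35L, q2 = 35L, id = "p1") {
  tibble::tibble(
    read_id = id,
    seq1 = seq1, qual1 = strrep(intToUtf8(33L + q1), nchar(seq1)),
    seq2 = seq2, qual2 = strrep(intToUtf8(33L + q2), nchar(seq2))
  )
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate k distinct positions of a sequence (guaranteed mismatches)
mutate_bases <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}
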